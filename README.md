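# odptools

Ontology-based Open Discovery for drug repurposing from literature.

`odptools` is for text-mining and drug-repurposing researchers who want to
connect a disease to candidate drugs through the scientific literature
when the disease and the drug are never mentioned together. It implements
the Open Discovery Process — the set-valued form of Swanson's ABC model —
using complete disease ontologies as the intermediate vocabulary: every
label and synonym of an epilepsy ontology becomes a *B-term*, drug names
are the *C-terms*, and a drug is linked to the disease by how many
documents contain both a B-term and the drug (document frequency, not
mention frequency).

The pipeline covers:

- **Dictionary NER** — ontology/vocabulary term sources (OWL or a simple
  TSV dialect) compiled into normalized lookup dictionaries, optionally
  stem-expanded with a built-in Porter2 (snowball) stemmer, and matched
  token-wise (case-insensitive, leftmost-longest) against a JSON-Lines
  citation corpus, producing stand-off annotations.
- **Co-occurrence ranking** — per-ontology drug document frequencies and
  deterministic ranked lists.
- **Prioritization** — ATC class-N (nervous system) filtering and an
  additive 0–5 priority score: one point per reference treatment list
  containing the drug, plus one for an ATC N03 (antiepileptics) code.
- **Rank fusion** — a final top-k list minimizing the mean Spearman
  footrule (or Kendall) distance to the per-ontology lists, by exhaustive
  search (small unions) or cross-entropy Monte Carlo.
- **Drug Set Enrichment Analysis (DSEA)** — a running-sum score along a
  ranked list D = (d₁,…,d_N) against a reference set R (|R| = S):

      x_i = x_{i−1} + ϑ_i,   τ_i = #matches among d₁..d_i
      ϑ_i = ln((S + τ′_i)/(S − τ′_i))   if d_i ∈ R   (τ′ = min(τ, S−1))
      ϑ_i = ln((N − τ_i)/(N + τ_i))     otherwise

  with the curve maximum Ψ\* and its position k as the summary. The
  literal published sign of the bonus is also available
  (`convention = "verbatim"`); see the methods vignette.
- **Ontology comparison** — shared-synonym concept matching (explicit and
  implicit similarity via connected components), synonym-overlap reports
  and document-set Venn statistics.
- **Synthetic data** — deterministic generators for corpora, term sources
  and reference sets with recorded ground truth, so the whole pipeline is
  testable offline.

## Worked example

```r
library(odptools)

epi  <- TermSource("epi", c("b1", "b2"), c("Seizure", "Status epilepticus"))
drug <- TermSource("drugs", c("d1", "d2"), c("Ketamine", "Phenobarbital"),
                   role = "C")
dicts <- lapply(list(epi, drug), buildDictionary, stem = TRUE)

corpus <- data.frame(
  pmid = c("p1", "p2", "p3"),
  title = c("Ketamine reduced seizures",
            "Phenobarbital pharmacokinetics",
            "Status epilepticus treated with Phenobarbital"),
  abstractText = c("convulsive activity declined",
                   "no epilepsy terms here",
                   "Ketamine was added later"))

res <- annotateCorpus(corpus, dicts)
res$annotations
#>   docId offset length        matchedText       conceptLabel sourceId
#> 1    p1      0      8           Ketamine           Ketamine    drugs
#> 2    p1     17      8           seizures            Seizure      epi
#> 3    p2      0     13      Phenobarbital      Phenobarbital    drugs
#> 4    p3      0     18 Status epilepticus Status epilepticus      epi
#> 5    p3     32     13      Phenobarbital      Phenobarbital    drugs
#> 6    p3     46      8           Ketamine           Ketamine    drugs
```

The stemmed dictionary matched "seizures" to the concept "Seizure", and
the two-token form "Status epilepticus" won over any shorter match.
Documents p1 and p3 carry B-terms; p2 mentions a drug but no epilepsy
term, so it never counts:

```r
tab <- aggregateCounts(res$summaries, "epi")
rankDrugs(tab)
#> RankedDrugList 'epi': 2 drugs
#>    1. Ketamine (2)
#>    2. Phenobarbital (1)
ratioBCoverB(tab)    # % of B-term documents that also mention a drug
#> [1] 100
```

Ketamine co-occurs with epilepsy terms in 2 of the 2 B-term documents and
ranks first. Scoring the ranked list against a reference set and scoring
a drug against four treatment lists plus the ATC map:

```r
cv <- dseaCurve(rankDrugs(tab),
                ReferenceSet("refs", c("Phenobarbital", "Valproic acid")))
round(scores(cv), 4)
#> [1] 0.0000 1.0986
cv
#> EnrichmentCurve (corrected): N = 2, S = 2, 1 matches; max 1.0986 at k = 2

refs <- lapply(c("lancet", "drugse", "efo", "u2d"),
               function(l) ReferenceSet(l, "Phenobarbital"))
priorityScore("Phenobarbital", refs, list(Phenobarbital = "N03AA02"))
#> [1] 5
```

The miss at position 1 contributes ln(2/2) = 0 (no match seen yet); the
match at position 2 contributes ln((2+1)/(2−1)) ≈ 1.0986, the curve
maximum. Phenobarbital sits on all four reference lists and carries an
N03 code, the maximal priority of 5.

`runPipeline(config)` orchestrates all stages over plain files and writes
every intermediate artifact plus a manifest with input/output hashes; see
`?runPipeline` and the methods vignette (`vignettes/odp-methods.Rmd`) for
the model, parameter and convention details.

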