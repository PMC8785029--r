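---
title: "Methods: literature-based drug discovery with ontology term sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature-based drug discovery with ontology term sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The discovery model

`odptools` implements the Open Discovery Process, the set-valued extension
of Swanson's ABC model of literature-based discovery. A disease concept A
(here: epilepsy) is connected to candidate drugs C through intermediate
B-terms — the pooled labels and synonyms of disease-specific ontologies —
that co-occur with drug names in citation abstracts, even when the disease
name and the drug never share a document. The pipeline is:

1. **Dictionary compilation** (`loadTermSource()`, `buildDictionary()`):
   each ontology is flattened to a term set (no axioms, no hierarchy —
   the discovery model uses ontologies purely as vocabularies). Surface
   forms are normalized by case-folding, punctuation splitting and
   whitespace collapsing; optionally each token is Porter2-stemmed and the
   stemmed variant added as an *additional* entry, so exact forms always
   match and inflected text forms ("seizures") still reach the concept
   ("Seizure").
2. **Named-entity recognition** (`annotateDocument()`,
   `annotateCorpus()`): token-granular, case-insensitive,
   leftmost-longest matching of dictionary forms against the concatenated
   title + abstract of each citation, emitting stand-off annotations
   (0-based character offset, length, matched slice, concept label,
   source dictionary). Within one dictionary matches never overlap;
   across dictionaries they may (a drug name inside a B-term span).
3. **Co-occurrence aggregation** (`aggregateCounts()`, `rankDrugs()`):
   per ontology, the document frequency of each drug among documents with
   at least one B-term hit — presence, not mention counts. Ranking is by
   descending document frequency with lexicographic tie-break.
4. **Prioritization** (`filterATC()`, `priorityScore()`): candidate lists
   are restricted to nervous-system drugs (ATC class N; antiepileptics
   are N03) because neurological repurposing candidates must plausibly
   pass the blood–brain barrier. The priority score of a drug is additive:
   one point per reference list containing it plus one point for an N03
   code, so four published treatment lists give a maximum of 5.
5. **Rank fusion** (`combineLists()`): the per-ontology lists are merged
   into one final top-k ordering minimizing the mean rank distance to the
   inputs (Spearman footrule by default, Kendall optionally), by
   exhaustive enumeration for unions of up to 8 items or by cross-entropy
   Monte Carlo (CEMC) otherwise.
6. **Drug Set Enrichment Analysis** (`dseaCurve()`): a running-sum score
   along a ranked list against a reference set, with an adaptive
   bonus/penalty (below). The curve maximum and its position k summarize
   how strongly and how early the reference drugs are enriched.
7. **Ontology comparison** (`conceptOverlap()`, `synonymOverlap()`,
   `docsetOverlap()`): concepts of different sources match when they
   share at least one synonym string; connected components of the match
   graph capture *implicit* similarity (b2 ~ b3 through b1). Document-set
   overlap mirrors the same bookkeeping on the annotated corpus.

## The DSEA score

For a ranked list D = (d_1, ..., d_N) and reference set R with |R| = S,
position i contributes an increment to the running sum x_i = x_{i-1} + ϑ_i,
where τ_i is the number of matches among d_1..d_i (including d_i itself):

- miss: ϑ_i = ln((N − τ_i) / (N + τ_i)) — zero while no match has been
  seen, increasingly negative as matches accumulate;
- match, corrected convention (default): ϑ_i = ln((S + τ'_i) / (S − τ'_i))
  with τ'_i = min(τ_i, S − 1) — strictly positive (for S > 1) and growing
  with τ, so short reference sets are rewarded progressively.

Two conventions are exposed because the printed form of the bonus,
ln((S − τ) / (S + τ)), is negative — contradicting its description as a
bonus and the rising-then-falling shape of published enrichment profiles.
`convention = "verbatim"` reproduces that literal form; `"corrected"`
inverts the fraction and is the default. Both are first-class and tested.
The τ' clamp (applied inside the bonus only, in both conventions) keeps
the score finite once all S reference drugs have been found, at the cost
of a zero bonus in the degenerate S = 1 case; τ is read as including the
current element, and the penalty guard (increment 0 if N = τ) is
unreachable for valid inputs but kept defensively. The maximum is taken
over x_1..x_N with k the smallest attaining index (1-based; an all-zero
curve reports (0, 1)).

## Rank fusion choices

The fusion criterion is the mean Spearman footrule distance over the input
lists, with an item absent from a list of length ℓ assigned rank ℓ + 1 —
the standard top-k list convention. The CEMC optimizer samples
permutations from a position-by-item weight matrix, keeps the best 10% of
each sample of 100, and tilts the matrix towards the elite with smoothing
0.7; the incumbent best permutation is re-injected every iteration, so the
best objective is monotone non-increasing, and search stops after 10
iterations without improvement beyond `tol = 1e-6` (or 100 iterations).
`k = "auto"` picks the smallest k at which the per-item objective of the
optimal full ordering stops improving by more than `tol`; the exact
data-driven rule used for the published final list is not specified, so
this is the package's own choice and the final ordering is not asserted
bit-for-bit against the published table. Ties among optimal orderings are
broken lexicographically under exhaustive search; CEMC may return any
optimum, which is why equivalence is asserted on the objective value.

## Normalization and matching policies

- Dictionary matching: case-insensitive, token-granular; substring
  matches inside tokens are rejected. Offsets are 0-based, half-open,
  into title + abstract joined by a single space (the offset base is a
  package decision; only consistency matters downstream).
- Ontology comparison matches synonyms by case-insensitive exact string
  equality after trimming, *without* stemming: stemmed matching would
  merge distinct terms and inflate the cross-ontology mapping.
- Synonym bookkeeping counts stored synonym strings (preferred labels
  excluded); report percentages are recomputed from loaded counts at the
  printed precision (3 decimals for concept/synonym shares, 2 for corpus
  coverage). Published per-concept synonym ratios that are inconsistent
  with their own printed counts are deliberately not reproduced.
- The Porter2 (English snowball) stemmer is implemented in the package
  from the published algorithm definition (no R implementation is
  declared as a dependency); it is verified in the test suite against the
  algorithm's documented exception lists and hand-traced derivations.

## The synthetic-data generators

`genCorpus()` plants B-terms (per ontology, probability `pB`) and drug
names (per drug, probability `pDrug`) independently into documents of
background tokens drawn from a small closed vocabulary; generation is
refused if the background vocabulary collides with any planted token, so
dictionary hits are exactly the planted occurrences. At least 20% of the
generated vocabulary is multi-word to exercise leftmost-longest matching.
`genTermSources()` *constructs* (never samples) sources whose pairwise
shared-concept counts equal the planted overlap exactly, and
`genReferenceSet()` plants reference matches at chosen list positions.
Every ground truth is recomputable from the generated artifacts by brute
force, and the test suite does so.

What the generators do **not** emulate: Medline's term-frequency and
document-length distributions, ambiguous drug names (a drug name that is
also an everyday word), nested or overlapping ontology terms beyond the
planted vocabulary, and negated or hypothetical mentions. Passing tests
therefore certify the mechanics of matching, counting, ranking, fusion
and scoring — not NER accuracy on real text.

## Problem sizes and determinism

The test suite runs corpora of 20–400 synthetic documents, ontologies of
up to ~20 concepts per source (137 where a published shared-concept
percentage is mirrored arithmetically), fusion unions of 4–6 items with
100 seeded CEMC-vs-exhaustive instances, and DSEA lists up to length 15 —
sizes chosen so the full suite completes in well under a minute while
every code path, including the degenerate ones (empty corpus, zero
matches, S > N, τ = S), is exercised. All stochastic stages take explicit
seeds, preserve the caller's RNG state, and the pipeline's manifest
records input and output hashes; two runs with the same configuration and
seed are byte-identical.

## Known limitations

- The published full-corpus results (per-ontology lists of 6,318–8,620
  drugs from 15.5M citations, the EPILONT enrichment maximum at k = 93,
  final filtered lengths of 431–471) require the original corpus,
  ontology files and drug vocabulary and are out of desk-scale reach;
  the package reproduces the printed report arithmetic and validates the
  machinery by oracle equivalence instead.
- Relation types between a drug and the disease (treats, potentially
  treats, related, causes as side effect) are a manual-curation
  pass-through column, never computed.
- Raw document frequency is the only association measure, as in the
  underlying method; no PMI, chi-square or significance testing of
  enrichment scores is provided.
- OWL parsing extracts labels and common synonym annotation properties
  from RDF/XML; it does not reason over axioms, imports or OBO-style
  cross-references.
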