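## Deterministic synthetic-data generation: every pipeline stage is
## testable without the real corpus, ontologies or drug vocabulary. The
## generators record ground truth during generation; the truth is always
## independently recomputable from the generated artifacts by brute force.

.odpBackgroundVocab <- c(
  "lorem", "ipsum", "dolor", "amet", "consectetur", "adipiscing", "elit",
  "tempor", "incididunt", "labore", "magna", "aliqua", "veniam", "quis",
  "nostrud", "ullamco", "laboris", "nisi", "aliquip", "commodo")

# restore the caller's RNG state on exit
.withSeed <- function(seed) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    fn <- function() assign(".Random.seed", old, envir = .GlobalEnv)
  } else {
    fn <- function() if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  }
  set.seed(as.integer(seed))
  fn
}

#' Generate synthetic term sources with planted synonym overlap
#'
#' Constructs (never samples) `nSources` term sources of `nConcepts`
#' concepts each. The first `round(overlapFraction * nConcepts)` concepts
#' of every source carry a synonym shared verbatim across all sources, so
#' pairwise shared-concept counts equal the planted number exactly; all
#' other labels and synonyms are unique to their source. At least 20% of
#' the vocabulary is multi-word to exercise leftmost-longest matching.
#'
#' @param nSources number of sources (default 2).
#' @param nConcepts concepts per source.
#' @param overlapFraction fraction of concepts shared between sources,
#'   in \[0, 1\].
#' @param seed kept for interface symmetry; the construction is
#'   deterministic.
#' @param role role flag of the generated sources.
#' @return list with `sources` (list of [TermSource-class]) and `truth`
#'   (list: `nShared`, `pairwise` matrix, `shared_pct`).
#' @export
genTermSources <- function(nSources = 2L, nConcepts = 20L,
                           overlapFraction = 0, seed = 1L, role = "B") {
  stopifnot(overlapFraction >= 0, overlapFraction <= 1, nConcepts >= 1L)
  nShared <- round(overlapFraction * nConcepts)
  sources <- lapply(seq_len(nSources), function(s) {
    ids <- sprintf("S%d_C%03d", s, seq_len(nConcepts))
    labels <- sprintf("s%dterm%03d", s, seq_len(nConcepts))
    syns <- lapply(seq_len(nConcepts), function(j) {
      if (j <= nShared) sprintf("shared synonym %03d", j)
      else sprintf("s%d synonym %03d", s, j)
    })
    TermSource(sprintf("synthsrc%d", s), ids, labels, syns, role = role)
  })
  ids <- vapply(sources, sourceId, character(1))
  pairwise <- matrix(nShared, nSources, nSources,
                     dimnames = list(ids, ids))
  diag(pairwise) <- 0L
  list(sources = sources,
       truth = list(nShared = nShared, pairwise = pairwise,
                    shared_pct = overlapPercent(nShared, nConcepts)))
}

#' Generate a synthetic citation corpus with planted co-occurrences
#'
#' Each document independently receives, per B-term source, one of its
#' terms with probability `pB[ontology]`, and, per drug, that drug name
#' with probability `pDrug[drug]`; remaining tokens come from a small
#' closed background vocabulary that is checked (and required) to be
#' disjoint from every planted vocabulary, so no accidental dictionary
#' hits occur. The per-ontology co-occurrence table is recorded during
#' generation as ground truth. With a fixed seed, regeneration is
#' byte-identical.
#'
#' @param nDocs number of documents.
#' @param bVocab named list: ontology id to character vector of B-terms
#'   (multi-word terms allowed and encouraged).
#' @param drugVocab character vector of drug names.
#' @param pB named numeric, per-ontology B-term inclusion probability
#'   (single value recycled; default 0.6).
#' @param pDrug named numeric per drug (single value recycled;
#'   default 0.3).
#' @param seed RNG seed; the caller's RNG state is preserved.
#' @param file optional path; the corpus is written as JSON-Lines with
#'   fields `pmid`, `title`, `abstractText`.
#' @param nBackground background tokens per document.
#' @return list with `records` (data.frame `pmid`, `title`,
#'   `abstractText`), `truth` (list of [CooccurrenceTable-class], one per
#'   ontology), `presence` (per-document logical matrices `b` and `drug`)
#'   and `file`.
#' @export
genCorpus <- function(nDocs, bVocab, drugVocab, pB = 0.6, pDrug = 0.3,
                      seed = 1L, file = NULL, nBackground = 8L) {
  stopifnot(is.list(bVocab), !is.null(names(bVocab)),
            length(drugVocab) >= 1L)
  onts <- names(bVocab)
  if (is.null(names(pB)))
    pB <- stats::setNames(rep_len(pB, length(onts)), onts)
  if (is.null(names(pDrug)))
    pDrug <- stats::setNames(rep_len(pDrug, length(drugVocab)), drugVocab)
  stopifnot(all(pB >= 0 & pB <= 1), all(pDrug >= 0 & pDrug <= 1))

  planted <- normalizeTerm(c(unlist(bVocab, use.names = FALSE), drugVocab))
  plantedTokens <- unique(unlist(strsplit(planted, " ", fixed = TRUE)))
  clash <- intersect(.odpBackgroundVocab, plantedTokens)
  if (length(clash))
    stop("background vocabulary collides with planted terms: ",
         paste(clash, collapse = ", "))

  restore <- .withSeed(seed)
  on.exit(restore())

  bHas <- matrix(FALSE, nDocs, length(onts), dimnames = list(NULL, onts))
  drugHas <- matrix(FALSE, nDocs, length(drugVocab),
                    dimnames = list(NULL, drugVocab))
  pmid <- sprintf("doc%05d", seq_len(nDocs))
  title <- abstract <- character(nDocs)
  for (i in seq_len(nDocs)) {
    phrases <- character()
    for (o in onts) {
      if (stats::runif(1) < pB[[o]]) {
        bHas[i, o] <- TRUE
        phrases <- c(phrases, sample(bVocab[[o]], 1L))
      }
    }
    for (d in drugVocab) {
      if (stats::runif(1) < pDrug[[d]]) {
        drugHas[i, d] <- TRUE
        phrases <- c(phrases, d)
      }
    }
    bg <- sample(.odpBackgroundVocab, nBackground, replace = TRUE)
    parts <- sample(c(phrases, bg))
    cut <- min(3L, length(parts))
    title[i] <- paste(parts[seq_len(cut)], collapse = " ")
    abstract[i] <- paste(parts[-seq_len(cut)], collapse = " ")
  }
  records <- data.frame(pmid = pmid, title = title,
                        abstractText = abstract, stringsAsFactors = FALSE)

  truth <- lapply(onts, function(o) {
    hasB <- bHas[, o]
    anyDrug <- rowSums(drugHas) > 0L
    counts <- colSums(drugHas[hasB, , drop = FALSE])
    counts <- counts[counts > 0L]
    new("CooccurrenceTable", ontologyId = o,
        counts = stats::setNames(as.integer(counts), names(counts)),
        nDocsB = sum(hasB), nDocsBC = sum(hasB & anyDrug),
        nDocs = as.integer(nDocs))
  })
  names(truth) <- onts

  if (!is.null(file)) {
    lines <- vapply(seq_len(nDocs), function(i)
      as.character(jsonlite::toJSON(
        list(pmid = pmid[i], title = title[i],
             abstractText = abstract[i]), auto_unbox = TRUE)),
      character(1))
    writeLines(lines, file, useBytes = TRUE)
  }
  list(records = records, truth = truth,
       presence = list(b = bHas, drug = drugHas), file = file)
}

#' Generate a ranked list / reference set pair with planted matches
#'
#' Builds a ranked drug list of `listLength` synthetic drugs (counts
#' strictly decreasing) and a reference set that contains exactly the
#' drugs at `matchPositions`, padded with reference-only items up to
#' `refSize`, so a DSEA curve on the pair receives its bonus increments at
#' exactly the planted positions.
#'
#' @param listLength length N of the ranked list.
#' @param matchPositions integer positions (1-based) of the planted
#'   matches; may be empty (all-penalty curve).
#' @param refSize total reference-set size S; defaults to the number of
#'   planted positions (at least 1 — an empty reference set is invalid).
#' @return list with `list` (a [RankedDrugList-class]) and `ref` (a
#'   [ReferenceSet-class]).
#' @export
genReferenceSet <- function(listLength, matchPositions = integer(),
                            refSize = NULL) {
  stopifnot(listLength >= 1L)
  matchPositions <- sort(unique(as.integer(matchPositions)))
  stopifnot(all(matchPositions >= 1L), all(matchPositions <= listLength))
  if (is.null(refSize)) refSize <- max(1L, length(matchPositions))
  stopifnot(refSize >= length(matchPositions), refSize >= 1L)
  drugNames <- sprintf("synthdrug%03d", seq_len(listLength))
  rdl <- new("RankedDrugList", ontologyId = "synthetic",
             drugs = drugNames,
             counts = as.numeric(rev(seq_len(listLength))))
  extras <- sprintf("refonly%03d", seq_len(refSize - length(matchPositions)))
  ref <- ReferenceSet("synthetic-ref",
                      c(drugNames[matchPositions], extras))
  list(list = rdl, ref = ref)
}
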