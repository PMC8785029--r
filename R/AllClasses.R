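#' @import methods
NULL

#' TermSource: a flat ontology or vocabulary as a set of concepts
#'
#' A term source is an ontology (or a drug-name vocabulary) reduced to a flat
#' set of concepts, each carrying an opaque identifier, a preferred label and
#' zero or more synonym strings. No class hierarchy or axioms are retained:
#' for the Open Discovery Process the ontologies act purely as term sets.
#'
#' @slot sourceId single string naming the source (e.g. an ontology acronym).
#' @slot role either `"B"` (intermediate-term source, e.g. a disease
#'   ontology) or `"C"` (target-term source, e.g. the drug vocabulary).
#' @slot ids character vector of concept identifiers, unique within a source.
#' @slot labels character vector of preferred labels, parallel to `ids`.
#' @slot synonyms list of character vectors, parallel to `ids`; each element
#'   holds the stored synonym strings of one concept (may be empty).
#'
#' @seealso [loadTermSource()], [buildDictionary()], [conceptOverlap()]
#' @export
setClass("TermSource",
  representation(
    sourceId = "character",
    role     = "character",
    ids      = "character",
    labels   = "character",
    synonyms = "list"
  )
)

setValidity("TermSource", function(object) {
  msg <- character()
  if (length(object@sourceId) != 1L || !nzchar(object@sourceId))
    msg <- c(msg, "sourceId must be a single non-empty string")
  if (length(object@role) != 1L || !object@role %in% c("B", "C"))
    msg <- c(msg, "role must be \"B\" or \"C\"")
  n <- length(object@ids)
  if (length(object@labels) != n || length(object@synonyms) != n)
    msg <- c(msg, "ids, labels and synonyms must have equal length")
  if (anyDuplicated(object@ids))
    msg <- c(msg, sprintf("duplicate concept ids in source '%s'",
                          object@sourceId))
  if (any(!nzchar(trimws(object@ids))))
    msg <- c(msg, "concept ids must be non-empty")
  if (n > 0L && any(!nzchar(trimws(object@labels))))
    msg <- c(msg, "preferred labels must be non-empty after trimming")
  syn <- unlist(object@synonyms, use.names = FALSE)
  if (length(syn) && any(!nzchar(trimws(syn))))
    msg <- c(msg, "synonyms must be non-empty after trimming")
  if (length(msg)) msg else TRUE
})

#' TermDictionary: normalized lookup dictionary compiled from a TermSource
#'
#' Maps normalized surface forms (token sequences after case-folding,
#' whitespace collapsing and optional per-token Porter2 stemming) to the
#' concepts they name. Stemmed forms are additional entries, never
#' replacements, so exact surface forms always match.
#'
#' @slot sourceId source the dictionary was compiled from.
#' @slot role `"B"` or `"C"`, inherited from the source.
#' @slot stemmed logical; `TRUE` if stem-expanded entries were added.
#' @slot entries data.frame with columns `normform` (normalized surface
#'   form), `conceptId`, `label` (preferred label of the concept), `surface`
#'   (the original stored surface form) and `fromStem` (logical; entry added
#'   by stemming).
#' @slot maxTokens largest token count over all entries; bounds the span
#'   length the annotator needs to consider.
#'
#' @seealso [buildDictionary()], [annotateDocument()]
#' @export
setClass("TermDictionary",
  representation(
    sourceId  = "character",
    role      = "character",
    stemmed   = "logical",
    entries   = "data.frame",
    maxTokens = "integer"
  )
)

setValidity("TermDictionary", function(object) {
  msg <- character()
  need <- c("normform", "conceptId", "label", "surface", "fromStem")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, paste("entries must have columns:",
                        paste(need, collapse = ", ")))
  if (length(object@role) != 1L || !object@role %in% c("B", "C"))
    msg <- c(msg, "role must be \"B\" or \"C\"")
  if (length(msg)) msg else TRUE
})

#' RankedDrugList: drugs ordered by document frequency
#'
#' The ordered sequence D = (d_1, ..., d_N) of drug names produced by ranking
#' co-occurrence document frequencies (or by rank fusion, in which case the
#' counts slot is empty).
#'
#' @slot ontologyId id of the ontology whose B-terms defined the
#'   co-occurrence (or a label such as `"final"` for a fused list).
#' @slot drugs character vector of unique drug labels, best rank first.
#' @slot counts numeric vector of document frequencies aligned to `drugs`
#'   (non-increasing), or empty when the list does not carry counts.
#'
#' @seealso [rankDrugs()], [combineLists()], [dseaCurve()]
#' @export
setClass("RankedDrugList",
  representation(
    ontologyId = "character",
    drugs      = "character",
    counts     = "numeric"
  )
)

setValidity("RankedDrugList", function(object) {
  msg <- character()
  if (length(object@ontologyId) != 1L)
    msg <- c(msg, "ontologyId must be a single string")
  if (anyDuplicated(object@drugs))
    msg <- c(msg, "drug labels must be unique")
  nc <- length(object@counts)
  if (nc != 0L && nc != length(object@drugs))
    msg <- c(msg, "counts must be empty or parallel to drugs")
  if (nc > 1L && any(diff(object@counts) > 0))
    msg <- c(msg, "counts must be non-increasing along the ranking")
  if (nc && any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CooccurrenceTable: per-ontology drug/B-term document frequencies
#'
#' @slot ontologyId id of the B-term source.
#' @slot counts named integer vector: for each drug label, the number of
#'   documents containing at least one B-term of this ontology and that drug.
#' @slot nDocsB number of documents with at least one B-term hit.
#' @slot nDocsBC number of documents with at least one B-term hit and at
#'   least one drug hit.
#' @slot nDocs corpus size the table was aggregated over.
#'
#' @seealso [aggregateCounts()], [rankDrugs()], [ratioBCoverB()]
#' @export
setClass("CooccurrenceTable",
  representation(
    ontologyId = "character",
    counts     = "integer",
    nDocsB     = "integer",
    nDocsBC    = "integer",
    nDocs      = "integer"
  )
)

setValidity("CooccurrenceTable", function(object) {
  msg <- character()
  if (length(object@counts) && is.null(names(object@counts)))
    msg <- c(msg, "counts must be named by drug label")
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@counts) && max(object@counts) > object@nDocsBC)
    msg <- c(msg, "no drug count may exceed nDocsBC")
  if (object@nDocsBC > object@nDocsB)
    msg <- c(msg, "nDocsBC must not exceed nDocsB")
  if (object@nDocsB > object@nDocs)
    msg <- c(msg, "nDocsB must not exceed the corpus size")
  if (length(msg)) msg else TRUE
})

#' ReferenceSet: a set of reference drug names
#'
#' The reference set R = \{r_1, ..., r_S\} of drugs recommended for the
#' indication under study (here: pooled published epilepsy treatment lists).
#' Membership tests downstream are case-insensitive on labels.
#'
#' @slot label short name of the set (e.g. `"lancet"` or a pooled union).
#' @slot items unique, non-empty drug names.
#'
#' @seealso [readReferenceSet()], [dseaCurve()], [priorityScore()]
#' @export
setClass("ReferenceSet",
  representation(label = "character", items = "character")
)

setValidity("ReferenceSet", function(object) {
  msg <- character()
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single string")
  if (anyDuplicated(tolower(object@items)))
    msg <- c(msg, "reference items must be unique (case-insensitively)")
  if (length(object@items) && any(!nzchar(trimws(object@items))))
    msg <- c(msg, "reference items must be non-empty")
  if (length(msg)) msg else TRUE
})

#' EnrichmentCurve: the DSEA running-sum score along a ranked list
#'
#' Holds the running scores x_1..x_N (x_0 = 0 is implicit), the per-position
#' increments, the cumulative match counts tau, and the curve maximum with
#' its (1-based, first-attaining) position k.
#'
#' @slot scores numeric running scores x_1..x_N.
#' @slot increments per-position increments (bonus or penalty terms).
#' @slot tau cumulative reference matches including the current position.
#' @slot isMatch logical; position-wise reference membership.
#' @slot maxScore the curve maximum over x_1..x_N.
#' @slot maxPosition smallest index attaining the maximum.
#' @slot convention `"corrected"` or `"verbatim"` (bonus-sign reading).
#' @slot N length of the ranked list.
#' @slot S size of the reference set.
#'
#' @seealso [dseaCurve()], [dseaMax()], [dseaProfile()]
#' @export
setClass("EnrichmentCurve",
  representation(
    scores      = "numeric",
    increments  = "numeric",
    tau         = "integer",
    isMatch     = "logical",
    maxScore    = "numeric",
    maxPosition = "integer",
    convention  = "character",
    N           = "integer",
    S           = "integer"
  )
)

setValidity("EnrichmentCurve", function(object) {
  msg <- character()
  n <- length(object@scores)
  if (length(object@increments) != n || length(object@tau) != n ||
      length(object@isMatch) != n)
    msg <- c(msg, "scores, increments, tau and isMatch must be parallel")
  if (n > 0L) {
    if (max(abs(object@scores - cumsum(object@increments))) > 1e-9)
      msg <- c(msg, "scores must equal the cumulative sum of increments")
    if (any(diff(object@tau) < 0L))
      msg <- c(msg, "tau must be non-decreasing")
    if (object@tau[n] > min(object@N, object@S))
      msg <- c(msg, "final tau may not exceed min(N, S)")
  }
  if (!object@convention %in% c("corrected", "verbatim"))
    msg <- c(msg, "convention must be \"corrected\" or \"verbatim\"")
  if (length(msg)) msg else TRUE
})

#' SimilarityGraph: shared-synonym similarity between ontology concepts
#'
#' Nodes are (source, concept) pairs over two or more term sources; an
#' undirected edge joins two concepts sharing at least one normalized
#' surface form. Connected components give implicit similarity classes
#' (two concepts may be implicitly similar through a third).
#'
#' @slot nodes data.frame with columns `source`, `conceptId`, `label`.
#' @slot edges data.frame with columns `from`, `to` (row indices into
#'   `nodes`) and `sharedForms` (pipe-joined witnessing forms).
#' @slot component integer vector, parallel to the rows of `nodes`, giving
#'   the connected-component membership.
#'
#' @seealso [conceptOverlap()], [exportMapping()]
#' @export
setClass("SimilarityGraph",
  representation(
    nodes     = "data.frame",
    edges     = "data.frame",
    component = "integer"
  )
)

setValidity("SimilarityGraph", function(object) {
  msg <- character()
  if (length(object@component) != nrow(object@nodes))
    msg <- c(msg, "component must be parallel to nodes")
  if (nrow(object@edges) &&
      !all(c("from", "to", "sharedForms") %in% names(object@edges)))
    msg <- c(msg, "edges must have columns from, to, sharedForms")
  if (length(msg)) msg else TRUE
})
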