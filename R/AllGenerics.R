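#' @rdname TermSource-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname TermSource-class
#' @export
setGeneric("sourceRole", function(x) standardGeneric("sourceRole"))

#' @rdname TermSource-class
#' @export
setGeneric("conceptIds", function(x) standardGeneric("conceptIds"))

#' @rdname TermSource-class
#' @export
setGeneric("conceptLabels", function(x) standardGeneric("conceptLabels"))

#' @rdname TermSource-class
#' @export
setGeneric("synonyms", function(x) standardGeneric("synonyms"))

#' @rdname TermSource-class
#' @export
setGeneric("nConcepts", function(x) standardGeneric("nConcepts"))

#' @rdname TermSource-class
#' @export
setGeneric("nSynonyms", function(x) standardGeneric("nSynonyms"))

#' @rdname TermDictionary-class
#' @export
setGeneric("dictEntries", function(x) standardGeneric("dictEntries"))

#' @rdname RankedDrugList-class
#' @export
setGeneric("drugs", function(x) standardGeneric("drugs"))

#' @rdname RankedDrugList-class
#' @export
setGeneric("drugCounts", function(x) standardGeneric("drugCounts"))

#' @rdname RankedDrugList-class
#' @export
setGeneric("ontologyId", function(x) standardGeneric("ontologyId"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("refItems", function(x) standardGeneric("refItems"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("refLabel", function(x) standardGeneric("refLabel"))

#' @rdname EnrichmentCurve-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname EnrichmentCurve-class
#' @export
setGeneric("increments", function(x) standardGeneric("increments"))

#' @rdname EnrichmentCurve-class
#' @export
setGeneric("matchCounts", function(x) standardGeneric("matchCounts"))

#' @rdname EnrichmentCurve-class
#' @export
setGeneric("maxScore", function(x) standardGeneric("maxScore"))

#' @rdname EnrichmentCurve-class
#' @export
setGeneric("maxPosition", function(x) standardGeneric("maxPosition"))

#' @rdname CooccurrenceTable-class
#' @export
setGeneric("cooccurrenceCounts", function(x) standardGeneric("cooccurrenceCounts"))

#' @rdname CooccurrenceTable-class
#' @export
setGeneric("nDocsB", function(x) standardGeneric("nDocsB"))

#' @rdname CooccurrenceTable-class
#' @export
setGeneric("nDocsBC", function(x) standardGeneric("nDocsBC"))

#' Percentage of B-term documents that also contain a drug name
#'
#' Computes 100 * nDocsBC / nDocsB, the share of documents containing at
#' least one B-term of an ontology that additionally contain at least one
#' drug name (C-term), reported to three decimals.
#'
#' @param x a [CooccurrenceTable-class] object, or the numerator
#'   (documents with B- and C-terms) as a single count.
#' @param ... further arguments; for the numeric method, `nB` (documents
#'   with B-terms) and optionally `digits` (default 3).
#' @return a single numeric percentage, rounded to `digits` decimals.
#' @examples
#' ratioBCoverB(43, 62)   # 69.355
#' @export
setGeneric("ratioBCoverB", function(x, ...) standardGeneric("ratioBCoverB"))
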