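#' Aggregate drug/B-term co-occurrence document frequencies
#'
#' Tallies, over the per-document presence summaries produced by
#' [annotateCorpus()], how many documents contain at least one B-term of
#' the given ontology together with each drug (document frequency: a drug
#' mentioned ten times in one document still counts once). The counts of
#' documents with B-terms (`nDocsB`) and with both B-terms and at least one
#' drug (`nDocsBC`) are tallied simultaneously.
#'
#' @param summaries the `summaries` data.frame from [annotateCorpus()]
#'   (columns `docId`, `bSources`, `drugs`; attribute `bSourceIds`).
#' @param ontologyId id of the B-term source to aggregate for; must be one
#'   of the dictionaries the summaries were produced with.
#' @return a [CooccurrenceTable-class].
#' @export
aggregateCounts <- function(summaries, ontologyId) {
  known <- attr(summaries, "bSourceIds")
  if (!is.null(known) && !ontologyId %in% known)
    stop("unknown ontology id '", ontologyId, "'; summaries cover: ",
         paste(known, collapse = ", "))
  hasB <- vapply(summaries$bSources, function(b) ontologyId %in% b,
                 logical(1))
  drugsPerDoc <- summaries$drugs[hasB]
  hasDrug <- lengths(drugsPerDoc) > 0L
  counts <- table(unlist(drugsPerDoc, use.names = FALSE))
  counts <- stats::setNames(as.integer(counts), names(counts))
  new("CooccurrenceTable", ontologyId = ontologyId, counts = counts,
      nDocsB = sum(hasB), nDocsBC = sum(hasDrug),
      nDocs = nrow(summaries))
}

#' Rank drugs by descending document frequency
#'
#' Orders the drugs of a co-occurrence table by descending document
#' frequency; ties are broken by ascending lexicographic drug label so the
#' ranking is deterministic regardless of input order.
#'
#' @param table a [CooccurrenceTable-class].
#' @return a [RankedDrugList-class].
#' @export
rankDrugs <- function(table) {
  stopifnot(is(table, "CooccurrenceTable"))
  validObject(table)
  counts <- table@counts
  labs <- names(counts) %||% character()
  ord <- order(-as.numeric(counts), labs, method = "radix")
  new("RankedDrugList", ontologyId = table@ontologyId,
      drugs = labs[ord], counts = as.numeric(counts[ord]))
}

#' @rdname ratioBCoverB
#' @export
setMethod("ratioBCoverB", "CooccurrenceTable", function(x, ...) {
  ratioBCoverB(as.numeric(x@nDocsBC), nB = as.numeric(x@nDocsB), ...)
})

#' @rdname ratioBCoverB
#' @param nB number of documents with B-terms (denominator).
#' @param digits decimals to report (default 3, as printed).
#' @export
setMethod("ratioBCoverB", "numeric", function(x, nB, digits = 3L, ...) {
  if (nB <= 0)
    stop("ratio undefined: no documents with B-terms (nDocsB = 0)")
  round(100 * x / nB, digits)
})

#' Write a ranked drug list as TSV
#'
#' Three columns: rank (1-based), drug label, document-frequency count
#' (`NA` for fused lists without counts).
#'
#' @param x a [RankedDrugList-class].
#' @param path output file; comment header lines carry the ontology id and
#'   any metadata attributes (e.g. fusion objective).
#' @return `path`, invisibly.
#' @export
writeRankedList <- function(x, path) {
  stopifnot(is(x, "RankedDrugList"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# ontologyId=%s", x@ontologyId), con)
  meta <- attributes(x)[setdiff(names(attributes(x)),
                                c("class", methods::slotNames(x)))]
  for (nm in names(meta))
    if (is.atomic(meta[[nm]]) && length(meta[[nm]]) == 1L)
      writeLines(sprintf("# %s=%s", nm, format(meta[[nm]])), con)
  n <- length(x@drugs)
  cnt <- if (length(x@counts)) x@counts else rep(NA_real_, n)
  utils::write.table(
    data.frame(rank = seq_len(n), drug = x@drugs, count = cnt),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked drug list written by [writeRankedList()]
#' @param path file to read.
#' @return a [RankedDrugList-class].
#' @export
readRankedList <- function(path) {
  lines <- readLines(path, n = 50L)
  nHdr <- sum(cumprod(startsWith(lines, "#")))
  ontologyId <- sub("^# ontologyId=", "", lines[1L])
  tab <- utils::read.delim(path, skip = nHdr, quote = "",
                           fileEncoding = "UTF-8",
                           colClasses = c(rank = "integer",
                                          drug = "character",
                                          count = "numeric"))
  counts <- if (all(is.na(tab$count))) numeric() else tab$count
  new("RankedDrugList", ontologyId = ontologyId, drugs = tab$drug,
      counts = counts)
}

## ---- accessors & show ------------------------------------------------

#' @rdname RankedDrugList-class
#' @export
setMethod("drugs", "RankedDrugList", function(x) x@drugs)
#' @rdname RankedDrugList-class
#' @export
setMethod("drugCounts", "RankedDrugList",
          function(x) if (length(x@counts)) stats::setNames(x@counts, x@drugs)
                      else x@counts)
#' @rdname RankedDrugList-class
#' @export
setMethod("ontologyId", "RankedDrugList", function(x) x@ontologyId)
#' @rdname RankedDrugList-class
#' @export
setMethod("length", "RankedDrugList", function(x) length(x@drugs))

#' @rdname CooccurrenceTable-class
#' @export
setMethod("cooccurrenceCounts", "CooccurrenceTable", function(x) x@counts)
#' @rdname CooccurrenceTable-class
#' @export
setMethod("nDocsB", "CooccurrenceTable", function(x) x@nDocsB)
#' @rdname CooccurrenceTable-class
#' @export
setMethod("nDocsBC", "CooccurrenceTable", function(x) x@nDocsBC)
#' @rdname CooccurrenceTable-class
#' @export
setMethod("ontologyId", "CooccurrenceTable", function(x) x@ontologyId)

setMethod("show", "CooccurrenceTable", function(object) {
  cat(sprintf(
    "CooccurrenceTable '%s': %d drugs; %d/%d docs with B-terms (%d also with drugs)\n",
    object@ontologyId, length(object@counts), object@nDocsB, object@nDocs,
    object@nDocsBC))
})

setMethod("show", "RankedDrugList", function(object) {
  cat(sprintf("RankedDrugList '%s': %d drugs\n", object@ontologyId,
              length(object@drugs)))
  n <- min(5L, length(object@drugs))
  if (n > 0L) {
    cnt <- if (length(object@counts)) object@counts[seq_len(n)]
           else rep(NA_real_, n)
    for (i in seq_len(n))
      cat(sprintf("  %2d. %s (%s)\n", i, object@drugs[i], format(cnt[i])))
    if (length(object@drugs) > n) cat("  ...\n")
  }
})
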