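## Dictionary-based NER producing stand-off annotations.
##
## Matching is at token granularity: a dictionary form matches a contiguous
## token subsequence of the document, case-insensitively, with a stemmed
## fallback when the dictionary was stem-expanded. Within one dictionary the
## leftmost-longest match wins and matches never overlap; across
## dictionaries overlaps are allowed (a drug name may sit inside a B-term
## span). Offsets are 0-based, half-open character positions into the
## concatenated title + abstract string.

# internal: hashed lookup of normform -> row indices of dict@entries
.dictIndex <- function(dict) {
  env <- new.env(hash = TRUE, parent = emptyenv(), size = max(
    64L, nrow(dict@entries)))
  nf <- dict@entries$normform
  for (i in seq_along(nf)) {
    key <- nf[i]
    env[[key]] <- c(env[[key]], i)
  }
  env
}

#' Annotate a single document with one or more dictionaries
#'
#' Scans the document's token sequence for dictionary matches and emits one
#' stand-off annotation per (matched span, concept, source dictionary).
#' Per dictionary the scan is leftmost-longest: at each token position the
#' longest matching span wins and scanning resumes after it, so annotations
#' from one dictionary never overlap. The annotation records the 0-based
#' character offset, the length in characters, the exact text slice, the
#' preferred label of the matched concept and the source dictionary.
#'
#' @param doc either a single string, or a list/1-row data.frame with
#'   fields `docId` (or `pmid`) and `text` (or `title`/`abstractText`,
#'   joined by a single space).
#' @param dicts a [TermDictionary-class] or list of them, built with a
#'   common normalization.
#' @param docId identifier used when `doc` is a plain string.
#' @return data.frame with columns `docId`, `offset`, `length`,
#'   `matchedText`, `conceptLabel`, `sourceId`, sorted by offset.
#' @examples
#' d <- buildDictionary(TermSource("drugs", "d1", "Ketamine", role = "C"))
#' b <- buildDictionary(TermSource("epi", "b1", "seizure"))
#' annotateDocument("Ketamine reduced seizure frequency", list(d, b))
#' @export
annotateDocument <- function(doc, dicts, docId = "doc1") {
  rec <- .asDocumentRecord(doc, docId)
  if (is(dicts, "TermDictionary")) dicts <- list(dicts)
  idx <- lapply(dicts, .dictIndex)
  out <- .annotateText(rec$docId, rec$text, dicts, idx)
  out[order(out$offset, out$sourceId, out$conceptLabel), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

.asDocumentRecord <- function(doc, docId = "doc1") {
  if (is.character(doc) && length(doc) == 1L)
    return(list(docId = docId, text = doc))
  if (is.data.frame(doc)) doc <- as.list(doc[1L, , drop = FALSE])
  id <- doc$docId %||% doc$pmid %||% docId
  text <- doc$text
  if (is.null(text)) {
    title <- doc$title %||% ""
    abstract <- doc$abstractText %||% doc$abstract %||% ""
    if (is.na(title)) title <- ""
    if (is.na(abstract)) abstract <- ""
    text <- if (nzchar(title) && nzchar(abstract))
      paste(title, abstract) else paste0(title, abstract)
  }
  list(docId = as.character(id), text = as.character(text))
}

.emptyAnnotations <- function() {
  data.frame(docId = character(), offset = integer(), length = integer(),
             matchedText = character(), conceptLabel = character(),
             sourceId = character(), stringsAsFactors = FALSE)
}

.annotateText <- function(docId, text, dicts, idx) {
  toks <- tokenizeText(text)
  nt <- nrow(toks)
  if (nt == 0L) return(.emptyAnnotations())
  stems <- NULL
  anns <- list()
  for (k in seq_along(dicts)) {
    dict <- dicts[[k]]
    if (nrow(dict@entries) == 0L) next
    if (dict@stemmed && is.null(stems)) stems <- snowballStem(toks$token)
    env <- idx[[k]]
    i <- 1L
    while (i <= nt) {
      span <- 0L
      hit <- NULL
      for (L in rev(seq_len(min(dict@maxTokens, nt - i + 1L)))) {
        j <- i + L - 1L
        key <- paste(toks$token[i:j], collapse = " ")
        rows <- env[[key]]
        if (is.null(rows) && dict@stemmed) {
          skey <- paste(stems[i:j], collapse = " ")
          rows <- env[[skey]]
        }
        if (!is.null(rows)) {
          span <- L
          hit <- rows
          break
        }
      }
      if (span > 0L) {
        j <- i + span - 1L
        off <- toks$offset[i]
        len <- toks$offset[j] + toks$length[j] - off
        concepts <- unique(dict@entries[hit, c("conceptId", "label")])
        anns[[length(anns) + 1L]] <- data.frame(
          docId = docId, offset = off, length = len,
          matchedText = substr(text, off + 1L, off + len),
          conceptLabel = concepts$label, sourceId = dict@sourceId,
          stringsAsFactors = FALSE)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(anns)) return(.emptyAnnotations())
  do.call(rbind, anns)
}

#' Annotate a JSON-Lines corpus and summarize per-document presence
#'
#' Streams a citation corpus (one JSON object per line with fields `pmid`,
#' `title`, `abstractText`; missing abstracts tolerated), annotates each
#' document with all dictionaries, and produces one presence summary per
#' document: the set of B-source ids with at least one hit and the set of
#' distinct drug concept labels (from C-role dictionaries) with at least
#' one hit. Malformed records are skipped with a warning and counted.
#'
#' @param corpus path to a JSON-Lines file, or a data.frame/list of records
#'   with the same fields.
#' @param dicts list of [TermDictionary-class] objects.
#' @param annotationsFile optional path; annotations are streamed out as
#'   JSON-Lines (one object per annotation).
#' @param summaryFile optional path; summaries written as JSON-Lines.
#' @param chunkSize number of corpus lines read per batch when streaming.
#' @return a list with elements `summaries` (data.frame with columns
#'   `docId` and list-columns `bSources`, `drugs`; attribute `bSourceIds`
#'   holds all B-dictionary ids), `annotations` (stand-off annotation
#'   data.frame), `nDocs` and `nSkipped`.
#' @export
annotateCorpus <- function(corpus, dicts, annotationsFile = NULL,
                           summaryFile = NULL, chunkSize = 500L) {
  if (is(dicts, "TermDictionary")) dicts <- list(dicts)
  roles <- vapply(dicts, function(d) d@role, character(1))
  dictIds <- vapply(dicts, function(d) d@sourceId, character(1))
  idx <- lapply(dicts, .dictIndex)

  annCon <- if (!is.null(annotationsFile))
    file(annotationsFile, "w", encoding = "UTF-8") else NULL
  sumCon <- if (!is.null(summaryFile))
    file(summaryFile, "w", encoding = "UTF-8") else NULL
  on.exit({
    if (!is.null(annCon)) close(annCon)
    if (!is.null(sumCon)) close(sumCon)
  })

  allAnns <- list()
  sumId <- character()
  sumB <- list()
  sumDrugs <- list()
  nSkipped <- 0L

  processRecord <- function(rec) {
    rec2 <- tryCatch(.asDocumentRecord(rec, docId = NA_character_),
                     error = function(e) NULL)
    if (is.null(rec2) || is.null(rec2$docId) || is.na(rec2$docId) ||
        !nzchar(rec2$docId)) {
      nSkipped <<- nSkipped + 1L
      warning("skipping malformed corpus record", call. = FALSE)
      return(invisible())
    }
    ann <- .annotateText(rec2$docId, rec2$text, dicts, idx)
    ann <- ann[order(ann$offset, ann$sourceId, ann$conceptLabel), ,
               drop = FALSE]
    bHit <- sort(unique(ann$sourceId[ann$sourceId %in% dictIds[roles == "B"]]))
    drugHit <- sort(unique(ann$conceptLabel[
      ann$sourceId %in% dictIds[roles == "C"]]))
    sumId[length(sumId) + 1L] <<- rec2$docId
    sumB[[length(sumB) + 1L]] <<- bHit
    sumDrugs[[length(sumDrugs) + 1L]] <<- drugHit
    if (nrow(ann)) allAnns[[length(allAnns) + 1L]] <<- ann
    if (!is.null(annCon) && nrow(ann))
      writeLines(vapply(seq_len(nrow(ann)), function(r)
        as.character(jsonlite::toJSON(as.list(ann[r, ]),
                                      auto_unbox = TRUE)),
        character(1)), annCon)
    if (!is.null(sumCon))
      writeLines(as.character(jsonlite::toJSON(
        list(docId = rec2$docId, bSources = I(bHit), drugs = I(drugHit)),
        auto_unbox = TRUE)), sumCon)
    invisible()
  }

  if (is.character(corpus) && length(corpus) == 1L) {
    con <- file(corpus, "r", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    repeat {
      lines <- readLines(con, n = chunkSize)
      if (!length(lines)) break
      for (ln in lines) {
        if (!nzchar(trimws(ln))) next
        rec <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
        if (is.null(rec)) {
          nSkipped <- nSkipped + 1L
          warning("skipping malformed corpus line", call. = FALSE)
          next
        }
        processRecord(rec)
      }
    }
  } else if (is.data.frame(corpus)) {
    for (r in seq_len(nrow(corpus)))
      processRecord(as.list(corpus[r, , drop = FALSE]))
  } else {
    for (rec in corpus) processRecord(rec)
  }

  annotations <- if (length(allAnns)) do.call(rbind, allAnns)
                 else .emptyAnnotations()
  rownames(annotations) <- NULL
  summaries <- data.frame(docId = sumId, stringsAsFactors = FALSE)
  summaries$bSources <- sumB
  summaries$drugs <- sumDrugs
  attr(summaries, "bSourceIds") <- unname(dictIds[roles == "B"])
  list(summaries = summaries, annotations = annotations,
       nDocs = length(sumId), nSkipped = nSkipped)
}
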