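#' Construct a TermSource from vectors
#'
#' Low-level constructor used by the loaders and the synthetic-data
#' generators; validates invariants (unique non-empty ids, non-empty labels
#' and synonyms).
#'
#' @param sourceId short name of the source.
#' @param ids concept identifiers.
#' @param labels preferred labels, parallel to `ids`.
#' @param synonyms list of character vectors parallel to `ids`; a plain
#'   character vector is recycled as one synonym per concept; `NULL` means
#'   no synonyms.
#' @param role `"B"` (intermediate-term source) or `"C"` (drug vocabulary).
#' @return a [TermSource-class] object.
#' @export
TermSource <- function(sourceId, ids, labels, synonyms = NULL, role = "B") {
  if (is.null(synonyms)) synonyms <- rep(list(character()), length(ids))
  if (is.character(synonyms)) synonyms <- as.list(synonyms)
  synonyms <- lapply(synonyms, function(s) {
    s <- trimws(as.character(s))
    s[nzchar(s)]
  })
  new("TermSource", sourceId = as.character(sourceId), role = role,
      ids = as.character(ids), labels = trimws(as.character(labels)),
      synonyms = synonyms)
}

#' Load a term source from an OWL file or the tabular dialect
#'
#' Reads an ontology (or drug vocabulary) as a flat set of concepts with
#' preferred labels and synonyms. For OWL (RDF/XML), concept labels are
#' taken from `rdfs:label` and synonyms from the common synonym annotation
#' properties (`oboInOwl:hasExactSynonym` and relatives, `skos:altLabel`,
#' or any property whose local name contains "synonym"). The tabular
#' dialect is UTF-8 tab-separated with a required header and three columns:
#' concept id, preferred label, pipe-separated synonyms.
#'
#' @param path file to read.
#' @param format `"owl"` or `"tabular"` (`"tsv"` is accepted as an alias).
#' @param sourceId name of the source; defaults to the file name without
#'   extension.
#' @param role `"B"` or `"C"`.
#' @return a [TermSource-class]; the concept count and total synonym count
#'   (stored synonym strings, preferred labels excluded) are reported via
#'   `message()` and available through [nConcepts()] and [nSynonyms()].
#' @export
loadTermSource <- function(path, format = c("tabular", "owl", "tsv"),
                           sourceId = NULL, role = "B") {
  format <- match.arg(format)
  if (format == "tsv") format <- "tabular"
  if (!file.exists(path)) stop("cannot read term source file: ", path)
  if (is.null(sourceId)) sourceId <- sub("\\.[^.]*$", "", basename(path))
  src <- if (format == "owl") .loadOwlSource(path, sourceId, role)
         else .loadTabularSource(path, sourceId, role)
  if (nConcepts(src) == 0L)
    stop("term source '", sourceId, "' contains zero concepts")
  message(sprintf("term source '%s': %d concepts, %d synonyms",
                  sourceId, nConcepts(src), nSynonyms(src)))
  src
}

.loadTabularSource <- function(path, sourceId, role) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", colClasses = "character",
                           fileEncoding = "UTF-8")
  if (ncol(tab) < 3L)
    stop("tabular term source '", sourceId,
         "' must have three columns (id, label, synonyms)")
  syns <- lapply(tab[[3L]], function(s) {
    if (is.na(s) || !nzchar(s)) character()
    else strsplit(s, "|", fixed = TRUE)[[1]]
  })
  TermSource(sourceId, ids = tab[[1L]], labels = tab[[2L]],
             synonyms = syns, role = role)
}

.loadOwlSource <- function(path, sourceId, role) {
  doc <- xml2::read_xml(path)
  classes <- xml2::xml_find_all(
    doc, ".//*[local-name() = 'Class' or local-name() = 'Concept']")
  ids <- labels <- character()
  syns <- list()
  for (cl in classes) {
    about <- xml2::xml_attr(cl, "about")
    if (is.na(about) || !nzchar(about)) next
    kids <- xml2::xml_children(cl)
    knames <- xml2::xml_name(kids)
    lab <- trimws(xml2::xml_text(kids[knames == "label"]))
    lab <- lab[nzchar(lab)]
    if (!length(lab)) {
      frag <- sub("^.*[#/]", "", about)
      if (!nzchar(frag)) next
      lab <- gsub("_", " ", frag)
    }
    sy <- trimws(xml2::xml_text(
      kids[grepl("synonym|altlabel", knames, ignore.case = TRUE)]))
    sy <- unique(sy[nzchar(sy)])
    ids <- c(ids, about)
    labels <- c(labels, lab[1L])
    syns <- c(syns, list(sy))
  }
  TermSource(sourceId, ids = ids, labels = labels, synonyms = syns,
             role = role)
}

#' Write a term source in the tabular dialect
#'
#' Inverse of [loadTermSource()] for the tabular format: tab-separated,
#' UTF-8, header line `id  label  synonyms`, synonyms pipe-joined. A
#' written source reloads to identical concept and synonym multisets.
#'
#' @param source a [TermSource-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTermSource <- function(source, path) {
  stopifnot(is(source, "TermSource"))
  lines <- c("id\tlabel\tsynonyms",
             vapply(seq_along(source@ids), function(i) {
               paste(source@ids[i], source@labels[i],
                     paste(source@synonyms[[i]], collapse = "|"),
                     sep = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Compile a TermSource into a normalized lookup dictionary
#'
#' Every preferred label and synonym contributes an entry keyed by its
#' normalized form (case-folded, punctuation-split, whitespace-collapsed
#' token sequence; see [normalizeTerm()]). With `stem = TRUE`, the
#' token-wise Porter2-stemmed variant of each form is added as an
#' additional entry mapping to the same concept, so exact forms always
#' still match. A normalized form used by several concepts retains all of
#' them (multi-map).
#'
#' @param source a [TermSource-class].
#' @param stem add snowball-stemmed entries (default `FALSE`).
#' @return a [TermDictionary-class].
#' @examples
#' src <- TermSource("demo", "c1", "Seizures")
#' dictEntries(buildDictionary(src, stem = TRUE))
#' @export
buildDictionary <- function(source, stem = FALSE) {
  stopifnot(is(source, "TermSource"))
  validObject(source)
  n <- nConcepts(source)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    surfaces <- unique(c(source@labels[i], source@synonyms[[i]]))
    nf <- normalizeTerm(surfaces)
    keep <- nzchar(nf)
    df <- data.frame(normform = nf[keep], conceptId = source@ids[i],
                     label = source@labels[i], surface = surfaces[keep],
                     fromStem = FALSE, stringsAsFactors = FALSE)
    if (stem && nrow(df)) {
      sf <- normalizeTermStemmed(surfaces[keep])
      new <- sf != nf[keep]
      if (any(new))
        df <- rbind(df, data.frame(normform = sf[new],
                                   conceptId = source@ids[i],
                                   label = source@labels[i],
                                   surface = surfaces[keep][new],
                                   fromStem = TRUE,
                                   stringsAsFactors = FALSE))
    }
    rows[[i]] <- df
    if (nrow(df) == 0L)
      warning("concept '", source@ids[i],
              "' contributed no dictionary entry (no alphanumeric content)")
  }
  entries <- do.call(rbind, rows)
  entries <- entries[!duplicated(entries[c("normform", "conceptId")]), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  maxTokens <- if (nrow(entries))
    max(lengths(strsplit(entries$normform, " ", fixed = TRUE))) else 0L
  new("TermDictionary", sourceId = source@sourceId, role = source@role,
      stemmed = stem, entries = entries, maxTokens = as.integer(maxTokens))
}

#' Write / read a dictionary as a flat TSV
#'
#' Dictionaries are persisted as tab-separated entry tables with columns
#' `normform`, `conceptId`, `label`, `surface`, `fromStem`, preceded by
#' comment header lines (`# sourceId=...`, `# role=...`, `# stemmed=...`).
#'
#' @param dict a [TermDictionary-class].
#' @param path file to write or read.
#' @return `writeDictionary`: `path` invisibly; `readDictionary`: the
#'   [TermDictionary-class].
#' @export
writeDictionary <- function(dict, path) {
  stopifnot(is(dict, "TermDictionary"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# sourceId=%s", dict@sourceId),
               sprintf("# role=%s", dict@role),
               sprintf("# stemmed=%s", dict@stemmed)), con)
  utils::write.table(dict@entries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDictionary
#' @export
readDictionary <- function(path) {
  hdr <- readLines(path, n = 3L)
  meta <- sub("^# [a-zA-Z]+=", "", hdr)
  entries <- utils::read.delim(path, skip = 3L, colClasses = c(
    normform = "character", conceptId = "character", label = "character",
    surface = "character", fromStem = "logical"), quote = "",
    fileEncoding = "UTF-8")
  maxTokens <- if (nrow(entries))
    max(lengths(strsplit(entries$normform, " ", fixed = TRUE))) else 0L
  new("TermDictionary", sourceId = meta[1L], role = meta[2L],
      stemmed = as.logical(meta[3L]), entries = entries,
      maxTokens = as.integer(maxTokens))
}

## ---- accessors & show ------------------------------------------------

#' @rdname TermSource-class
#' @export
setMethod("sourceId", "TermSource", function(x) x@sourceId)
#' @rdname TermSource-class
#' @export
setMethod("sourceRole", "TermSource", function(x) x@role)
#' @rdname TermSource-class
#' @export
setMethod("conceptIds", "TermSource", function(x) x@ids)
#' @rdname TermSource-class
#' @export
setMethod("conceptLabels", "TermSource", function(x) x@labels)
#' @rdname TermSource-class
#' @export
setMethod("synonyms", "TermSource", function(x) x@synonyms)
#' @rdname TermSource-class
#' @export
setMethod("nConcepts", "TermSource", function(x) length(x@ids))
#' @rdname TermSource-class
#' @export
setMethod("nSynonyms", "TermSource",
          function(x) length(unlist(x@synonyms, use.names = FALSE)))

#' @rdname TermDictionary-class
#' @export
setMethod("dictEntries", "TermDictionary", function(x) x@entries)
#' @rdname TermDictionary-class
#' @export
setMethod("sourceId", "TermDictionary", function(x) x@sourceId)
#' @rdname TermDictionary-class
#' @export
setMethod("sourceRole", "TermDictionary", function(x) x@role)

setMethod("show", "TermSource", function(object) {
  cat(sprintf("TermSource '%s' (role %s): %d concepts, %d synonyms\n",
              object@sourceId, object@role, nConcepts(object),
              nSynonyms(object)))
})

setMethod("show", "TermDictionary", function(object) {
  cat(sprintf(
    "TermDictionary '%s' (role %s%s): %d entries over %d concepts\n",
    object@sourceId, object@role,
    if (object@stemmed) ", stem-expanded" else "",
    nrow(object@entries), length(unique(object@entries$conceptId))))
})
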