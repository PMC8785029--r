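#' Read an ATC code map
#'
#' Tab-separated, two columns with header: drug label and comma-separated
#' ATC codes. Codes must match the ATC pattern (letter, two digits, letter,
#' letter, two digits) truncatable at any classification level, e.g. `N`,
#' `N03`, `N03A`, `N03AB`, `N03AB02`.
#'
#' @param path file to read.
#' @return named list mapping drug label to a character vector of codes.
#' @export
readAtcMap <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(tab) < 2L)
    stop("ATC map must have two columns (drug, comma-separated codes)")
  codes <- lapply(tab[[2L]], function(s) {
    cs <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    cs[nzchar(cs)]
  })
  atc <- stats::setNames(codes, tab[[1L]])
  validateAtcMap(atc)
}

#' @rdname readAtcMap
#' @param atc a named list (drug label to ATC code vector) to validate.
#' @export
validateAtcMap <- function(atc) {
  pat <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"
  bad <- unlist(lapply(atc, function(cs) cs[!grepl(pat, cs)]),
                use.names = FALSE)
  if (length(bad))
    stop("invalid ATC codes: ", paste(unique(bad), collapse = ", "))
  atc
}

# case-insensitive lookup: codes for one drug label, character() if absent
.atcLookup <- function(drug, atc) {
  hit <- match(tolower(drug), tolower(names(atc)))
  if (is.na(hit)) character() else atc[[hit]]
}

#' Filter a ranked list to drugs in an ATC class
#'
#' Retains, in original order, exactly the drugs carrying at least one ATC
#' code starting with `prefix` (default `"N"`, the nervous-system class;
#' `"N03"` restricts to antiepileptics). Drug-to-code matching is
#' case-insensitive on the drug label. Drugs absent from the map are
#' treated as non-matching; the number dropped for that reason is reported
#' via `message()` and attached as attribute `nUnmapped`.
#'
#' @param list a [RankedDrugList-class].
#' @param atc named list from [readAtcMap()].
#' @param prefix non-empty ATC code prefix.
#' @return the filtered [RankedDrugList-class].
#' @export
filterATC <- function(list, atc, prefix = "N") {
  stopifnot(is(list, "RankedDrugList"), nzchar(prefix))
  codes <- lapply(list@drugs, .atcLookup, atc = atc)
  unmapped <- lengths(codes) == 0L
  keep <- vapply(codes, function(cs) any(startsWith(cs, prefix)), logical(1))
  if (any(unmapped))
    message(sum(unmapped), " drug(s) absent from the ATC map were dropped")
  out <- new("RankedDrugList", ontologyId = list@ontologyId,
             drugs = list@drugs[keep],
             counts = if (length(list@counts)) list@counts[keep]
                      else numeric())
  attr(out, "nUnmapped") <- sum(unmapped)
  out
}

#' Priority score of a drug against reference lists and ATC class N03
#'
#' One point per reference list containing the drug (case-insensitive
#' label match) plus one point if any of the drug's ATC codes starts with
#' `"N03"` (antiepileptics). With the four published reference lists the
#' optimal score is 5: present in all four lists and carrying an N03 code.
#'
#' @param drug drug label.
#' @param refsets list of [ReferenceSet-class] objects (typically four).
#' @param atc named list from [readAtcMap()].
#' @return integer score between 0 and `length(refsets) + 1`.
#' @examples
#' refs <- lapply(c("a", "b"), function(l) ReferenceSet(l, "Phenobarbital"))
#' priorityScore("Phenobarbital", refs, list(Phenobarbital = "N03AA02"))
#' @export
priorityScore <- function(drug, refsets, atc) {
  inRef <- vapply(refsets, function(rs) {
    tolower(drug) %in% tolower(refItems(rs))
  }, logical(1))
  isN03 <- any(startsWith(.atcLookup(drug, atc), "N03"))
  as.integer(sum(inRef) + isN03)
}

#' Build the final prioritized drug table
#'
#' One record per drug of the final combined ranked list, in final order,
#' carrying the rank, the additive priority score, per-reference-list
#' membership flags, the ATC-N03 flag, and the set of ontologies whose
#' ranked lists contain the drug. The free relation-type annotation
#' (T/P/R/S) is a pass-through column, never computed.
#'
#' @param final the combined [RankedDrugList-class].
#' @param perOntology named list of per-ontology [RankedDrugList-class]
#'   objects.
#' @param refsets named list of [ReferenceSet-class] objects; names become
#'   membership columns `in_<name>`.
#' @param atc named list from [readAtcMap()].
#' @param relationType optional named character vector (drug to T/P/R/S
#'   annotation) merged in as-is.
#' @return data.frame with columns `rank`, `drug`, `priority`, one
#'   `in_<refset>` logical per reference list, `is_n03`, `ontology_hits`
#'   (comma-joined), `relation_type`.
#' @export
buildFinalTable <- function(final, perOntology, refsets, atc,
                            relationType = NULL) {
  stopifnot(is(final, "RankedDrugList"))
  n <- length(final@drugs)
  out <- data.frame(rank = seq_len(n), drug = final@drugs,
                    stringsAsFactors = FALSE)
  out$priority <- vapply(final@drugs, priorityScore, integer(1),
                         refsets = refsets, atc = atc, USE.NAMES = FALSE)
  for (nm in names(refsets)) {
    items <- tolower(refItems(refsets[[nm]]))
    out[[paste0("in_", nm)]] <- tolower(final@drugs) %in% items
  }
  out$is_n03 <- vapply(final@drugs, function(d)
    any(startsWith(.atcLookup(d, atc), "N03")), logical(1),
    USE.NAMES = FALSE)
  out$ontology_hits <- vapply(final@drugs, function(d) {
    hits <- names(perOntology)[vapply(perOntology, function(l)
      tolower(d) %in% tolower(l@drugs), logical(1))]
    paste(hits, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  out$relation_type <- if (is.null(relationType)) rep(NA_character_, n)
                       else unname(relationType[out$drug])
  out
}

#' Read a reference drug list from plain text
#'
#' One drug name per line; blank lines and `#` comments are ignored.
#'
#' @param path file to read.
#' @param label set label; defaults to the file name without extension.
#' @return a [ReferenceSet-class].
#' @export
readReferenceSet <- function(path, label = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ReferenceSet(label, unique(lines))
}

#' Construct a ReferenceSet
#' @param label set label.
#' @param items drug names (made unique).
#' @return a [ReferenceSet-class].
#' @export
ReferenceSet <- function(label, items) {
  items <- trimws(as.character(items))
  new("ReferenceSet", label = as.character(label),
      items = items[!duplicated(tolower(items))])
}

#' Pool several reference sets into their union
#' @param refsets list of [ReferenceSet-class] objects.
#' @param label label of the pooled set.
#' @return a [ReferenceSet-class] holding the case-insensitive union.
#' @export
unionReferenceSets <- function(refsets, label = "union") {
  ReferenceSet(label, unlist(lapply(refsets, refItems), use.names = FALSE))
}

#' @rdname ReferenceSet-class
#' @export
setMethod("refItems", "ReferenceSet", function(x) x@items)
#' @rdname ReferenceSet-class
#' @export
setMethod("refLabel", "ReferenceSet", function(x) x@label)
#' @rdname ReferenceSet-class
#' @export
setMethod("length", "ReferenceSet", function(x) length(x@items))

setMethod("show", "ReferenceSet", function(object) {
  cat(sprintf("ReferenceSet '%s': %d drugs\n", object@label,
              length(object@items)))
})
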