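#' Tokenize text into maximal alphanumeric runs with character offsets
#'
#' Splits a string into tokens (maximal runs of alphanumeric characters),
#' recording for each token its 0-based character offset and length in the
#' original string. Tokens are returned case-folded; offsets always index
#' the original, unmodified string. Punctuation and whitespace separate
#' tokens and are never part of one.
#'
#' @param text a single string (may be empty or `NA`; both yield zero rows).
#' @return data.frame with columns `token` (lower-cased surface), `offset`
#'   (0-based start) and `length` (in characters).
#' @examples
#' tokenizeText("Ketamine, 5 mg")
#' @export
tokenizeText <- function(text) {
  stopifnot(length(text) == 1L)
  empty <- data.frame(token = character(), offset = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1L) return(empty)
  len <- attr(m, "match.length")
  data.frame(
    token  = tolower(regmatches(text, list(m))[[1]]),
    offset = as.integer(m) - 1L,
    length = as.integer(len),
    stringsAsFactors = FALSE
  )
}

#' Normalize a surface form for dictionary lookup
#'
#' Case-folds, trims, collapses internal whitespace and splits on
#' punctuation, returning the token sequence joined by single spaces.
#' Normalization is idempotent: applying it to an already-normalized form
#' is a no-op.
#'
#' @param x character vector of surface forms.
#' @return character vector of normalized forms ("" for forms with no
#'   alphanumeric content).
#' @examples
#' normalizeTerm(c("  Status   Epilepticus ", "petit-mal"))
#' @export
normalizeTerm <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s)) return(NA_character_)
    paste(tokenizeText(s)$token, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Normalize and additionally stem each token (used for stem-expanded
# dictionary entries and the annotator's stemmed fallback lookup).
normalizeTermStemmed <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s)) return(NA_character_)
    paste(snowballStem(tokenizeText(s)$token), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
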