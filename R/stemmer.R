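## Porter2 ("English Snowball") stemmer, implemented from the published
## algorithm definition: exception lists, prelude (consonant-y marking),
## R1/R2 region marking (with the gener-/commun-/arsen- special cases),
## steps 0, 1a, 1b, 1c, 2, 3, 4, 5, postlude. Region offsets are fixed once
## after the prelude; all later suffix edits happen at the right end of the
## word, so "suffix lies in R1/R2" reduces to comparing the suffix start
## position against the stored offset, as in the reference implementation.

.p2_vowels <- c("a", "e", "i", "o", "u", "y")
.p2_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
.p2_li_valid <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

.p2_exception1 <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

.p2_exception2 <- c("inning", "outing", "canning", "herring", "earring",
                    "proceed", "exceed", "succeed")

.p2_is_vowel <- function(ch) ch %in% .p2_vowels

# does `word` end in a short syllable?
.p2_ends_shortv <- function(chars) {
  n <- length(chars)
  if (n == 2L)
    return(.p2_is_vowel(chars[1L]) && !.p2_is_vowel(chars[2L]))
  if (n >= 3L)
    return(!.p2_is_vowel(chars[n - 2L]) &&
           .p2_is_vowel(chars[n - 1L]) &&
           !.p2_is_vowel(chars[n]) && !chars[n] %in% c("w", "x", "Y"))
  FALSE
}

# start offsets (1-based position of the first character) of R1 and R2;
# positions past length(chars) denote an empty region
.p2_regions <- function(chars) {
  word <- paste(chars, collapse = "")
  n <- length(chars)
  r1 <- n + 1L
  pre <- c("gener", "commun", "arsen")
  hit <- pre[startsWith(word, pre)]
  if (length(hit)) {
    r1 <- nchar(hit[1L]) + 1L
  } else {
    i <- 1L
    while (i < n) {
      if (.p2_is_vowel(chars[i]) && !.p2_is_vowel(chars[i + 1L])) {
        r1 <- i + 2L
        break
      }
      i <- i + 1L
    }
  }
  r2 <- n + 1L
  i <- r1
  while (i < n) {
    if (.p2_is_vowel(chars[i]) && !.p2_is_vowel(chars[i + 1L])) {
      r2 <- i + 2L
      break
    }
    i <- i + 1L
  }
  c(r1 = r1, r2 = r2)
}

# longest suffix of `word` among `sufs`; "" when none matches
.p2_longest_suffix <- function(word, sufs) {
  sufs <- sufs[order(-nchar(sufs))]
  for (s in sufs) if (endsWith(word, s)) return(s)
  ""
}

.p2_stem_one <- function(word) {
  if (is.na(word)) return(NA_character_)
  if (startsWith(word, "'")) word <- substring(word, 2L)
  ex <- .p2_exception1[word]
  if (!is.na(ex)) return(unname(ex))
  if (nchar(word) <= 2L) return(word)

  ## prelude: mark consonant y as Y
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  if (chars[1L] == "y") chars[1L] <- "Y"
  if (length(chars) > 1L) {
    for (i in 2:length(chars))
      if (chars[i] == "y" && .p2_is_vowel(chars[i - 1L])) chars[i] <- "Y"
  }
  reg <- .p2_regions(chars)
  r1 <- reg[["r1"]]; r2 <- reg[["r2"]]
  w <- paste(chars, collapse = "")

  in_r1 <- function(start) start >= r1
  in_r2 <- function(start) start >= r2
  chop <- function(w, k) substr(w, 1L, nchar(w) - k)

  ## step 0: longest of 's'  's  '
  s0 <- .p2_longest_suffix(w, c("'s'", "'s", "'"))
  if (nzchar(s0)) w <- chop(w, nchar(s0))

  ## step 1a
  s1a <- .p2_longest_suffix(w, c("sses", "ied", "ies", "us", "ss", "s"))
  if (s1a == "sses") {
    w <- paste0(chop(w, 4L), "ss")
  } else if (s1a %in% c("ied", "ies")) {
    w <- if (nchar(w) - 3L > 1L) paste0(chop(w, 3L), "i")
         else paste0(chop(w, 3L), "ie")
  } else if (s1a == "s") {
    body <- strsplit(chop(w, 1L), "", fixed = TRUE)[[1]]
    if (length(body) >= 2L && any(.p2_is_vowel(body[seq_len(length(body) - 1L)])))
      w <- chop(w, 1L)
  } # "us"/"ss": leave

  if (w %in% .p2_exception2) return(w)

  ## step 1b
  s1b <- .p2_longest_suffix(w, c("eedly", "ingly", "edly", "eed", "ing", "ed"))
  if (s1b %in% c("eed", "eedly")) {
    if (in_r1(nchar(w) - nchar(s1b) + 1L))
      w <- paste0(chop(w, nchar(s1b)), "ee")
  } else if (nzchar(s1b)) {
    body <- strsplit(chop(w, nchar(s1b)), "", fixed = TRUE)[[1]]
    if (any(.p2_is_vowel(body))) {
      w <- chop(w, nchar(s1b))
      if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
        w <- paste0(w, "e")
      } else if (substr(w, nchar(w) - 1L, nchar(w)) %in% .p2_doubles) {
        w <- chop(w, 1L)
      } else if (r1 > nchar(w) &&
                 .p2_ends_shortv(strsplit(w, "", fixed = TRUE)[[1]])) {
        w <- paste0(w, "e")
      }
    }
  }

  ## step 1c: y/Y -> i when preceded by a non-vowel that is not the first letter
  n <- nchar(w)
  if (n >= 3L && substr(w, n, n) %in% c("y", "Y") &&
      !.p2_is_vowel(substr(w, n - 1L, n - 1L)))
    w <- paste0(chop(w, 1L), "i")

  ## step 2 (longest matching suffix; act only if it lies in R1)
  step2 <- c(
    ization = "ize",ational = "ate", fulness = "ful", ousness = "ous",
    iveness = "ive", tional = "tion", biliti = "ble", lessli = "less",
    entli = "ent", ation = "ate", alism = "al", aliti = "al",
    ousli = "ous", iviti = "ive", fulli = "ful", enci = "ence",
    anci = "ance", abli = "able", izer = "ize", ator = "ate",
    alli = "al", bli = "ble", ogi = "og", li = ""
  )
  s2 <- .p2_longest_suffix(w, names(step2))
  if (nzchar(s2)) {
    start <- nchar(w) - nchar(s2) + 1L
    if (in_r1(start)) {
      prev <- if (start > 1L) substr(w, start - 1L, start - 1L) else ""
      ok <- if (s2 == "ogi") prev == "l"
            else if (s2 == "li") prev %in% .p2_li_valid
            else TRUE
      if (ok) w <- paste0(substr(w, 1L, start - 1L), step2[[s2]])
    }
  }

  ## step 3
  step3 <- c(ational = "ate", tional = "tion", alize = "al", icate = "ic",
             iciti = "ic", ative = "", ical = "ic", ness = "", ful = "")
  s3 <- .p2_longest_suffix(w, names(step3))
  if (nzchar(s3)) {
    start <- nchar(w) - nchar(s3) + 1L
    if (in_r1(start) && (s3 != "ative" || in_r2(start)))
      w <- paste0(substr(w, 1L, start - 1L), step3[[s3]])
  }

  ## step 4 (delete in R2; "ion" only after s or t)
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er", "ic")
  s4 <- .p2_longest_suffix(w, step4)
  if (nzchar(s4)) {
    start <- nchar(w) - nchar(s4) + 1L
    if (in_r2(start)) {
      prev <- if (start > 1L) substr(w, start - 1L, start - 1L) else ""
      if (s4 != "ion" || prev %in% c("s", "t"))
        w <- substr(w, 1L, start - 1L)
    }
  }

  ## step 5
  n <- nchar(w)
  last <- substr(w, n, n)
  if (last == "e") {
    body <- strsplit(chop(w, 1L), "", fixed = TRUE)[[1]]
    if (in_r2(n) || (in_r1(n) && !.p2_ends_shortv(body)))
      w <- chop(w, 1L)
  } else if (last == "l") {
    if (in_r2(n) && n > 1L && substr(w, n - 1L, n - 1L) == "l")
      w <- chop(w, 1L)
  }

  gsub("Y", "y", w, fixed = TRUE)
}

#' Stem English words with the Porter2 (snowball) algorithm
#'
#' Reduces inflected English word forms to a common stem, e.g. `"seizures"`
#' and `"seizure"` both map to `"seizur"`. Used to stem-expand dictionary
#' entries so that morphological variants of ontology terms still match in
#' text. Input is expected in lower case (dictionary normalization
#' case-folds first); words of two letters or fewer are returned unchanged.
#'
#' @param words character vector of (lower-case) words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' snowballStem(c("seizures", "running", "epilepsies"))
#' @export
snowballStem <- function(words) {
  vapply(as.character(words), .p2_stem_one, character(1), USE.NAMES = FALSE)
}
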