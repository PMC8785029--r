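#' Drug Set Enrichment Analysis running-sum curve
#'
#' Walks a ranked drug list D = (d_1, ..., d_N) against a reference set R
#' of S drugs and accumulates a running score: each position contributes a
#' bonus when d_i is in R (tested case-insensitively on labels) and a
#' penalty otherwise, with the cumulative match count tau_i (matches among
#' d_1..d_i, including the current element) adapting the step size — early
#' matches in a mostly-unmatched list step gently, late matches step hard,
#' so short reference sets are not drowned by long lists. The penalty term
#' is ln((N - tau_i) / (N + tau_i)), which is 0 while no match has been
#' seen and increasingly negative afterwards.
#'
#' Two bonus-sign conventions are provided. Under `"corrected"` (the
#' default) the bonus is ln((S + tau') / (S - tau')), positive for every
#' match, so curves rise at matches and fall at misses and the running
#' maximum sits at a match position. Under `"verbatim"` the bonus is
#' ln((S - tau') / (S + tau')), the literal published form, which is
#' negative; it is retained as a first-class option for comparison. In
#' both conventions tau' = min(tau_i, S - 1) inside the bonus term only,
#' keeping the score finite once all S reference drugs have been found.
#'
#' @param D a [RankedDrugList-class] or non-empty character vector.
#' @param R a [ReferenceSet-class] or character vector with at least one
#'   item.
#' @param convention `"corrected"` or `"verbatim"`.
#' @return an [EnrichmentCurve-class] with the running scores x_1..x_N
#'   (x_0 = 0 implicit), increments, cumulative match counts, and the
#'   maximum with its 1-based first-attaining position k.
#' @examples
#' d <- paste0("drug", 1:6)
#' dseaCurve(d, c("drug1", "drug2", "drug4", "other"))
#' @export
dseaCurve <- function(D, R, convention = c("corrected", "verbatim")) {
  convention <- match.arg(convention)
  drugs <- if (is(D, "RankedDrugList")) D@drugs else as.character(D)
  items <- if (is(R, "ReferenceSet")) R@items else as.character(R)
  items <- unique(items[!is.na(items)])
  N <- length(drugs)
  S <- length(items)
  if (N == 0L) stop("ranked list D must be non-empty")
  if (S == 0L) stop("reference set R must contain at least one item")

  isMatch <- tolower(drugs) %in% tolower(items)
  tau <- cumsum(isMatch)
  inc <- numeric(N)
  guarded <- FALSE
  for (i in seq_len(N)) {
    if (isMatch[i]) {
      tp <- min(tau[i], S - 1L)
      inc[i] <- if (convention == "corrected") log((S + tp) / (S - tp))
                else log((S - tp) / (S + tp))
    } else {
      if (N == tau[i]) {          # unreachable for valid tau; kept as guard
        inc[i] <- 0
        guarded <- TRUE
      } else {
        inc[i] <- log((N - tau[i]) / (N + tau[i]))
      }
    }
  }
  if (guarded)
    message("penalty guard hit (N == tau): increment set to 0")
  scores <- cumsum(inc)
  maxPos <- which.max(scores)
  new("EnrichmentCurve", scores = scores, increments = inc,
      tau = as.integer(tau), isMatch = isMatch,
      maxScore = scores[maxPos], maxPosition = as.integer(maxPos),
      convention = convention, N = as.integer(N), S = as.integer(S))
}

#' Maximum of an enrichment curve and its position
#'
#' @param curve an [EnrichmentCurve-class].
#' @return list with elements `score` (max over x_1..x_N) and `k` (the
#'   smallest 1-based index attaining it).
#' @export
dseaMax <- function(curve) {
  stopifnot(is(curve, "EnrichmentCurve"))
  validObject(curve)
  list(score = curve@maxScore, k = curve@maxPosition)
}

#' DSEA curves for several ranked lists against one reference set
#'
#' Applies [dseaCurve()] to each list and returns a long-format table of
#' scores suitable for plotting the enrichment profiles side by side,
#' together with a per-list maxima summary.
#'
#' @param lists named list of [RankedDrugList-class] objects (or character
#'   vectors); unnamed lists are named list1, list2, ...
#' @param R the reference set.
#' @param convention passed to [dseaCurve()].
#' @return list with `curves` (data.frame: list, position, drug, is_match,
#'   tau, increment, score) and `maxima` (data.frame: list, max_score, k).
#' @export
dseaProfile <- function(lists, R, convention = c("corrected", "verbatim")) {
  convention <- match.arg(convention)
  if (is.null(names(lists)))
    names(lists) <- paste0("list", seq_along(lists))
  curves <- lapply(names(lists), function(nm) {
    cv <- dseaCurve(lists[[nm]], R, convention)
    dr <- if (is(lists[[nm]], "RankedDrugList")) lists[[nm]]@drugs
          else as.character(lists[[nm]])
    data.frame(list = nm, position = seq_along(cv@scores), drug = dr,
               is_match = cv@isMatch, tau = cv@tau,
               increment = cv@increments, score = cv@scores,
               stringsAsFactors = FALSE)
  })
  maxima <- do.call(rbind, lapply(names(lists), function(nm) {
    cv <- dseaCurve(lists[[nm]], R, convention)
    data.frame(list = nm, max_score = cv@maxScore, k = cv@maxPosition,
               stringsAsFactors = FALSE)
  }))
  list(curves = do.call(rbind, curves), maxima = maxima)
}

## ---- accessors & show ------------------------------------------------

#' @rdname EnrichmentCurve-class
#' @export
setMethod("scores", "EnrichmentCurve", function(x) x@scores)
#' @rdname EnrichmentCurve-class
#' @export
setMethod("increments", "EnrichmentCurve", function(x) x@increments)
#' @rdname EnrichmentCurve-class
#' @export
setMethod("matchCounts", "EnrichmentCurve", function(x) x@tau)
#' @rdname EnrichmentCurve-class
#' @export
setMethod("maxScore", "EnrichmentCurve", function(x) x@maxScore)
#' @rdname EnrichmentCurve-class
#' @export
setMethod("maxPosition", "EnrichmentCurve", function(x) x@maxPosition)

setMethod("show", "EnrichmentCurve", function(object) {
  cat(sprintf(
    "EnrichmentCurve (%s): N = %d, S = %d, %d matches; max %.4f at k = %d\n",
    object@convention, object@N, object@S, sum(object@isMatch),
    object@maxScore, object@maxPosition))
})
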