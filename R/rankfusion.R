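## Top-k rank aggregation: combine per-ontology ranked drug lists into one
## final list minimizing the mean rank distance to the inputs, either by
## exhaustive enumeration (small unions) or by cross-entropy Monte Carlo
## (CEMC) optimization over orderings.

.asDrugVector <- function(x) {
  v <- if (is(x, "RankedDrugList")) x@drugs else as.character(x)
  if (anyDuplicated(v)) stop("duplicate items within one ranked list")
  v
}

# rank of each element of `space` in list `v`; absent items take rank
# length(v) + 1 (the standard missing-item convention for top-k lists)
.spaceRanks <- function(v, space) {
  r <- match(space, v)
  r[is.na(r)] <- length(v) + 1L
  r
}

#' Spearman footrule distance between two (top-k) ranked lists
#'
#' Sum over the items of `space` of the absolute rank difference, where an
#' item absent from a list of length l is assigned rank l + 1. Identical
#' lists have distance 0.
#'
#' @param a,b ranked lists ([RankedDrugList-class] or character vectors);
#'   duplicate items within one list are an error.
#' @param space item set to sum over; defaults to the union of `a` and `b`.
#' @return a single non-negative number.
#' @examples
#' footruleDistance(c("x", "y", "z"), c("z", "x", "y"))  # 4
#' @export
footruleDistance <- function(a, b, space = NULL) {
  a <- .asDrugVector(a); b <- .asDrugVector(b)
  if (is.null(space)) space <- union(a, b)
  sum(abs(.spaceRanks(a, space) - .spaceRanks(b, space)))
}

#' Kendall distance between two (top-k) ranked lists
#'
#' Number of item pairs ranked in opposite order by the two lists, with the
#' same missing-item convention as [footruleDistance()]; pairs tied in
#' either list contribute 0.
#'
#' @inheritParams footruleDistance
#' @return a single non-negative count.
#' @export
kendallDistance <- function(a, b, space = NULL) {
  a <- .asDrugVector(a); b <- .asDrugVector(b)
  if (is.null(space)) space <- union(a, b)
  ra <- .spaceRanks(a, space); rb <- .spaceRanks(b, space)
  da <- outer(ra, ra, "-"); db <- outer(rb, rb, "-")
  sum(da * db < 0) / 2
}

# all permutations of 1..n in lexicographic order (rows)
.permutations <- function(n) {
  if (n == 0L) return(matrix(integer(), 0L, 0L))
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)), deparse.level = 0L)
  }))
}

#' Combine ranked lists into one final top-k list
#'
#' Returns the ordering of k items from the union of the input lists that
#' minimizes the mean rank distance (Spearman footrule by default, Kendall
#' optionally) to the inputs. `method = "exhaustive"` enumerates all
#' orderings and is only permitted for unions of at most 8 items;
#' `method = "cemc"` runs a seeded cross-entropy Monte Carlo search over
#' orderings: permutations are sampled from a position-by-item probability
#' matrix which is iteratively tilted towards the elite (lowest-objective)
#' fraction of each sample, so the best objective found never increases
#' across iterations.
#'
#' @param lists list of [RankedDrugList-class] objects (or character
#'   vectors); a single list is returned as its own optimum.
#' @param k target length, or `"auto"`: the smallest k at which the
#'   per-item objective of the optimal full ordering stops improving by
#'   more than `tol`.
#' @param distance `"footrule"` or `"kendall"`.
#' @param method `"cemc"` or `"exhaustive"`.
#' @param seed integer seed for the Monte Carlo search (recorded in the
#'   output metadata; the caller's RNG state is preserved).
#' @param nSamples permutations sampled per CEMC iteration.
#' @param eliteFrac fraction of each sample used to update the sampling
#'   distribution.
#' @param maxIter maximum CEMC iterations.
#' @param tol convergence tolerance: CEMC stops after `patience`
#'   iterations without improvement beyond `tol`; also the threshold of
#'   the `"auto"` k rule.
#' @param patience CEMC iterations without improvement before stopping.
#' @return a [RankedDrugList-class] (ontologyId `"final"`, no counts) with
#'   attributes `objective` (the achieved mean distance), `k`, `distance`,
#'   `method` and `seed`.
#' @export
combineLists <- function(lists, k = "auto",
                         distance = c("footrule", "kendall"),
                         method = c("cemc", "exhaustive"), seed = 1L,
                         nSamples = 100L, eliteFrac = 0.1, maxIter = 100L,
                         tol = 1e-6, patience = 10L) {
  distance <- match.arg(distance)
  method <- match.arg(method)
  if (!length(lists)) stop("at least one input list is required")
  vecs <- lapply(lists, .asDrugVector)
  if (any(lengths(vecs) == 0L)) stop("input lists must be non-empty")
  space <- sort(unique(unlist(vecs, use.names = FALSE)))
  n <- length(space)
  B <- vapply(vecs, .spaceRanks, integer(n), space = space)
  B <- matrix(B, nrow = n)

  objective <- function(permIdx, kk) {
    rc <- rep.int(kk + 1L, n)
    rc[permIdx[seq_len(kk)]] <- seq_len(kk)
    if (distance == "footrule") {
      mean(colSums(abs(rc - B)))
    } else {
      mean(apply(B, 2L, function(rb) {
        da <- outer(rc, rc, "-"); db <- outer(rb, rb, "-")
        sum(da * db < 0) / 2
      }))
    }
  }

  if (!identical(k, "auto") && as.integer(k) > n)
    stop("k exceeds the union of input drugs (", n, " items)")
  if (length(vecs) == 1L) {
    kk <- if (identical(k, "auto")) n else as.integer(k)
    perm <- match(vecs[[1L]], space)
    out <- new("RankedDrugList", ontologyId = "final",
               drugs = vecs[[1L]][seq_len(kk)], counts = numeric())
    attr(out, "objective") <- objective(perm, kk)
    attr(out, "k") <- kk; attr(out, "distance") <- distance
    attr(out, "method") <- "identity"; attr(out, "seed") <- seed
    return(out)
  }

  kFixed <- if (identical(k, "auto")) n else {
    k <- as.integer(k)
    if (k > n) stop("k exceeds the union of input drugs (", n, " items)")
    k
  }

  bestPerm <- NULL
  if (method == "exhaustive") {
    if (n > 8L)
      stop("exhaustive enumeration is limited to unions of 8 items ",
           "(requested ", n, "); use method = \"cemc\"")
    perms <- .permutations(n)
    vals <- apply(perms, 1L, objective, kk = kFixed)
    bestPerm <- perms[which.min(vals), ]   # first = lexicographic smallest
    bestVal <- min(vals)
  } else {
    if (exists(".Random.seed", envir = .GlobalEnv)) {
      oldSeed <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", oldSeed, envir = .GlobalEnv),
              add = TRUE)
    }
    set.seed(as.integer(seed))
    P <- matrix(1 / n, n, n)            # position x item sampling weights
    nElite <- max(1L, ceiling(eliteFrac * nSamples))
    alpha <- 0.7
    bestVal <- Inf
    stale <- 0L
    trace <- numeric()
    samplePerm <- function() {
      perm <- integer(n)
      remaining <- seq_len(n)
      for (pos in seq_len(n)) {
        w <- P[pos, remaining]
        pick <- if (length(remaining) == 1L) remaining
                else remaining[sample.int(length(remaining), 1L,
                                          prob = w / sum(w))]
        perm[pos] <- pick
        remaining <- remaining[remaining != pick]
      }
      perm
    }
    for (iter in seq_len(maxIter)) {
      perms <- replicate(nSamples, samplePerm(), simplify = FALSE)
      if (!is.null(bestPerm)) perms[[1L]] <- bestPerm  # keep the incumbent
      vals <- vapply(perms, objective, numeric(1), kk = kFixed)
      ord <- order(vals)
      elite <- perms[ord[seq_len(nElite)]]
      if (vals[ord[1L]] < bestVal - tol) {
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (vals[ord[1L]] < bestVal) {
        bestVal <- vals[ord[1L]]
        bestPerm <- perms[[ord[1L]]]
      }
      freq <- matrix(0, n, n)
      for (p in elite)
        freq[cbind(seq_len(n), p)] <- freq[cbind(seq_len(n), p)] + 1
      P <- (1 - alpha) * P + alpha * freq / nElite
      trace[iter] <- bestVal
      if (stale >= patience) break
    }
  }

  if (identical(k, "auto")) {
    perItem <- vapply(seq_len(n), function(kk)
      objective(bestPerm, kk) / kk, numeric(1))
    kAuto <- n
    for (kk in seq_len(n - 1L)) {
      if (perItem[kk] - perItem[kk + 1L] <= tol) { kAuto <- kk; break }
    }
    kFixed <- kAuto
    bestVal <- objective(bestPerm, kFixed)
  }

  out <- new("RankedDrugList", ontologyId = "final",
             drugs = space[bestPerm[seq_len(kFixed)]], counts = numeric())
  attr(out, "objective") <- bestVal
  attr(out, "k") <- kFixed
  attr(out, "distance") <- distance
  attr(out, "method") <- method
  attr(out, "seed") <- as.integer(seed)
  if (method == "cemc") attr(out, "trace") <- trace
  out
}
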