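test_that("explicit edges induce implicit similarity in one component", {
  # b1 {s1, s2}, b2 {s1}, b3 {s2}: explicit b1-b2 and b1-b3, implicit b2~b3
  src1 <- TermSource("A", "b1", "conceptB1", list(c("s1", "s2")))
  src2 <- TermSource("B", c("b2", "b3"), c("conceptB2", "conceptB3"),
                     list("s1", "s2"))
  res <- conceptOverlap(list(src1, src2))
  g <- res$graph
  expect_equal(nrow(g@edges), 2L)
  key <- paste(g@nodes$conceptId[g@edges$from],
               g@nodes$conceptId[g@edges$to], sep = "-")
  expect_setequal(key, c("b1-b2", "b1-b3"))
  expect_equal(length(unique(g@component)), 1L)
})

test_that("two copies of a source are 100% shared in one spanning component", {
  src <- genTermSources(1L, 8L, 0)$sources[[1]]
  copy <- TermSource("copy", conceptIds(src), conceptLabels(src),
                     synonyms(src))
  res <- conceptOverlap(list(src, copy))
  expect_equal(res$report$perSource$shared_pct, c(100, 100))
  comps <- split(res$graph@nodes$source, res$graph@component)
  expect_true(all(vapply(comps, function(s)
    all(c(sourceId(src), "copy") %in% s), logical(1))))
})

test_that("disjoint sources share nothing", {
  gen <- genTermSources(3L, 10L, 0)
  res <- conceptOverlap(gen$sources)
  expect_true(all(res$report$perSource$shared == 0L))
  expect_true(all(res$report$pairwise == 0L))
  syn <- synonymOverlap(gen$sources)
  expect_true(all(syn$perSource$shared == 0L))
  expect_equal(syn$pooled$sharedForms, 0L)
})

test_that("planted shared fractions are reported exactly", {
  gen <- genTermSources(2L, 137L, 60 / 137)
  res <- conceptOverlap(gen$sources)
  expect_equal(res$report$perSource$shared, c(60L, 60L))
  expect_equal(res$report$perSource$shared_pct, c(43.796, 43.796))
  expect_equal(res$report$perSource$unshared_pct, c(56.204, 56.204))
  expect_equal(unname(res$report$pairwise[1, 2]), 60L)
})

test_that("shared + unshared = total for concepts and synonyms", {
  for (ov in c(0, 0.3, 1)) {
    gen <- genTermSources(3L, 12L, ov)
    cr <- conceptOverlap(gen$sources)$report$perSource
    expect_equal(cr$shared + cr$unshared, cr$total)
    sr <- synonymOverlap(gen$sources)$perSource
    expect_equal(sr$shared + sr$unshared, sr$total)
  }
})

test_that("matching equals the all-pairs brute-force oracle", {
  set.seed(19)
  for (rep in 1:5) {
    nShared <- sample(0:5, 1)
    gen <- genTermSources(sample(2:3, 1), sample(6:15, 1),
                          overlapFraction = nShared / 10)
    # perturb: give some concepts an extra cross-source synonym
    srcs <- gen$sources
    srcs[[1]]@synonyms[[1]] <- c(srcs[[1]]@synonyms[[1]],
                                 conceptLabels(srcs[[2]])[2])
    res <- conceptOverlap(srcs)
    oracle <- matrix(as.integer(bruteConceptPairs(srcs)), ncol = 2L)
    mine <- matrix(as.integer(as.matrix(res$graph@edges[c("from", "to")])),
                   ncol = 2L)
    expect_equal(mine[order(mine[, 1], mine[, 2]), , drop = FALSE],
                 oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE])
  }
})

test_that("reports are invariant to source order", {
  gen <- genTermSources(3L, 9L, 0.4)
  r1 <- conceptOverlap(gen$sources)$report
  r2 <- conceptOverlap(rev(gen$sources))$report
  p1 <- r1$perSource[order(r1$perSource$source), ]
  p2 <- r2$perSource[order(r2$perSource$source), ]
  rownames(p1) <- rownames(p2) <- NULL
  expect_equal(p1, p2)
  expect_equal(r1$pairwise[rownames(r1$pairwise), colnames(r1$pairwise)],
               r2$pairwise[rownames(r1$pairwise), colnames(r1$pairwise)])
  expect_equal(r1$pooled, r2$pooled)
})

test_that("every component is connected through shared-synonym edges", {
  gen <- genTermSources(3L, 10L, 0.5)
  g <- conceptOverlap(gen$sources)$graph
  # BFS over the edge list, independent of igraph
  n <- nrow(g@nodes)
  adj <- lapply(seq_len(n), function(i)
    c(g@edges$to[g@edges$from == i], g@edges$from[g@edges$to == i]))
  reach <- function(start) {
    seen <- logical(n); queue <- start; seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    which(seen)
  }
  for (comp in unique(g@component)) {
    members <- which(g@component == comp)
    expect_setequal(reach(members[1]), members)
  }
})

test_that("pooled synonym bookkeeping adds up", {
  s1 <- TermSource("w", "c1", "l1", list(c("alpha", "beta")))
  s2 <- TermSource("x", "c1", "l2", list(c("alpha", "gamma", "delta")))
  s3 <- TermSource("y", "c1", "l3", list("epsilon"))
  s4 <- TermSource("z", c("c1", "c2"), c("l4", "l5"),
                   list(c("beta", "gamma"), c("zeta", "eta")))
  rep4 <- synonymOverlap(list(s1, s2, s3, s4))
  expect_equal(rep4$pooled$total, 2L + 3L + 1L + 4L)
  expect_equal(rep4$pooled$uniqueForms, 7L)  # alpha beta gamma delta epsilon zeta eta
  expect_equal(rep4$pooled$sharedForms, 3L)  # alpha, beta, gamma
  expect_equal(rep4$pooled$singleSourceForms, 4L)
  expect_equal(rep4$pooled$uniqueForms,
               rep4$pooled$sharedForms + rep4$pooled$singleSourceForms)
  expect_equal(unname(rep4$pairwise["w", "x"]), 1L)  # alpha
  expect_equal(unname(rep4$pairwise["w", "z"]), 1L)  # beta
  ps <- rep4$perSource
  expect_equal(ps$shared[ps$source == "w"], 2L)      # alpha and beta
  expect_equal(ps$shared_pct[ps$source == "w"], 100)
})

test_that("document-set overlap counts Venn cells and coverage", {
  sets <- list(A = c("d1", "d2", "d3"), B = c("d2", "d3", "d4"),
               C = "d5")
  res <- docsetOverlap(sets, corpusSize = 10L)
  expect_equal(res$unionSize, 5L)
  expect_equal(res$coverage_pct, 50)
  expect_equal(unname(res$vennCells[["A&B"]]), 2L)
  expect_equal(unname(res$vennCells[["C"]]), 1L)
  expect_equal(sum(res$vennCells), res$unionSize)
  ps <- res$perSet
  expect_equal(ps$shared[ps$set == "A"], 2L)
  expect_equal(ps$shared_pct[ps$set == "C"], 0)
  # identical sets collapse to a single full cell
  res2 <- docsetOverlap(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(names(res2$vennCells), "X&Y")
  expect_equal(res2$perSet$shared_pct, c(100, 100))
  # beyond four sets only pairwise counts are emitted
  many <- setNames(rep(list("d1"), 5), paste0("s", 1:5))
  expect_message(res3 <- docsetOverlap(many), "pairwise")
  expect_length(res3$vennCells, 0L)
  expect_equal(unname(res3$pairwise["s1", "s2"]), 1L)
})

test_that("the exported mapping lists cross-source pairs with witnesses", {
  src1 <- TermSource("A", "a1", "left", list("shared form"))
  src2 <- TermSource("B", c("b1", "b2"), c("right", "other"),
                     list("shared form", character()))
  res <- conceptOverlap(list(src1, src2))
  f <- withr::local_tempfile(fileext = ".tsv")
  map <- exportMapping(res$graph, f)
  expect_equal(nrow(map), 1L)
  expect_equal(map$concept_a, "a1")
  expect_equal(map$concept_b, "b1")
  expect_equal(map$shared_synonyms, "shared form")
  expect_true(file.exists(f))
  back <- read.delim(f, colClasses = "character")
  expect_equal(back$concept_b, "b1")
})
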