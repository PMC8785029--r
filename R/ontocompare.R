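## Synonym-overlap comparison of term sources and document-set overlap
## statistics. Matching uses case-insensitive exact string equality after
## trimming (no stemming: stemmed matching would merge distinct terms and
## inflate the mapping).

# normalized matching forms of each concept of a source: label + synonyms
.matchForms <- function(source) {
  lapply(seq_len(nConcepts(source)), function(i) {
    f <- tolower(trimws(c(source@labels[i], source@synonyms[[i]])))
    unique(f[nzchar(f)])
  })
}

#' Percentage helper used throughout the overlap reports
#'
#' @param shared,total counts.
#' @param digits decimals to report (3 for concept/synonym shares, 2 for
#'   corpus coverage figures).
#' @return `round(100 * shared / total, digits)`.
#' @examples
#' overlapPercent(60, 137)            # 43.796
#' overlapPercent(14759054, 15501443, 2)  # 95.21
#' @export
overlapPercent <- function(shared, total, digits = 3L) {
  round(100 * shared / total, digits)
}

#' Shared-synonym concept overlap across term sources
#'
#' Two concepts match if their normalized surface-form sets (preferred
#' label plus synonyms; case-insensitive, trimmed) intersect. A concept is
#' "shared" if it matches a concept of another source. The similarity
#' graph records every matching pair; its connected components are the
#' implicit similarity classes (concepts b2 and b3 that both match b1 are
#' implicitly similar even without a direct shared synonym).
#'
#' @param sources list of at least two [TermSource-class] objects.
#' @param digits decimals for the reported percentages.
#' @return list with `graph` (a [SimilarityGraph-class]) and `report`:
#'   `perSource` (source, total, shared, unshared concept counts and
#'   percentages), `pairwise` (matrix; entry \[a, b\] counts concepts of a
#'   matching at least one concept of b), `vennCells` (named by
#'   `&`-joined source combinations; counts similarity classes spanning
#'   exactly that combination, up to 4 sources) and `pooled` (`total`
#'   concepts, `unique` similarity classes, `redundant` = total - unique,
#'   `unsharedTotal` concepts shared with no other source).
#' @export
conceptOverlap <- function(sources, digits = 3L) {
  stopifnot(length(sources) >= 2L)
  ids <- vapply(sources, sourceId, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  nodes <- do.call(rbind, lapply(seq_along(sources), function(s)
    data.frame(source = ids[s], conceptId = sources[[s]]@ids,
               label = sources[[s]]@labels, stringsAsFactors = FALSE)))
  forms <- unlist(lapply(sources, .matchForms), recursive = FALSE)

  ## inverted index: form -> node indices
  formTab <- data.frame(
    form = unlist(forms, use.names = FALSE),
    node = rep.int(seq_along(forms), lengths(forms)),
    stringsAsFactors = FALSE)
  byForm <- split(formTab$node, formTab$form)
  pairs <- list()
  for (f in names(byForm)) {
    nd <- byForm[[f]]
    if (length(nd) < 2L) next
    cmb <- utils::combn(sort(nd), 2L)
    pairs[[length(pairs) + 1L]] <- data.frame(
      from = cmb[1L, ], to = cmb[2L, ], form = f,
      stringsAsFactors = FALSE)
  }
  edges <- if (length(pairs)) {
    pr <- do.call(rbind, pairs)
    agg <- stats::aggregate(form ~ from + to, data = pr,
                            FUN = function(x)
                              paste(sort(unique(x)), collapse = "|"))
    names(agg)[3L] <- "sharedForms"
    agg[order(agg$from, agg$to), , drop = FALSE]
  } else {
    data.frame(from = integer(), to = integer(),
               sharedForms = character(), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to")],
    vertices = data.frame(name = seq_len(nrow(nodes))), directed = FALSE)
  comp <- igraph::components(g)$membership[as.character(seq_len(nrow(nodes)))]
  graph <- new("SimilarityGraph", nodes = nodes, edges = edges,
               component = as.integer(unname(comp)))

  ## per-source shared counts: matched to a concept of another source
  crossMate <- logical(nrow(nodes))
  if (nrow(edges)) {
    cross <- nodes$source[edges$from] != nodes$source[edges$to]
    crossMate[unique(c(edges$from[cross], edges$to[cross]))] <- TRUE
  }
  perSource <- do.call(rbind, lapply(ids, function(s) {
    sel <- nodes$source == s
    total <- sum(sel); shared <- sum(crossMate & sel)
    data.frame(source = s, total = total, shared = shared,
               unshared = total - shared,
               shared_pct = overlapPercent(shared, total, digits),
               unshared_pct = overlapPercent(total - shared, total, digits),
               stringsAsFactors = FALSE)
  }))
  pairwise <- matrix(0L, length(ids), length(ids),
                     dimnames = list(ids, ids))
  if (nrow(edges)) {
    both <- rbind(data.frame(a = edges$from, b = edges$to),
                  data.frame(a = edges$to, b = edges$from))
    both$sa <- nodes$source[both$a]; both$sb <- nodes$source[both$b]
    both <- both[both$sa != both$sb, , drop = FALSE]
    if (nrow(both)) {
      u <- unique(both[c("a", "sb")])
      t <- table(nodes$source[u$a], u$sb)
      pairwise[rownames(t), colnames(t)] <- t
    }
  }
  vennCells <- .componentVenn(nodes$source, graph@component, ids)
  pooled <- list(total = nrow(nodes),
                 unique = length(unique(graph@component)),
                 redundant = nrow(nodes) - length(unique(graph@component)),
                 unsharedTotal = sum(!crossMate))
  list(graph = graph,
       report = list(perSource = perSource, pairwise = pairwise,
                     vennCells = vennCells, pooled = pooled))
}

# Venn cell counts of similarity classes by the set of sources they span
.componentVenn <- function(nodeSource, component, ids) {
  if (length(ids) > 4L) return(stats::setNames(integer(), character()))
  span <- tapply(nodeSource, component, function(s)
    paste(sort(unique(s)), collapse = "&"))
  tab <- table(unlist(span))
  stats::setNames(as.integer(tab), names(tab))
}

#' Synonym-overlap report across term sources
#'
#' Pools the stored synonym strings of each source (preferred labels are
#' excluded, matching the dictionary bookkeeping) and reports, per source,
#' how many of its stored synonyms are also used by another source, plus
#' pooled totals: the number of distinct normalized forms, how many occur
#' in a single source only, and how many are shared by two or more
#' sources.
#'
#' @inheritParams conceptOverlap
#' @return list with `perSource` (source, total, shared, unshared and
#'   percentages), `pairwise` (distinct shared forms per source pair),
#'   `vennCells` (distinct forms by source combination, up to 4 sources)
#'   and `pooled` (`total` stored synonyms, `uniqueForms`, `sharedForms`
#'   in >= 2 sources, `singleSourceForms`).
#' @export
synonymOverlap <- function(sources, digits = 3L) {
  stopifnot(length(sources) >= 2L)
  ids <- vapply(sources, sourceId, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  stored <- lapply(sources, function(src)
    tolower(trimws(unlist(src@synonyms, use.names = FALSE))))
  stored <- lapply(stored, function(s) s[nzchar(s)])
  formsBySource <- lapply(stored, unique)
  allForms <- sort(unique(unlist(formsBySource, use.names = FALSE)))
  inSource <- matrix(FALSE, length(allForms), length(ids),
                     dimnames = list(allForms, ids))
  for (s in seq_along(ids))
    inSource[, s] <- allForms %in% formsBySource[[s]]
  nSources <- rowSums(inSource)

  perSource <- do.call(rbind, lapply(seq_along(ids), function(s) {
    shared <- sum(stored[[s]] %in% allForms[nSources >= 2L &
                                              inSource[, s]])
    total <- length(stored[[s]])
    data.frame(source = ids[s], total = total, shared = shared,
               unshared = total - shared,
               shared_pct = overlapPercent(shared, total, digits),
               unshared_pct = overlapPercent(total - shared, total, digits),
               stringsAsFactors = FALSE)
  }))
  pairwise <- matrix(0L, length(ids), length(ids),
                     dimnames = list(ids, ids))
  for (a in seq_along(ids)) for (b in seq_along(ids))
    if (a != b) pairwise[a, b] <- sum(inSource[, a] & inSource[, b])
  vennCells <- if (length(ids) <= 4L) {
    combo <- apply(inSource, 1L, function(r)
      paste(ids[r], collapse = "&"))
    tab <- table(combo)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())
  pooled <- list(total = sum(lengths(stored)),
                 uniqueForms = length(allForms),
                 sharedForms = sum(nSources >= 2L),
                 singleSourceForms = sum(nSources == 1L))
  list(perSource = perSource, pairwise = pairwise, vennCells = vennCells,
       pooled = pooled)
}

#' Document-set overlap statistics
#'
#' Compares the per-ontology document sets (e.g. documents containing at
#' least one B-term of each source ontology): Venn cell counts for up to
#' four named sets, the fraction of each set shared with at least one
#' other set, and the corpus coverage of the union. With more than four
#' sets only pairwise counts are emitted, as in the published quad Venn
#' figures.
#'
#' @param docIdSets named list of document-id vectors over a common corpus.
#' @param corpusSize optional corpus size for the coverage percentage.
#' @param digits decimals (default 2, as the coverage figures are printed).
#' @return list with `vennCells`, `perSet` (total, shared, shared_pct),
#'   `pairwise`, `unionSize` and `coverage_pct` (`NA` without
#'   `corpusSize`).
#' @export
docsetOverlap <- function(docIdSets, corpusSize = NULL, digits = 2L) {
  stopifnot(is.list(docIdSets), !is.null(names(docIdSets)))
  ids <- names(docIdSets)
  sets <- lapply(docIdSets, function(s) unique(as.character(s)))
  allDocs <- sort(unique(unlist(sets, use.names = FALSE)))
  inSet <- matrix(FALSE, length(allDocs), length(ids),
                  dimnames = list(allDocs, ids))
  for (s in seq_along(ids)) inSet[, s] <- allDocs %in% sets[[s]]
  nSets <- rowSums(inSet)
  vennCells <- if (length(ids) <= 4L) {
    combo <- apply(inSet, 1L, function(r) paste(ids[r], collapse = "&"))
    tab <- table(combo)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    message("more than 4 sets: Venn cells omitted, pairwise counts only")
    stats::setNames(integer(), character())
  }
  perSet <- do.call(rbind, lapply(seq_along(ids), function(s) {
    total <- sum(inSet[, s])
    shared <- sum(inSet[, s] & nSets >= 2L)
    data.frame(set = ids[s], total = total, shared = shared,
               shared_pct = overlapPercent(shared, total, digits),
               stringsAsFactors = FALSE)
  }))
  pairwise <- matrix(0L, length(ids), length(ids),
                     dimnames = list(ids, ids))
  for (a in seq_along(ids)) for (b in seq_along(ids))
    if (a != b) pairwise[a, b] <- sum(inSet[, a] & inSet[, b])
  list(vennCells = vennCells, perSet = perSet, pairwise = pairwise,
       unionSize = length(allDocs),
       coverage_pct = if (is.null(corpusSize)) NA_real_
                      else overlapPercent(length(allDocs), corpusSize,
                                          digits))
}

#' Export the concept-to-concept mapping of a similarity graph
#'
#' One row per matched concept pair with the witnessing shared synonyms
#' (pipe-joined). By default only cross-source pairs are exported — the
#' mapping between ontologies; set `crossOnly = FALSE` to include
#' within-source synonym reuse.
#'
#' @param graph a [SimilarityGraph-class] from [conceptOverlap()].
#' @param path optional TSV output file.
#' @param crossOnly drop within-source pairs (default `TRUE`).
#' @return data.frame with columns `source_a`, `concept_a`, `source_b`,
#'   `concept_b`, `shared_synonyms`; written to `path` when given.
#' @export
exportMapping <- function(graph, path = NULL, crossOnly = TRUE) {
  stopifnot(is(graph, "SimilarityGraph"))
  e <- graph@edges
  out <- data.frame(
    source_a = graph@nodes$source[e$from],
    concept_a = graph@nodes$conceptId[e$from],
    source_b = graph@nodes$source[e$to],
    concept_b = graph@nodes$conceptId[e$to],
    shared_synonyms = e$sharedForms,
    stringsAsFactors = FALSE)
  if (crossOnly) out <- out[out$source_a != out$source_b, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

setMethod("show", "SimilarityGraph", function(object) {
  cat(sprintf(
    "SimilarityGraph: %d concepts from %d sources, %d matching pairs, %d similarity classes\n",
    nrow(object@nodes), length(unique(object@nodes$source)),
    nrow(object@edges), length(unique(object@component))))
})
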