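#' Extract per-ontology document-id sets from annotation summaries
#'
#' @param summaries the `summaries` data.frame from [annotateCorpus()].
#' @param requireDrug additionally require at least one drug hit in the
#'   document (B- and C-term sets, as in the co-occurrence Venn figures).
#' @return named list of document-id vectors, one per B-term source.
#' @export
docsetsFromSummaries <- function(summaries, requireDrug = FALSE) {
  srcs <- attr(summaries, "bSourceIds") %||%
    sort(unique(unlist(summaries$bSources, use.names = FALSE)))
  hasDrug <- lengths(summaries$drugs) > 0L
  out <- lapply(srcs, function(s) {
    sel <- vapply(summaries$bSources, function(b) s %in% b, logical(1))
    if (requireDrug) sel <- sel & hasDrug
    summaries$docId[sel]
  })
  stats::setNames(out, srcs)
}

#' Run the full Open Discovery pipeline
#'
#' Orchestrates every stage over plain-file artifacts: dictionary
#' compilation, corpus annotation, per-ontology co-occurrence aggregation
#' and ranking, ATC filtering, rank fusion, priority scoring, DSEA
#' profiling and the ontology/document-set comparisons. All intermediate
#' TSV/JSON-Lines artifacts, a machine-readable run manifest (input
#' hashes, seed, per-stage counts) and the serialized configuration are
#' written to the output directory. Corpus processing is streaming and
#' single-pass with bounded per-document memory. Reruns with an identical
#' configuration and seed produce byte-identical artifacts.
#'
#' @param config a list (or JSON file path) with elements:
#'   \describe{
#'     \item{corpus}{path to the JSON-Lines citation corpus.}
#'     \item{termSources}{named list; each element either a
#'       [TermSource-class] or a list with `path` and `format`
#'       (`"tabular"`/`"owl"`).}
#'     \item{drugVocab}{drug vocabulary: a [TermSource-class] or a
#'       `path`/`format` list (role is forced to `"C"`).}
#'     \item{atcMap}{path to the ATC TSV or a named list of code vectors.}
#'     \item{refLists}{named list of reference-list paths or
#'       [ReferenceSet-class] objects.}
#'     \item{stem}{stem-expand dictionaries (default `TRUE`).}
#'     \item{atcPrefix}{ATC filter prefix (default `"N"`).}
#'     \item{fusion}{list of [combineLists()] arguments (`k`, `distance`,
#'       `method`, `nSamples`, ...).}
#'     \item{dseaConvention}{`"corrected"` (default) or `"verbatim"`.}
#'     \item{outDir}{output directory (created if missing).}
#'     \item{seed}{integer seed for the stochastic stages.}
#'   }
#' @return the run manifest, invisibly; side effect: artifacts under
#'   `outDir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  outDir <- config$outDir %||% stop("config$outDir is required")
  seed <- as.integer(config$seed %||% 1L)
  stem <- isTRUE(config$stem %||% TRUE)
  atcPrefix <- config$atcPrefix %||% "N"
  convention <- config$dseaConvention %||% "corrected"
  fusion <- config$fusion %||% list()
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(seed = seed, stages = list())
  inputHash <- function(p)
    if (is.character(p) && file.exists(p))
      unname(tools::md5sum(p)) else NA_character_

  .asSource <- function(x, nm, role) {
    if (is(x, "TermSource")) return(x)
    loadTermSource(x$path, format = x$format %||% "tabular",
                   sourceId = nm, role = role)
  }

  ## 1. term sources and dictionaries
  bSources <- stage("load-sources", {
    lapply(stats::setNames(names(config$termSources),
                           names(config$termSources)),
           function(nm) .asSource(config$termSources[[nm]], nm, "B"))
  })
  drugSource <- stage("load-drug-vocab", {
    src <- .asSource(config$drugVocab, "drugs", "C")
    src@role <- "C"
    src
  })
  dicts <- stage("build-dict", {
    d <- lapply(c(bSources, list(drugs = drugSource)), buildDictionary,
                stem = stem)
    dictDir <- file.path(outDir, "dicts")
    dir.create(dictDir, showWarnings = FALSE)
    for (dd in d)
      writeDictionary(dd, file.path(dictDir, paste0(dd@sourceId, ".tsv")))
    d
  })

  ## 2. annotation
  ann <- stage("annotate", {
    annotateCorpus(config$corpus, dicts,
                   annotationsFile = file.path(outDir, "annotations.jsonl"),
                   summaryFile = file.path(outDir, "summaries.jsonl"))
  })
  manifest$stages$annotate <- list(nDocs = ann$nDocs,
                                   nSkipped = ann$nSkipped,
                                   nAnnotations = nrow(ann$annotations))
  message(sprintf("[annotate] %d documents (%d skipped), %d annotations",
                  ann$nDocs, ann$nSkipped, nrow(ann$annotations)))

  ## 3. aggregation + ranking per ontology
  atc <- if (is.character(config$atcMap)) readAtcMap(config$atcMap)
         else validateAtcMap(config$atcMap)
  ranked <- list(); filtered <- list()
  for (nm in names(bSources)) {
    tab <- stage(paste0("aggregate-", nm),
                 aggregateCounts(ann$summaries, nm))
    rk <- rankDrugs(tab)
    writeRankedList(rk, file.path(outDir, paste0("ranked_", nm, ".tsv")))
    fl <- stage(paste0("filter-", nm), filterATC(rk, atc, atcPrefix))
    writeRankedList(fl, file.path(outDir, paste0("filtered_", nm, ".tsv")))
    ranked[[nm]] <- rk; filtered[[nm]] <- fl
    manifest$stages[[paste0("rank_", nm)]] <-
      list(nDrugs = length(rk@drugs), nRetained = length(fl@drugs),
           nDocsB = tab@nDocsB, nDocsBC = tab@nDocsBC)
    message(sprintf("[rank-%s] %d drugs, %d retained after ATC '%s'",
                    nm, length(rk@drugs), length(fl@drugs), atcPrefix))
  }

  ## 4. rank fusion
  nonEmpty <- filtered[vapply(filtered, function(l) length(l@drugs) > 0L,
                              logical(1))]
  final <- stage("combine", {
    if (!length(nonEmpty)) {
      new("RankedDrugList", ontologyId = "final", drugs = character(),
          counts = numeric())
    } else {
      do.call(combineLists,
              c(list(lists = unname(nonEmpty), seed = seed), fusion))
    }
  })
  writeRankedList(final, file.path(outDir, "final_ranked.tsv"))
  manifest$stages$combine <- list(
    k = length(final@drugs),
    objective = attr(final, "objective") %||% NA_real_)

  ## 5. reference sets, priority score, DSEA
  refsets <- stage("load-refs", {
    lapply(stats::setNames(names(config$refLists), names(config$refLists)),
           function(nm) {
             x <- config$refLists[[nm]]
             if (is(x, "ReferenceSet")) x else readReferenceSet(x, nm)
           })
  })
  finalTable <- stage("score", buildFinalTable(final, filtered, refsets, atc))
  utils::write.table(finalTable, file.path(outDir, "final_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  unionRef <- unionReferenceSets(refsets)
  dseaLists <- c(nonEmpty,
                 if (length(final@drugs)) list(final = final))
  if (length(dseaLists)) {
    prof <- stage("dsea", dseaProfile(dseaLists, unionRef, convention))
    utils::write.table(prof$curves, file.path(outDir, "dsea_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(prof$maxima, file.path(outDir, "dsea_maxima.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$dsea <- list(
      maxima = stats::setNames(prof$maxima$max_score, prof$maxima$list))
  }

  ## 6. ontology and document-set comparison
  if (length(bSources) >= 2L) {
    cmp <- stage("compare", conceptOverlap(unname(bSources)))
    syn <- synonymOverlap(unname(bSources))
    exportMapping(cmp$graph, file.path(outDir, "mapping.tsv"))
    jsonlite::write_json(
      list(concepts = cmp$report, synonyms = syn),
      file.path(outDir, "ontology_overlap.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  dsets <- docsetsFromSummaries(ann$summaries)
  jsonlite::write_json(
    docsetOverlap(dsets, corpusSize = ann$nDocs),
    file.path(outDir, "docset_overlap.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)

  ## 7. manifest
  sanitize <- function(x) {
    if (is(x, "TermSource") || is(x, "ReferenceSet")) return("<in-memory>")
    if (is.list(x)) return(lapply(x, sanitize))
    x
  }
  manifest$config <- sanitize(config)
  manifest$inputs <- list(corpus = inputHash(config$corpus))
  outFiles <- sort(setdiff(list.files(outDir, recursive = TRUE),
                           "manifest.json"))
  manifest$outputs <- as.list(stats::setNames(
    unname(tools::md5sum(file.path(outDir, outFiles))), outFiles))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
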