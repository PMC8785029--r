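writeToyInputs <- function(dir) {
  writeLines(c("id\tlabel\tsynonyms",
               "b1\tfocal seizure\t",
               "b2\tabsence attack\t"),
             file.path(dir, "ont1.tsv"))
  writeLines(c("id\tlabel\tsynonyms",
               "b3\tmyoclonic jerk\t",
               "b4\tphotosensitive response\t"),
             file.path(dir, "ont2.tsv"))
  writeLines(c("id\tlabel\tsynonyms",
               "d1\tKetamine\t",
               "d2\tPhenobarbital\t",
               "d3\tAspirin\t"),
             file.path(dir, "drugs.tsv"))
  writeLines(c("drug\tcodes",
               "Ketamine\tN01AX03",
               "Phenobarbital\tN03AA02",
               "Aspirin\tB01AC06"),
             file.path(dir, "atc.tsv"))
  for (rl in c("lancet", "drugse", "efo", "u2d"))
    writeLines(c("# reference list", "Phenobarbital",
                 if (rl == "drugse") "Ketamine"),
               file.path(dir, paste0(rl, ".txt")))
  invisible(dir)
}

toyConfig <- function(dir, corpus, outDir, seed = 1L) {
  list(
    corpus = corpus,
    termSources = list(
      ont1 = list(path = file.path(dir, "ont1.tsv"), format = "tabular"),
      ont2 = list(path = file.path(dir, "ont2.tsv"), format = "tabular")),
    drugVocab = list(path = file.path(dir, "drugs.tsv"),
                     format = "tabular"),
    atcMap = file.path(dir, "atc.tsv"),
    refLists = as.list(setNames(
      file.path(dir, paste0(c("lancet", "drugse", "efo", "u2d"), ".txt")),
      c("lancet", "drugse", "efo", "u2d"))),
    stem = TRUE, atcPrefix = "N",
    fusion = list(k = "auto", method = "cemc", nSamples = 60L,
                  maxIter = 40L),
    dseaConvention = "corrected",
    outDir = outDir, seed = seed)
}

test_that("the three-document toy corpus yields hand-checkable outputs", {
  dir <- withr::local_tempdir()
  writeToyInputs(dir)
  corpus <- file.path(dir, "corpus.jsonl")
  writeLines(c(
    '{"pmid":"p1","title":"focal seizure with Ketamine","abstractText":"also Phenobarbital given"}',
    '{"pmid":"p2","title":"Ketamine alone","abstractText":"no b terms"}',
    '{"pmid":"p3","title":"myoclonic jerk and absence attack","abstractText":"Ketamine helped"}'),
    corpus)
  outDir <- file.path(dir, "run1")
  manifest <- suppressMessages(
    runPipeline(toyConfig(dir, corpus, outDir)))
  # hand tally: ont1 B-docs = p1, p3; both contain Ketamine, p1 also
  # Phenobarbital; ont2 B-docs = p3 (Ketamine)
  r1 <- readRankedList(file.path(outDir, "ranked_ont1.tsv"))
  expect_equal(drugCounts(r1), c(Ketamine = 2, Phenobarbital = 1))
  r2 <- readRankedList(file.path(outDir, "ranked_ont2.tsv"))
  expect_equal(drugCounts(r2), c(Ketamine = 1))
  # ATC N filter keeps both drugs (Aspirin is class B and never co-occurs)
  f1 <- readRankedList(file.path(outDir, "filtered_ont1.tsv"))
  expect_equal(drugs(f1), c("Ketamine", "Phenobarbital"))
  # final table flags: Phenobarbital has all four lists + N03 when present
  tab <- read.delim(file.path(outDir, "final_table.tsv"))
  expect_true(all(c("rank", "drug", "priority") %in% names(tab)))
  if ("Phenobarbital" %in% tab$drug)
    expect_equal(tab$priority[tab$drug == "Phenobarbital"], 5L)
  if ("Ketamine" %in% tab$drug)
    expect_equal(tab$priority[tab$drug == "Ketamine"], 1L)  # drugse only

  expect_equal(manifest$stages$annotate$nDocs, 3L)
  expect_equal(manifest$stages$annotate$nSkipped, 0L)
  expect_equal(manifest$stages$rank_ont1$nDocsB, 2L)
  expect_equal(manifest$stages$rank_ont1$nDocsBC, 2L)
  # comparison artifacts exist
  expect_true(file.exists(file.path(outDir, "ontology_overlap.json")))
  expect_true(file.exists(file.path(outDir, "docset_overlap.json")))
  dso <- jsonlite::fromJSON(file.path(outDir, "docset_overlap.json"))
  expect_equal(dso$unionSize, 2L)  # p1 and p3 carry B-terms
})

test_that("an empty corpus runs to completion with zero counts", {
  dir <- withr::local_tempdir()
  writeToyInputs(dir)
  corpus <- file.path(dir, "empty.jsonl")
  writeLines(character(), corpus)
  outDir <- file.path(dir, "runE")
  manifest <- suppressMessages(
    runPipeline(toyConfig(dir, corpus, outDir)))
  expect_equal(manifest$stages$annotate$nDocs, 0L)
  expect_equal(manifest$stages$rank_ont1$nDrugs, 0L)
  expect_equal(manifest$stages$combine$k, 0L)
  final <- readRankedList(file.path(outDir, "final_ranked.tsv"))
  expect_length(drugs(final), 0L)
})

test_that("identical config and seed reproduce byte-identical artifacts", {
  dir <- withr::local_tempdir()
  writeToyInputs(dir)
  gen <- genCorpus(25L,
                   bVocab = list(ont1 = c("focal seizure",
                                          "absence attack"),
                                 ont2 = c("myoclonic jerk")),
                   drugVocab = c("Ketamine", "Phenobarbital"),
                   pB = 0.7, pDrug = 0.5, seed = 14L,
                   file = file.path(dir, "corpus.jsonl"))
  m1 <- suppressMessages(runPipeline(
    toyConfig(dir, file.path(dir, "corpus.jsonl"),
              file.path(dir, "runA"), seed = 3L)))
  m2 <- suppressMessages(runPipeline(
    toyConfig(dir, file.path(dir, "corpus.jsonl"),
              file.path(dir, "runB"), seed = 3L)))
  expect_identical(m1$outputs, m2$outputs)
})

test_that("document-id sets per ontology are extracted from summaries", {
  s <- data.frame(docId = c("p1", "p2", "p3"), stringsAsFactors = FALSE)
  s$bSources <- list("ontA", character(), c("ontA", "ontB"))
  s$drugs <- list(character(), "X", "X")
  attr(s, "bSourceIds") <- c("ontA", "ontB")
  d <- docsetsFromSummaries(s)
  expect_equal(d$ontA, c("p1", "p3"))
  expect_equal(d$ontB, "p3")
  d2 <- docsetsFromSummaries(s, requireDrug = TRUE)
  expect_equal(d2$ontA, "p3")
})
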