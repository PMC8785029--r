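makeDicts <- function(stem = FALSE) {
  list(
    buildDictionary(TermSource("drugs", c("d1", "d2"),
                               c("Ketamine", "Valproic acid"),
                               role = "C"), stem = stem),
    buildDictionary(TermSource("epi", c("b1", "b2"),
                               c("seizure", "status epilepticus"),
                               list(character(), "status")), stem = stem))
}

test_that("tokenizer reports offsets into the original string", {
  t1 <- tokenizeText("Ketamine, 5 mg")
  expect_equal(t1$token, c("ketamine", "5", "mg"))
  expect_equal(t1$offset, c(0L, 10L, 12L))
  expect_equal(t1$length, c(8L, 1L, 2L))
  expect_equal(nrow(tokenizeText("")), 0L)
  expect_equal(nrow(tokenizeText("   ...   ")), 0L)
})

test_that("re-tokenizing a token's surface reproduces that token", {
  toks <- tokenizeText("Valproic acid reduced tonic-clonic seizures (n=12)")
  for (i in seq_len(nrow(toks))) {
    again <- tokenizeText(toks$token[i])
    expect_equal(again$token, toks$token[i])
    expect_equal(again$length, toks$length[i])
  }
})

test_that("annotations carry exact offsets and lengths", {
  ann <- annotateDocument("Ketamine reduced seizure frequency", makeDicts())
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$offset, c(0L, 17L))
  expect_equal(ann$length, c(8L, 7L))
  expect_equal(ann$matchedText, c("Ketamine", "seizure"))
  expect_equal(ann$sourceId, c("drugs", "epi"))
})

test_that("the leftmost-longest match wins within a dictionary", {
  ann <- annotateDocument("status epilepticus persisted", makeDicts())
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$matchedText, "status epilepticus")
  expect_equal(ann$length, 18L)
  # the shorter synonym still matches when alone
  ann2 <- annotateDocument("status worsened", makeDicts())
  expect_equal(ann2$conceptLabel, "status epilepticus")
  expect_equal(ann2$length, 6L)
})

test_that("documents without dictionary terms yield no annotations", {
  expect_equal(nrow(annotateDocument("nothing relevant here",
                                     makeDicts())), 0L)
  expect_equal(nrow(annotateDocument("", makeDicts())), 0L)
})

test_that("stem-expanded dictionaries match inflected text", {
  d <- buildDictionary(TermSource("epi", "b1", "Seizure"), stem = TRUE)
  ann <- annotateDocument("Recurrent seizures were observed", d)
  expect_equal(ann$matchedText, "seizures")
  expect_equal(ann$conceptLabel, "Seizure")
  # without stemming, the inflected form does not match
  d0 <- buildDictionary(TermSource("epi", "b1", "Seizure"), stem = FALSE)
  expect_equal(nrow(annotateDocument("Recurrent seizures occur", d0)), 0L)
})

test_that("slice identity and oracle equivalence hold on synthetic corpora", {
  gen <- genCorpus(
    nDocs = 40L,
    bVocab = list(ontA = c("focal seizure", "absence attack"),
                  ontB = c("photosensitive response", "myoclonic jerk")),
    drugVocab = c("Ketamine", "Valproic acid", "Phenobarbital"),
    pB = 0.7, pDrug = 0.4, seed = 11L)
  srcs <- list(
    TermSource("ontA", c("a1", "a2"),
               c("focal seizure", "absence attack")),
    TermSource("ontB", c("b1", "b2"),
               c("photosensitive response", "myoclonic jerk")),
    TermSource("drugs", c("d1", "d2", "d3"),
               c("Ketamine", "Valproic acid", "Phenobarbital"),
               role = "C"))
  dicts <- lapply(srcs, buildDictionary, stem = TRUE)
  for (i in seq_len(nrow(gen$records))) {
    rec <- gen$records[i, ]
    text <- paste(rec$title, rec$abstractText)
    ann <- annotateDocument(list(docId = rec$pmid, text = text), dicts)
    # slice identity
    if (nrow(ann))
      expect_identical(substring(text, ann$offset + 1L,
                                 ann$offset + ann$length),
                       ann$matchedText)
    # oracle equivalence, dictionary by dictionary
    for (d in dicts) {
      mine <- ann[ann$sourceId == sourceId(d), , drop = FALSE]
      oracle <- naiveAnnotate(text, d, docId = rec$pmid)
      rownames(mine) <- rownames(oracle) <- NULL
      expect_equal(mine, oracle)
    }
    # no overlaps within one dictionary
    for (sid in unique(ann$sourceId)) {
      a <- ann[ann$sourceId == sid, , drop = FALSE]
      a <- a[!duplicated(a$offset), , drop = FALSE]  # multi-concept spans
      a <- a[order(a$offset), , drop = FALSE]
      if (nrow(a) > 1L)
        expect_true(all(utils::head(a$offset + a$length, -1L) <=
                          utils::tail(a$offset, -1L)))
    }
  }
})

test_that("corpus annotation summarizes presence and tallies skips", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"pmid":"p1","title":"Ketamine and seizure","abstractText":"more text"}',
    'this is not json',
    '{"title":"no pmid either"}',
    '{"pmid":"p2","title":"Valproic acid only"}',
    '{"pmid":"p3","title":"status epilepticus","abstractText":"Ketamine"}'),
    f)
  res <- suppressWarnings(annotateCorpus(f, makeDicts()))
  expect_equal(res$nDocs, 3L)
  expect_equal(res$nSkipped, 2L)
  expect_equal(res$summaries$docId, c("p1", "p2", "p3"))
  expect_equal(res$summaries$bSources[[1]], "epi")
  expect_equal(res$summaries$drugs[[1]], "Ketamine")
  expect_equal(res$summaries$bSources[[2]], character())
  expect_equal(res$summaries$drugs[[2]], "Valproic acid")
  expect_setequal(res$summaries$drugs[[3]], "Ketamine")
  expect_equal(attr(res$summaries, "bSourceIds"), "epi")
})

test_that("annotation and summary streams are valid JSON-Lines", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(
    '{"pmid":"p1","title":"Ketamine and seizure","abstractText":"x"}', f)
  af <- withr::local_tempfile(fileext = ".jsonl")
  sf <- withr::local_tempfile(fileext = ".jsonl")
  res <- annotateCorpus(f, makeDicts(), annotationsFile = af,
                        summaryFile = sf)
  annLines <- lapply(readLines(af), jsonlite::fromJSON)
  expect_equal(length(annLines), nrow(res$annotations))
  expect_equal(annLines[[1]]$docId, "p1")
  sumLine <- jsonlite::fromJSON(readLines(sf)[1])
  expect_equal(sumLine$docId, "p1")
  expect_equal(sumLine$bSources, "epi")
})
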