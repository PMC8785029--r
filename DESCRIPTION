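Package: odptools
Title: Ontology-Based Open Discovery for Drug Repurposing from Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Open Discovery Process (Swanson's ABC model) for
    literature-based drug repurposing. Ontology term sources (OWL or tabular)
    are compiled into normalized lookup dictionaries with optional Porter2
    (snowball) stemming, applied as dictionary-based named-entity recognition
    over a JSON-Lines citation corpus to produce stand-off annotations, and
    aggregated into per-ontology drug/B-term co-occurrence document
    frequencies. Ranked drug lists are filtered by Anatomical Therapeutic
    Chemical (ATC) class, fused into a final top-k list by cross-entropy
    Monte Carlo minimization of Spearman footrule or Kendall rank distance,
    scored against reference drug lists with an additive priority score, and
    evaluated with the Drug Set Enrichment Analysis (DSEA) running-sum
    statistic with an adaptive bonus/penalty. Synonym-overlap comparison of
    ontologies and document-set overlap statistics are included, as are
    deterministic synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
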