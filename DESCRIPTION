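Package: epiclock
Title: Epigenetic Clocks and Aging EWAS for Cross-Tissue and Cross-Species
    Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating elastic-net epigenetic clocks
    from CpG methylation beta-value matrices, including single-tissue,
    dual-tissue and dual-species (relative-age) clocks with leave-one-out and
    k-fold cross-validation, age-acceleration analysis of isogenic tissue
    pairs, and an epigenome-wide association screen of aging with Stouffer
    cross-tissue meta-analysis, top-CpG selection, divergence classification
    and annotation-based enrichment statistics. Includes a synthetic
    methylation-array data generator with ground truth so every stage of the
    analysis is testable without access to consortium array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
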