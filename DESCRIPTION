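Package: nutrilink
Title: Record Linkage of Branded Food Products to Food Composition Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Semi-automated record linkage that maps branded food products
    (name, energy and seven nutrients) to their closest equivalents in a
    reference food-composition table.  Candidate matches are screened by
    nutrient-share threshold filters, restricted to shared food-category
    blocking groups, and scored with a partial token sort ratio fuzzy
    string match.  A multi-sift parameter schedule routes products with
    zero or single suggestions through progressively looser filter sets,
    candidates are ranked by maximal nutritional difference, and helper
    routines compute inter-rater agreement and accuracy statistics for
    the expert adjudication stages.  A seeded synthetic-data generator
    produces product/reference database pairs with known ground-truth
    linkage for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
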