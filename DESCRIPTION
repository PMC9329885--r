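Package: pfasmix
Title: Dose-Response and Mixture-Additivity Analysis for Binary PFAS
    Toxicity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for binary-mixture developmental toxicity
    studies in zebrafish embryos, built around the PFOS / 6:2 FTS swim
    bladder case. Provides points of departure (NOAEL/LOAEL with
    bounded/unbounded qualifiers, benchmark dose BMD/BMDL at an
    SD-based benchmark response with profile-likelihood lower bounds),
    full-curve relative potency via linear dose-response inversion,
    the index-chemical dose-balance procedure for whole-mixture
    experiments, isobole construction, response-additivity checks, and
    a synthetic study generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
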