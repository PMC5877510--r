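Package: nanoscreen
Title: Comparative Hazard Screening of Nanomaterials by Weight of
    Evidence and Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative hazard screening of engineered nanomaterials
    by two complementary frameworks. A weight-of-evidence (WoE)
    multi-criteria engine scores individual lines of evidence on
    physico-chemical, toxicological, and study-quality criteria and
    aggregates them into a hazard score in [0,100], with Monte Carlo
    uncertainty analysis of the score and of the relative hazard
    ranking. A discrete Bayesian-network engine provides exact
    inference by variable elimination, expectation-maximization
    parameter learning from incomplete categorical data, entropy-based
    value-of-information analysis, normalized hazard scoring, and
    cross-validation. A synthetic line-of-evidence generator with a
    known ground-truth network lets the full comparison run end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
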