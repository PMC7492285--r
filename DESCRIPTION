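Package: qmricart
Title: Serial Quantitative MRI Analysis of Cartilage Response to Loading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for serial multiparametric quantitative MRI (qMRI) analysis
    of articular cartilage under indentation loading. Provides a synthetic
    phantom generator for cartilage cross-sections imaged under three loading
    configurations and three exposure arms, pixel-wise mono-exponential
    T1/T1rho/T2/T2* relaxometry with adjusted-R-squared quality control,
    zonal/regional region-of-interest construction (sub- and peri-pistonal,
    upper and lower halves), relative response-to-loading statistics, and a
    paired nonparametric statistical battery with Bonferroni-Holm correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
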