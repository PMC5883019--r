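Package: flimcarbon
Title: NAD(P)H Fluorescence-Lifetime Analysis of Carbon Fate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-correlated single photon counting (TCSPC)
    fluorescence-lifetime imaging (FLIM) of NAD(P)H. Provides iterative
    reconvolution fitting of multi-exponential decay models with fixed or
    free lifetimes, chi-squared model selection, fixed-lifetime unmixing of
    NADH bound to two enzymes, binding-equilibrium design of NAD(P)H-enzyme
    solutions, a per-cell optical redox ratio and lifetime-component image
    pipeline, and a synthetic TCSPC data generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
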