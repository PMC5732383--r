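Package: hzclines
Title: Temporal Dynamics of Hybrid-Zone Clines from Museum Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising moving avian hybrid zones from unevenly
    sampled museum specimens: projection of specimen localities onto a best-fit
    transect line, morphometric body-size scores via principal components,
    segment-classification colour metrics (brightness, chroma, hue) from
    reflectance spectra, four-parameter log-logistic (Hill) cline fits with
    effective-dose based center and width estimates, filtered bootstrap
    uncertainty with cross-period ANOVA and Tukey comparisons, three-level
    AMOVA of mitochondrial haplotypes with permutation tests, expected cline
    widths under neutral diffusion, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
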