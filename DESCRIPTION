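Package: liftrisk
Title: Biomechanical Risk Classification of Lifting Tasks from a Sternum-Worn IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing biomechanical risk of manual lifting tasks from a
    single sternum-mounted inertial measurement unit. Implements the Revised NIOSH
    Lifting Equation (recommended weight limit and lifting index), automatic
    segmentation of repeated lifts from 6-channel inertial recordings (Butterworth
    band-pass, rectification, Savitzky-Golay envelope, threshold-based
    region-of-interest detection), a 114-column time- and frequency-domain feature
    table, paired statistical screening (Shapiro-Wilk gated paired t / Wilcoxon
    tests), and a pruned binary logistic-regression classifier with
    correlation-based feature reduction and Cook's-distance/leverage outlier
    removal. A seeded synthetic-signal generator emulating the rhythmic-lifting
    study design makes the full pipeline testable end to end.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
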