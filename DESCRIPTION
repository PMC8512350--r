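Package: perclosr
Title: Eye Closure-Based Driver Fatigue Indicators from Facial Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A camera-based driver-fatigue analysis pipeline: per-frame
    eye-state classification by normalized-correlation template matching,
    segmentation of eye-closure events with blink exclusion, windowed
    PERCLOS, eye closure duration (ECD) and frequency of eye closure (FEC)
    indicators with fatigue thresholds, and a multilevel statistical
    evaluation workflow (paired tests with dependent-samples effect sizes,
    ROC analysis with bootstrap confidence intervals, and three-level
    linear mixed models with intraclass correlations, marginal and
    conditional R-squared, and per-level delta R-squared). Includes
    ground-truthed synthetic generators for eye-aperture signals, rendered
    eye-region frame sequences, and three-level subjective-fatigue data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lme4,
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
    optparse,
    pROC,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
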