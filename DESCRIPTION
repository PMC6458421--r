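Package: scenegaze
Title: Task Effects on Social Attention Versus Physical Saliency in Scene Viewing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying early attentional
    prioritization of social scene regions (heads, bodies) relative to
    physically salient regions during free viewing and social-detection
    tasks. Includes multi-scale low-level saliency maps (centre-surround
    and graph-activation backends), saliency-decile region-of-interest
    partitioning, velocity/acceleration-threshold saccade and fixation
    parsing of 1000 Hz gaze streams, baseline drift correction with
    recursive outlier removal, area-normalized fixation-course and
    first-entry latency statistics, repeated-measures ANOVA with
    Huynh-Feldt correction, Harrell-Davis shift functions with percentile
    bootstrap, and a synthetic-data module that generates scenes, social
    masks and gaze traces with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
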