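Package: dyadsync
Title: Windowed Cross-Correlation Analysis of Dyadic Head-Movement Synchrony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies interpersonal head-movement synchrony between two
    interacting people from pose-tracker keypoint trajectories. Implements
    the full analysis chain used in video-based studies of nonverbal
    coordination: robust preprocessing of vertical nose-landmark series
    (scaled-MAD outlier removal, linear interpolation, median filtering,
    z-normalization), windowed cross-correlation with Fisher-Z transform and
    per-window peak picking yielding a per-dyad strength and signed delay of
    synchrony, a segment-shuffle pseudosynchrony null, and cohort-level
    statistics (paired genuine-versus-pseudo tests, assessor-nested linear
    mixed models with intraclass correlation, two-way ANOVAs, and Pearson
    correlations with Benjamini-Hochberg correction). A synthetic dyad and
    cohort generator with known coupling, lag, group effects, and assessor
    random effects makes every stage testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    car,
    emmeans,
    purrr,
    readr,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
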