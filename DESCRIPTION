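Package: nsfecg
Title: Fetal ECG Extraction by Null-Space Projection with an Idempotent
    Transformation Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Blind source separation of non-invasive abdominal
    electrocardiogram recordings into maternal and fetal components.
    Implements extraction via the null space of an idempotent
    transformation matrix (an orthogonal projector onto the row space of
    the preprocessed mixture), together with PCA-whitening, fixed-point
    ICA and parallel-linear-predictor baselines, Pan-Tompkins R-peak
    detection with maternal/fetal parameter sets, a control-logic driven
    adaptive comb filter that removes residual maternal beats, a full
    separation-quality metric suite (SPI, SIR/SAR/SDR, qSNR, SE/ACC/PPV),
    and a seeded synthetic abdominal-mixture simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
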