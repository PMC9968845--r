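Package: smrbci
Title: Inter- and Intra-Subject Variability Analysis for Motor-Imagery EEG
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how sensorimotor-rhythm (SMR) motor-imagery
    EEG decoding degrades when a model trained on one subject or session
    is applied to another.  Provides a synthetic multi-subject,
    multi-session SMR cohort generator with controllable inter-subject
    and inter-session parameter dispersion; the standard offline
    preprocessing chain (decimation, notch, 8-30 Hz band-pass, epoching);
    Morlet wavelet time-frequency analysis with the percent ERD/ERS
    index; common spatial patterns (CSP) and closed-form linear
    discriminant analysis (LDA) decoding; cross-train/test accuracy and
    feature-distribution transfer matrices with two-sample t-tests under
    Bonferroni correction; Gaussian Kullback-Leibler divergence; and six
    training-set selection strategies (Prev, Next, Best, Worst, Closest,
    All) for cross-session and cross-subject decoding tasks.  Results
    are tidy tibbles with broom-style tidy()/glance() methods and
    ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
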