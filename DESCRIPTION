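Package: hearsim
Title: Simulated Validation of Biologically Calibrated Mobile Audiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates hearing self-tests on mobile devices calibrated
    biologically from crowd-sourced measurements (the mHL scale), alongside
    clinical pure-tone audiometry, on fully synthetic listener cohorts.
    Provides psychometric yes/no listener models, adaptive staircase and
    Bekesy tracking procedures with contralateral masking, the robust
    37th-percentile crowd calibration estimator, method-agreement statistics
    (paired differences with confidence intervals, intraclass correlation,
    Cronbach alpha, Bland-Altman limits), hearing-loss screening metrics,
    and a paired sample-size calculation, organised as a reproducible
    end-to-end study pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
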