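Package: aperisleep
Title: Aperiodic Spectral Parameterization and Time-Resolved 1/f Dynamics
    in Sleep Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the aperiodic (1/f-like) component of
    sleep EEG and intracranial EEG. Implements spectral parameterization
    with fixed (single-exponent) and Lorentzian knee aperiodic models plus
    Gaussian oscillatory peaks, Welch and sliding-window PSD estimation,
    DPSS multitaper time-frequency decomposition, BIC model comparison,
    stage-level statistics (Friedman/Kendall W, Dunn post-hoc with Cliff's
    delta, Wilcoxon rank-biserial), sleep-stage classification with linear
    discriminant analysis and random-forest feature importance,
    cluster-based permutation tests, stage-transition and event-locked
    analyses of the aperiodic exponent, K-complex candidate detection, and
    a synthetic sleep-recording generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    randomForest,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
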