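Package: fractalEEG
Title: Higuchi Fractal Dimension Analysis of Event-Related EEG
Version: 0.1.0
Authors@R:
    person("EEG", "Complexity Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for nonlinear complexity analysis of
    multichannel EEG with the Higuchi fractal dimension (HFD): band-limited
    per-stimulus 60 s epoch assembly from a stimulus schedule, per-scale
    curve-length profiles and log-log slope estimation, rest-subtracted
    stimulus responses on a lateralized 10-20 montage, and group-level
    multivariate comparison (Wilks' lambda MANOVA with Rao's F
    approximation, Levene and Lilliefors assumption checks, Tukey,
    Games-Howell, Dunnett and Bonferroni post-hoc machinery).  Includes a
    synthetic EEG cohort generator with analytically known, band-resolved
    fractal structure (exact-covariance fractional Brownian motion,
    Weierstrass curves, spectrally shaped band noise) so the whole pipeline
    is testable without clinical recordings, plus EDF reading/writing and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
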