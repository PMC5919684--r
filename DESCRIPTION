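Package: vocamps
Title: Amplitude Modulation Spectra of Vocalization Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying why vocalization sequences (rodent pup calls,
    birdsong, primate calls, infant cries, running speech) exhibit
    scale-invariant 1/f^2 amplitude-modulation power spectra. Implements
    band-limited Hilbert envelope extraction, threshold-based vocalization
    segmentation, least-squares rectangular-pulse fitting, multitaper
    estimation of the amplitude modulation power spectrum (AMPS), a
    stochastic non-overlapping pulse-train model of vocalization envelopes
    with perturbation experiments, the closed-form shot-noise theory of the
    model AMPS (dual-regime lowpass with a duration-determined cutoff), and
    joint/serial statistics of fitted pulse parameters. A synthetic-scene
    generator renders pulse-modulated band-limited carriers over a noise
    floor so the full pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    signal,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
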