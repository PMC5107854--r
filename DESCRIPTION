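Package: respstab
Title: Visual and Quantitative Stability Analysis of Respiratory Motion Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the stability of respiratory motion traces
    recorded during respiratory-gated imaging. Transforms time-amplitude
    breathing signals into phase-space portraits, Fourier amplitude spectra,
    modified Poincare sections and largest-Lyapunov-exponent estimates;
    quantifies amplitude regularity (SD of Poincare crossing coordinates),
    period regularity (height of the fundamental spectral peak), and
    end-of-exhale baseline drift (maximal upward minus maximal downward drift);
    and classifies traces into a four-group regular/irregular taxonomy with
    published cutoff values. Includes a synthetic breathing-trace generator
    with per-cycle amplitude and period jitter, bounded baseline drift and
    sensor noise, so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    patchwork,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
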