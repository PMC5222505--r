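Package: stcov
Title: Second-Order Wiener Kernels and Spike-Triggered Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of second-order Wiener kernels from paired
    stimulus-response recordings via the response-weighted stimulus
    covariance, and their transformation into the standard family of
    spike-triggered covariance (STC) matrices: raw (C0), STA-subtracted
    (C1) and STA-projected (C2). Includes eigenspectrum analysis with
    significance assessment against time-shift null ensembles, subspace
    recovery diagnostics, simulators for second-order Volterra model
    cells and multi-filter rectified linear-nonlinear-Poisson spiking
    neurons, Gaussian white-noise stimulus generation, delimited-text
    input/output with JSON metadata sidecars, and a command-line
    interface. A naive reference implementation of the covariance
    estimator is provided alongside a vectorized backend under a strict
    numerical-equivalence contract.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
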