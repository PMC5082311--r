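Package: signedgc
Title: Audit of Signed Path Coefficient Granger Causality by VAR Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for examining the validity of "signed path coefficient"
    Granger causality, the practice of reading directed excitatory/inhibitory
    influence off the lag-1 coefficients of an order-1 vector autoregression
    fitted to multichannel (typically fMRI region-of-interest) time series.
    Provides vector-autoregressive data-generating processes and simulators,
    multivariate least-squares VAR fitting with AICc/BIC model-order
    selection, residual-variance Granger causality and signed lag-1 path
    coefficients, permutation surrogate significance testing, and Monte-Carlo
    sweep drivers that demonstrate when the sign of an underfitted order-1
    coefficient contradicts the true causal structure. An fMRI-like
    multichannel generator emulates the sampling-interval, bandpass-filtering
    and group-size effects seen in resting-state data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
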