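Package: lvfit
Title: Fitting Lotka-Volterra Interaction Models to Ecological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating Lotka-Volterra model parameters (intrinsic
    growth rates, self-limitation, and pairwise interaction coefficients)
    from multi-species abundance time series. Parameters are first estimated
    by ordinary least squares regression of per-capita growth rates on
    species abundances, then refined by sign-constrained Nelder-Mead
    optimization of fully simulated dynamics against observations, with
    approximate standard errors from a numerically differentiated Hessian
    in log-parameter space and an R-squared-like goodness-of-fit index.
    Includes a synthetic-data generator with presets emulating classic
    microcosm, predator-prey, and multi-trophic systems, plus a thin
    command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
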