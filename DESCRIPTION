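Package: voikit
Title: Value of Information Analysis for Health Impact Simulation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the expected value of perfect information (EVPI),
    partial perfect information (EVPPI), sample information (EVSI) and the
    expected net benefit of sampling (ENBS) for simulation models used
    either to decide among policies or to estimate a quantity, from a
    single Monte Carlo sample of model inputs and outputs.  EVPPI and EVSI
    are estimated by nonparametric regression emulation (penalized
    splines, adaptive regression splines, or Gaussian processes).
    Includes a fully reproducible PM2.5-to-stroke health impact model as a
    worked fixture, together with probabilistic bias modelling,
    hierarchical evidence synthesis, study-design utilities for EVSI, and
    tornado-style one-way sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
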