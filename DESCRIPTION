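Package: ddesens
Title: Dynamic Sensitivity Analysis of Delay Differential Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves systems of delay differential equations (DDEs) with discrete
    delays and simultaneously propagates first-order dynamic sensitivities with
    respect to all parameters and initial conditions, using an adaptive implicit
    trapezoidal collocation scheme in direct-decoupled form. All Jacobians are
    obtained exactly by forward-mode automatic differentiation over expression
    graphs parsed from plain-text model definitions supplied at run time, so no
    hand-derived or symbolic sensitivity equations are needed. Includes relative
    and semi-relative sensitivity measures, time-averaged sensitivity ranking
    tables, a baroreflex cardiovascular control model as a worked fixture, and
    finite-difference oracles built on an independent reference integrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
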