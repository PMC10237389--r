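Package: nfkbid
Title: Identifiability Workbench for a Reduced Model of the Canonical
    NF-kappaB Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and parameter-identifiability analysis of a reduced,
    non-dimensional six-variable ordinary differential equation model of the
    canonical NF-kappaB signaling pathway with two negative feedback loops
    mediated by IkBa and A20. Provides TNF stimulation protocols with
    per-genotype measurement schedules, geometric-mean normalization of
    in-silico measurements, multiplicative lognormal measurement noise,
    log-least-squares fitting (differential-evolution global search with
    Levenberg-Marquardt polish), linear identifiability analysis via the
    scaled singular value decomposition of the log-log sensitivity matrix,
    Monte Carlo practical identifiability, and classification of dynamical
    response regimes (adaptation, damped and sustained oscillations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
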