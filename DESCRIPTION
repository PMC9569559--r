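Package: angiopatch
Title: Hybrid Simulation of Arterial-Patch-Induced Angiogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hybrid continuum-discrete simulator of angiogenesis induced by
    suturing an arterial graft into a vein. A prescribed VEGFA concentration
    field (a damped sinusoid in time, quadratic in distance from the patch)
    drives sprout-tip agents through a chemotactic velocity proportional to
    the spatial gradient of the temporal derivative of the concentration.
    Tips perform biased random walks whose movement probabilities are the
    stencil weights of a positivity- and mass-preserving upwind finite
    difference scheme on a dual lattice, with age- and signal-gated
    branching, anastomosis, and patch-arrival termination. Includes the
    matching continuum density solver, nonlinear fitting of the kinetic
    model to measured concentration series, vessel-length metrics that
    mirror the in vivo measurement protocol, and a synthetic-series
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
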