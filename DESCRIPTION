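Package: tiltpost
Title: Rotational Platform Perturbation Analysis for Primate Postural Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and analysis of rotational support-surface
    perturbations that dissociate angular acceleration from peak velocity while
    holding total displacement fixed. Provides trapezoidal-velocity waveform
    construction and a study condition grid; a conceptual dual-pendulum
    (trunk-on-ankles, head-on-neck) model of platform tilt responses; center-of-
    pressure computation from four footplate load cells and stance-symmetry
    checks; trial quality control; short- and medium-latency window metrics with
    RMS-threshold onset latency detection and displacement integrals; a pairwise
    mean-absolute-percentage-error asymmetry index with Welch t-test and Fisher
    combination; unbalanced two-way ANOVA and pooled regression for condition
    dependence; and a seeded synthetic-trial generator with injectable ground
    truth for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    car,
    pracma,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
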