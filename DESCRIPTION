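Package: headingbias
Title: Heading-Perception Biases from Optic Flow: Designs, Synthetic
    Observers, a Bayesian Ideal Observer, and Serial-Dependence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the distribution of previously seen
    headings shapes heading perception from optic flow. Provides the six
    block designs of a three-experiment heading-estimation study (uniform
    and right-heavied nonuniform heading distributions), a seeded synthetic
    observer that generates trial-level perceived headings with
    configurable center bias, central-tendency attraction, constant shift,
    serial dependence and response noise, a grid-based Bayesian ideal
    observer combining an ego-centric prior with a heading-distribution
    prior, and the complete statistical pipeline: per-participant
    perceived-vs-actual heading slope fits and one-sample t-tests,
    repeated-measures and mixed ANOVAs with Greenhouse-Geisser correction,
    central-tendency contrasts, two-stage serial-dependence residual
    regression with participant-level bootstrap intervals, and a
    decomposition of the distribution-induced heading bias into its
    serial-dependence component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    car,
    ggplot2,
    grDevices,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
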