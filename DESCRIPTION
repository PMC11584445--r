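Package: coxplosive
Title: Explosive Cox Process Modelling of Acoustic-Emission Microfailures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic modelling of microfailure accumulation in loaded
    cortical bone monitored by acoustic emission (AE). Implements an
    explosive, doubly stochastic ("coxplosive") renewal process indexed by
    tensile strain, in which inter-event strain increments are exponential
    with a geometrically growing hazard rate, so an unbounded number of
    microfailures accumulates before a finite strain. Provides closed-form
    expectations, sequential simulation, penalty-function estimation of the
    process parameters (alpha, lambda) per specimen, Hill maximum-likelihood
    fitting of the Pareto tail of AE event energies, a synthetic-cohort
    generator linking parameters to age and body-mass index through a single
    latent degradation factor, and cohort-level statistics (Spearman
    correlation matrix, standardized principal component analysis, and the
    regression of the leading component on age and BMI).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
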