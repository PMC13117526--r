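Package: piglettrials
Title: Bayesian Analysis Toolkit for Randomized Piglet Neuroprotection Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for randomized preclinical neuroprotection
    studies in the newborn piglet model of inflammation-amplified
    hypoxic-ischemic encephalopathy: Bayesian probability-of-superiority
    models with noninformative priors for magnetic resonance spectroscopy,
    amplitude-integrated EEG and regional immunohistochemistry outcomes;
    simulation-based operating characteristics (type I error, power,
    futility stopping) and threshold calibration for the trial design; a
    two-compartment population pharmacokinetic model for intravenous
    azithromycin with Laplace-approximate mixed-effects fitting; multiple
    imputation by chained equations with Rubin pooling; bedside scalar
    scores (microglial ramification index, systemic inflammation response
    index, aEEG background score aggregation); repeated-measures mixed
    ANOVA for physiology and cytokine panels; and a seed-reproducible
    synthetic-trial generator so every stage is testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    lmerTest,
    emmeans,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
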