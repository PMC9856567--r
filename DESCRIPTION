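Package: lynchRisk
Title: Personalized Cancer Risk Projection for Lynch Syndrome Carriers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A risk engine for Lynch syndrome genetic counseling support.
    Stores age-specific conditional penetrance (ACP) curves for gene-cancer
    strata, converts published relative risks, odds ratios and time-varying
    hazard ratios into penetrance modifications via a discrete-time hazard
    calculus, deconvolves screening-contaminated colorectal baselines,
    personalizes baselines by body-mass index, projects cumulative future
    risk with and without preventive interventions (colonoscopy, aspirin,
    weight loss, prophylactic surgery), and quantizes the results for
    risk-communication displays (line series, five-year and lifetime
    snapshots, 20-icon personographs). Includes a deterministic synthetic
    penetrance generator for testing and demonstration, and a command-line
    interface over the engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'AcpDatabase-methods.R'
    'registry.R'
    'synthetic.R'
    'hazard-calculus.R'
    'baseline-adjustment.R'
    'profile.R'
    'risk-series.R'
    'risk-engine.R'
    'reporting.R'
    'cli.R'
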