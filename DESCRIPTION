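Package: tambja
Title: QSAR Analysis of Tambjamine Anion Transporters
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative structure-activity analysis of transmembrane
    chloride transport by tambjamine-type anionophores. Extracts transport
    parameters from vesicle efflux assays (Hill EC50 and cooperativity,
    initial release rates from asymptotic trace fits, correlation-based
    EC50 imputation), cleans molecular-descriptor matrices, fits parabolic
    lipophilicity-activity models by ordinary least squares with exhaustive
    all-subsets enumeration, validates coefficients by stratified bootstrap
    resampling, and fits structural-subgroup models with shared curvature
    and group-specific intercepts (fixed or random). Includes a synthetic
    data generator emulating the assay and library structure so the whole
    pipeline is testable end to end, and a one-call reproduction of the
    packaged 43-compound analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
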