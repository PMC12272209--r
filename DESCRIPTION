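Package: wmhprog
Title: Simulation and Mixed-Model Inference for White Matter Hyperintensity
    Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing two-timepoint studies of white
    matter hyperintensity (WMH) progression and its vascular risk factors. The
    package generates synthetic longitudinal cohorts from a Gamma/log-link
    cross-sectional model combined with normally distributed longitudinal
    effect modifiers, builds CERAD-plus composite cognitive scores, performs
    multilevel multiple imputation with Rubin and D1 pooling, fits confirmatory
    and exploratory linear mixed models with one-sided p-values and one-sided
    Jeffreys-Zellner-Siow Bayes factors, maps results to a joint p-value/Bayes
    factor evidence table, runs simulation-based and analytic power analyses,
    provides assumption and influence diagnostics, and analyses spatial WMH
    components on bullseye parcellations via parallel-analysis-guided PCA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
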