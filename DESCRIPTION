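Package: spzip
Title: Bayesian Zero-Inflated Poisson Spatio-Temporal Disease Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Small-area analysis of monthly infectious-disease surveillance
    counts: descriptive incidence tables and crude standardized morbidity
    ratios, seasonal-trend decomposition of monthly series, univariable
    Poisson screening of lagged climate covariates with AIC-based lag
    selection and variance inflation factors, and zero-inflated Poisson
    (ZIP) hierarchical models with unstructured, intrinsic conditional
    autoregressive (ICAR) or convolution area random effects plus
    area-specific trend slopes, fitted by an adaptive
    Metropolis-within-Gibbs sampler and compared by the deviance
    information criterion. Posterior products include relative-risk tables
    with credible intervals, exceedance probabilities and trend
    classification maps. A synthetic-data module generates lattice
    geographies, stratified populations, seasonal climate and ZIP counts
    from known ground truth so the whole pipeline is testable without
    access to confidential surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, yaml, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
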