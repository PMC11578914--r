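Package: ordinvar
Title: Measurement Invariance Testing and Latent Trends for Ordinal Symptom Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for deciding whether cross-cohort time trends in ordinal
    symptom scales reflect real latent change or measurement noninvariance.
    Implements two-step polychoric moment estimation with influence-function
    asymptotic covariances, diagonally weighted least squares (WLSMV-style)
    one-factor confirmatory factor analysis for ordinal items under the delta
    parameterization, the sequential threshold/loading/intercept invariance
    ladder with delta-fit decision rules and greedy partial-invariance search,
    the d_MACS effect size of noninvariance, parallel analysis for factor
    retention, simulation-based dynamic fit-index cutoffs, latent-mean trend
    estimation with freed-versus-fixed counterfactuals, and a synthetic
    multi-group ordinal survey generator with controllable noninvariance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, pracma, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ordinvar-package.R'
    'bvnorm.R'
    'AllClasses.R'
    'accessors.R'
    'popspec.R'
    'simulate.R'
    'polychoric.R'
    'model.R'
    'fit.R'
    'invariance.R'
    'effectsize.R'
    'dimensionality.R'
    'trends.R'
    'dfi.R'
    'io.R'
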