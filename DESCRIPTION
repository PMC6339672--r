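Package: promlink
Title: Calibrating Patient-Reported Outcome Measures onto a Common IRT Metric
Version: 0.1.0
Authors@R: person("Promlink", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for placing the items of several physical-function
    patient-reported outcome measures (PROMs) on a single latent metric using
    polytomous item response theory.  Implements concurrent marginal maximum
    likelihood (EM) calibration of the partial credit and generalized partial
    credit models across linked datasets with dataset-specific latent
    distributions, Stocking-Lord linking of externally calibrated instruments,
    differential item functioning and item fit screening via observed-versus-
    expected score contrasts, Yen's Q3 local-dependence diagnostics, kernel-
    smoothed monotonicity checks, hierarchical factor-analysis screens of
    essential unidimensionality (omega-hierarchical, explained common
    variance), expected-a-posteriori scoring on a standardized 10-points-per-
    logit metric, reliability coefficients, crosswalk tables, and a synthetic
    multi-registry data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
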