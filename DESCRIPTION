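Package: gswave
Title: Wavelet Functional Connectivity and Global Signal Analysis for
    Multi-Sequence fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying global signal (GS) phenomena and
    individual differences in wavelet-domain functional connectivity
    across multi-sequence fMRI sessions. Implements a maximal overlap
    discrete wavelet transform (MODWT, least-asymmetric 8-tap filter)
    with per-scale correlation and variance estimators, a modified
    two-stage component-based (CompCor-style) nuisance correction with
    spike isolation and principal-component motion regressors, a
    12-metric head-motion fingerprint (gamma fit, Hurst exponents,
    frequency ratios) with cohort-level PCA, three GS summary metrics
    per wavelet scale under raw and GS-regressed modes with linear
    acquisition-order contrasts, eigenvalue power-law spectrum fits,
    parcel-level GS topography with max-statistic permutation
    inference, ICC(3,1) reliability inventories, and permutation-tested
    partial least squares brain/behavior mapping with train/test
    correspondence. A seeded synthetic-cohort generator reproduces the
    statistical structure these analyses assume (two cohorts, six
    sequences per subject, group and order effects on GS amplitude) so
    the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    minpack.lm,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
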