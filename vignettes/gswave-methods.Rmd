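---
title: "Global signal metrics and wavelet connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global signal metrics and wavelet connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gswave)
```

# What this package computes

`gswave` studies how global signal (GS) phenomena, head motion, and
acquisition order shape individual-differences analyses of parcellated
fMRI time series collected across several sequences per subject.  The
pipeline is: component-based nuisance correction, maximal overlap
discrete wavelet transform (MODWT) decomposition into six frequency
scales, three GS summary metrics per scale, eigenvalue power-law fits,
parcel-level GS topography, ICC(3,1) reliability, and permutation-tested
partial least squares (PLS) linking brain measures to a 29-variable
behavior/demographics battery under a strict training/testing
replication protocol.

A synthetic cohort generator produces data with the statistical
structure these analyses assume, so every stage is testable end to end
without imaging data.

# The wavelet machinery

## MODWT, boundary handling, reconstruction

Each regional series is decomposed with the undecimated MODWT using the
least-asymmetric 8-tap (la8) filter into six detail series plus a
smooth.  At a 1.5-s sampling interval the scales span 0.17–0.33,
0.08–0.17, 0.04–0.08, 0.02–0.04, 0.01–0.02 and 0.005–0.01 Hz
(`scale_frequency_band()`).  Boundaries are handled by reflection: the
series is extended to length $2N$ by its reversal, the circular MODWT is
applied, and the first $N$ coefficients are kept.  The multiresolution
analysis is additive and exact: details plus smooth reconstruct the
input to machine precision (tested at $10^{-8}$ relative), and the
coefficient energies decompose the sample variance.

Coefficients with time index below the level-$j$ filter width
$L_j = (2^j-1)(L-1)+1$ involve the boundary.  When at least 8
boundary-free coefficients exist, variance and correlation estimates use
only those ("interior"); otherwise all $N$ reflection-boundary
coefficients are used and flagged.  The fallback is not academic: at the
session's own sequence lengths (180 and 240 time points), scales 5 and 6
have no boundary-free coefficients at all ($L_5 = 218$, $L_6 = 442$),
yet the GS analyses require all six scales.

## Effective degrees of freedom for wavelet correlation

The MODWT is undecimated, so neighbouring coefficients are strongly
autocorrelated and the usable coefficient count badly overstates the
information in a correlation estimate.  The Fisher transform
$z = \operatorname{atanh}(r)\sqrt{\mathrm{df}-3}$ therefore uses an
effective sample size: the usable count divided by the redundancy
$\sum_k \rho_j(k)^2$ of the equivalent level-$j$ wavelet filter, where
$\rho_j$ is the filter's normalized autocorrelation.  This quantity is
deterministic, computed once per level from the filter itself.  At
$N = 512$ the predicted effective sizes for scales 1–4 are 289, 195,
93 and 41, against Monte-Carlo values of 283, 185, 95 and 44; under
independence the resulting $z$ is standard normal to within a few
percent, which the test suite checks.  The naive conventions bracket
this choice: the raw interior count gives $z$ an SD near 1.5, and the
band-limited count $\hat N_j/2^j$ gives about 0.8.

# Nuisance correction

Stage 1 isolates spikes.  The noise pool (top-SD candidate series, with
an exclusion-label mechanism standing in for the anatomical exclusions
a voxel mask would apply) is decomposed by PCA; among the top 30
component series, those with raw kurtosis above 4.5 and at least one
$|z| > 4.5$ time point contribute spike series retaining only their
$|z| > 3$ entries.  Frames whose detrended framewise displacement (FWD)
exceeds 1 mm add unit spike regressors; "detrended" means zero-phase
4th-order Butterworth high-pass (0.01 Hz), i.e. the high-frequency
excursions that signal abrupt motion.  All spike series are jointly
PCA-reduced, keeping components with eigenvalue above $10^{-8}$ of the
trace — this removes exact collinearity without discarding information.
Spike regressors are zero off-spike, so regression cannot alter
spike-free time points through them.

Stage 2 removes 7 CompCor components plus their first differences
(zero-padded, preserving length) and 7 motion PCs.  The motion PCs come
from a 42-column design: six rigid-body series plus detrended FWD,
high-pass filtered at a 0.001 Hz stopband, expanded to basic and
square-root-of-absolute forms (14), plus first and second differences,
all z-scored.  Because the columns are z-scored, a planted oscillation
confined to a single channel does not necessarily own the first PC
(derivative families of rougher channels cohere more strongly); what
holds, and what the tests assert, is that the retained PCs capture such
a source almost completely ($R^2 > 0.9$).

Stage-2 regressors are orthogonalized against the stage-1 design before
the second regression; otherwise the CompCor regressors, which are not
orthogonal to a task design, would reintroduce task variance that
stage 1 removed.  Final residuals are orthogonal to every regressor
(checked at $10^{-8}$).

# GS summary metrics, order contrasts, and group tests

Three metrics per subject, sequence and scale: the mean of all pairwise
wavelet correlations (averaged on the Fisher-z scale — z can be
negative, so the log transform applied to the variance metrics would be
undefined here), the median regional wavelet variance, and the wavelet
variance of the global series.  In raw mode the GS variance uses the
pre-nuisance global series; standard GSR regresses the unweighted
global series of the cleaned data out of every region; weighted GSR
uses the mean of per-region z-scored series, so low-amplitude regions
contribute equally.  Sequence-averaged metrics are log-transformed
(variances only) and z-scored to a subject-by-18 matrix.

Linear order effects use the centered unit-spacing contrast
$(-2.5, -1.5, \dots, +2.5)$ on untransformed per-sequence values.  The
default sign convention is increase-positive; the literature this
mirrors weights the *first* sequence 2.5 while reporting variance
*increases* with positive statistics, which is internally inconsistent,
so both conventions are exposed
(`linear_order_contrast(..., sign_convention)`).

Group (e.g. sex) effects on the 18 measures are tested by regression
with five motion-PC covariates.  The training threshold is
$\alpha/(18 \times 3)$ for three demographic predictors — reported as
0.0009 — and a testing cohort inherits $\alpha/(\text{training hits})$.
Thresholds are reported rounded to four decimals (0.05/18 prints as
0.0028), matching the convention of the reported values this package
reproduces.

# Eigenvalue scaling

For each sequence, PCA eigenvalues of the time-by-region matrix are fit
by $\mathrm{EVM} = a\,(\#\mathrm{EV})^b + c$ over ranks
$1..\min(P, 100)$ with `minpack.lm::nlsLM` from three starts
($b_0 \in \{-0.5, -1, -2\}$; best RSS wins, so the fit is deterministic).
The fit is exact on model-class spectra and obeys the scaling law
(multiplying the spectrum by $s$ multiplies $a$ and $c$ by $s$, leaves
$b$).  Group comparisons average parameters across sequences per subject
and test $\log a$, $b$, $c$ with covariate-adjusted regression, in
scaled mode (regions z-transformed before PCA, eigenvalues summing to
the region count) and unscaled mode, broadband and low-frequency band.
The low band is the level-3 MODWT smooth (everything below the scale-3
band), computed directly rather than by summing details 4–6 of a deeper
decomposition — the two are identical to machine precision.  At
synthetic scale, the broadband $\log a$ test is diluted and the
low-band test carries a planted low-frequency amplitude effect; the
amplitude interpretation is confirmed when per-region z-scoring
abolishes it.

# Topography and inference

Parcel-level topography regresses each region on the standard or
weighted GS after a 128-s discrete-cosine high-pass; the slope t is
mapped to z through the normal quantile of the t distribution at the
residual df (no autocorrelation correction; |z| capped at 8 with a
flag).  Group differences and linear order trends are tested with
max-|t| permutation across regions — group labels permuted in the
covariate-residualized model, or subject sign-flips for the one-sample
order contrast — controlling parcel-level family-wise error, the
parcel analog of voxelwise cluster-FWE inference (random-field theory
and spatial smoothing have no parcel analog and are out of scope).

# Reliability and PLS

ICC(3,1) treats the six sequences as fixed raters (two-way mixed,
consistency, single measurement), computed from the ANOVA mean squares
and verified against `aov()` to $10^{-10}$; ICC(2,1) is exposed as an
option.  The inventory covers every FC pair and regional variance at
scales 3–5 — at the study's 262 usable regions that is 102,573 FC and
786 variance measures — with summary statistics and z-scored regional
maps.

Feature selection picks 30 measures by one of four rules (correlation,
ICC, combined z-sum, dynamic high-minus-low sequence change), after
excluding measures with |skewness| > 1, with ties broken by measure id.
The dynamic rule's ambiguity ("largest difference in correlations
across sequences") is resolved as: max over behavior scales of
(max minus min correlation across sequences), with the selected value
being the high-minus-low sequence difference; alternatives would be
easy to add but only one is shipped.  Selections are frozen on the
training cohort before touching the testing cohort.

PLS is the symmetric (PLS-SVD) variant: singular vectors of the
cross-covariance of column-standardized matrices, which is the variant
that matches salience vectors and per-component score correlations; a
first-component cross-check against an independent implementation
(`mixOmics::pls`, canonical mode) is part of the test suite.
Permutation inference permutes rows of Y only (5000 by default) and
compares each component's observed score correlation to the same-rank
permuted distribution, $p = (1+\#\{r^* \ge r\})/(B+1)$.  Because three
of the four selection rules use the behavior data, training-sample p
values are anti-conservative by construction; the suite demonstrates
this leakage and shows that frozen-feature testing-cohort p values are
calibrated.  Correspondence reports sign-aligned per-component and
offset-by-one salience correlations, and a PCA-loading correspondence
serves as the factor-stability proxy.

# The synthetic cohort generator

Each subject yields six sequences of 330, 330, 240, 240, 504 and 180
time points (1824 in all) at TR = 1.5 s over 278 regions by default.
Regional signal is a low-rank spatial model: a global mode with region
weights in (0.5, 1.5), eight local modes with Gaussian mixing, plus a
broadband artifact that dominates the 60-series noise pool (the CompCor
target) and leaks weakly into regions, plus white noise.  Temporal
sources are white noise split into the six dyadic octave bands with
brickwall FFT filters and reweighted to equal per-band variance (a 1/f
shape), so per-scale variances are controlled exactly and the
low-frequency component is stored for oracle tests.

Between-subject structure, all log-normal: a global amplitude factor
(`subject_amp_sd`, default 0.28), per-mode amplitudes stable across
sequences (`mode_amp_sd`, default 0.4) — the source of reliable,
region-patterned FC individual differences, without which ICC profiles
would not replicate across cohorts — and motion amplitude and
high-frequency-share factors (`subject_motion_sd`, default 0.3).
Cohort-level spatial structures are drawn from a separate
`structure_seed` held fixed by default, so independently seeded cohorts
share "anatomy" the way two samples scanned with one parcellation do;
cross-cohort replication properties (ICC profiles, motion loadings,
effect-size profiles) are meaningful only under this sharing.

Planted effects and their defaults, chosen once as realistic for this
kind of study and stated here rather than attributed to any dataset:

* `group_lowfreq_scale = 1.25`: group 1's low-frequency (scales 4–6)
  content — signal *and* idiosyncratic noise in that band — is scaled
  multiplicatively.  With the default amplitude heterogeneity this
  corresponds to a group difference of roughly $d = 0.8$ on
  low-frequency log-variance summaries, the upper end of what such
  studies report.  Scaling the in-band noise as well makes the planted
  effect a pure amplitude scaling, which per-region z-scoring removes;
  if only latent signal were scaled, a signal-to-noise difference would
  survive z-scoring and the scaled-mode null would be violated.
* `order_variance_slope = 0.05` per position (variance multiplier
  $\sqrt{1 + 0.05(p-1)}$), `order_meancorr_slope = -0.03` on the
  global-mode coupling: variance rises and mean correlation falls
  across the session.
* `hf_motion_ratio_effect` (default 0): additive group shift of the log
  high/low-frequency FWD variance ratio of the Gaussian base driving
  the gamma-marginal FWD copula.
* FWD: gamma(shape 2, scale 0.1 mm) marginal, AR(1) low-frequency
  component, Bernoulli spikes (rate 0.002) adding >1 mm excursions.
* Behavior: 26 scales from a deterministic block-loading factor model
  (4 factors by default) plus age, sex (= group) and education — 29
  analysis columns.

All randomness flows from `seed` through a fixed stream order
(structures from `structure_seed`; motion, BOLD, behavior from
`seed + 1..3`, subjects in order), so output is bit-identical under a
seed.  What the generator does **not** emulate: spatial autocorrelation
within parcels, physiological (cardiac/respiratory) waveforms, task
structure, scanner-specific spectra, non-stationarity beyond the order
drifts.  Passing tests therefore certify the estimators and the
inferential logic under the stated model, not robustness to every
property of real data.

# Problem sizes and numerical choices

The test suite and the acceptance script run at reduced problem sizes
chosen to keep the full run in the minutes range while leaving the
statistical properties testable: unit tests use 8–60 subjects and 10–24
regions with shortened sequences; calibration suites use 200–300
replicates at 150–500 permutations; the end-to-end recovery suite uses
the full sequence lengths with 50 subjects per group and 16 regions over
10 replicates; the acceptance script's train/test experiment uses 55
subjects per group (the study-scale cohort of ~110) and 24 regions.  Power-law fitting uses analytic-free
multi-start NLS as above; gamma fitting solves the profile likelihood by
`uniroot` (zeros replaced by half the smallest positive value); Hurst
estimator 2 inverts the exact expected variance ratio of the
smoothed-and-differenced filter under fBm (the naive ratio is biased by
the smoothing filter's response), and estimator 3 regresses log2 MODWT
variance on scale over scales 2 and deeper, where the octave-band
approximation holds, with $H = \text{slope}/2$.  Degenerate inputs
(constant series, rank-deficient pools, zero-variance regions) raise
errors or drop-with-warning paths that the tests exercise.

# Known limitations

Broadband eigenvalue scaling tests lose power at small region counts;
the low-frequency band carries the planted effect there.  Components 4–5
of the motion PCA do not replicate across synthetic cohorts (the
generator has only two latent motion dimensions); components 1–3 do.
Training-sample PLS inference is anti-conservative whenever selection
used behavior — by design, valid inference is restricted to the frozen
testing stage.  The t-to-z mapping in topography applies no
autocorrelation correction; with the 128-s high-pass and parcel-level
max-statistic inference this is adequate for the synthetic model but
would understate df loss in strongly autocorrelated real data.
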