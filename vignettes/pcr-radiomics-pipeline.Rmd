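---
title: "Predicting pathologic complete response from DCE-MRI radiomics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pathologic complete response from DCE-MRI radiomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Neoadjuvant chemotherapy (NAC) is given before surgery in large or locally
advanced breast cancers; its best outcome is pathologic complete response
(pCR), the absence of residual invasive tumour in the surgical specimen.
Identifying likely complete responders *before* treatment would support
personalised therapy. `pcrradiomics` implements a complete analysis chain
for this prediction task on cohorts of the typical single-institution
scale (tens of patients): quantitative shape/texture descriptors
(radiomics) of the lesion on pre-treatment dynamic contrast-enhanced MRI
are combined with clinical, radiological (BI-RADS descriptors, ADC,
PET SUVmax) and histological (Ki-67, ER, PgR, HER2) covariates, and every
covariate subset is evaluated as a predictive model.

Because the motivating cohort is private, the package ships a synthetic
cohort generator and lesion phantoms so that the entire chain is testable
and reproducible end to end.

## Radiomic features

Five features are computed, preceded by a fixed preprocessing chain:

1. **Intensity normalization** — the whole volume is linearly rescaled to
   mean 0 and standard deviation 100 (population convention). MR
   intensities have no absolute scale; this puts the fixed-width texture
   binning on a comparable footing across subjects. An ROI-only variant is
   available (`roi_only = TRUE`) since the choice is not standardized.
2. **Isotropic resampling** to 0.90 mm cubes. Images use cubic B-spline
   interpolation: coefficients are obtained by solving the banded
   collocation system with mirror boundary, so the interpolant passes
   through the samples exactly and reproduces polynomials up to degree 3
   (constants and linear ramps survive resampling; the mirror boundary
   perturbs only a geometrically-decaying neighbourhood of the volume
   faces). Masks use nearest-neighbour interpolation — B-splines would
   produce non-binary values.
3. **Discretization** of the masked voxels into a fixed bin count of 8
   equal-width gray levels spanning the ROI range (the top value is
   assigned the top level; a constant ROI is flagged degenerate).

The features, with their conventions:

* **F1 sphericity** `(36 pi V^2)^(1/3) / A` from a triangulated mask
  surface. The 0.5 iso-surface of the binary mask is extracted by
  marching tetrahedra (six Kuhn tetrahedra per cell — a
  translation-consistent decomposition, hence a watertight mesh) and
  low-pass filtered with 60 Taubin lambda/mu iterations
  (lambda = 0.5, mu = -0.53). The smoothing removes the half-voxel
  staircase corrugation of a binary iso-surface, which otherwise inflates
  the surface area by some 25% and depresses sphericity for every shape;
  with it, a digital ball of radius 20 voxels measures within 2–3% of
  sphericity 1. The trade-off is that structures close to one voxel thick
  are smoothed toward their skeleton, shrinking their mesh volume; for
  such masks the raw mesh (`smooth_iterations = 0`) is the better
  estimate, and orderings (ball above rod) are preserved either way.
* **F2 kurtosis** — Pearson (non-excess) population moments
  `m4 / m2^2` of the continuous masked intensities after normalization
  and resampling; a Gaussian ROI gives 3. No bias correction.
* **F3 GLDM dependence variance** — the dependence of a voxel is the
  count of its 26-neighbours (inside the mask) whose gray level differs
  by at most `alpha = 0`, plus one for the voxel itself; F3 is the
  variance of the dependence under the normalized gray-level dependence
  matrix. The neighbours-only convention is exposed via
  `include_center = FALSE` because the definition is not universal.
* **F4 GLRLM long-run high-gray-level emphasis** — per scan direction,
  maximal runs of equal gray level build the run-length matrix `P(i, j)`;
  the statistic `sum(P i^2 j^2) / Nr` is averaged, unweighted, over the
  13 unique 3D directions.
* **F5 GLSZM high-gray-level zone emphasis** — zones are 26-connected
  components of constant gray level; `sum(P i^2) / Nz`.

F2, F4 and F5 are computed on the dynamic (post-contrast) channel, F1 and
F3 on the subtracted (enhancement) channel. The channels are named
generically: the source acquisitions differ between reports of this
design, so `extract_features()` records the channel of each feature
rather than hard-coding an acquisition index. Every texture statistic is
validated in the test suite against an independent brute-force oracle
(neighbour loops, run scanners, flood fill) on randomized small ROIs.

## Univariate screening

`make_table1_report()` applies Welch's two-sample t-test to continuous
covariates and Fisher's exact test (two-sided, Freeman–Halton convention:
the probabilities of all tables no more probable than the observed one are
summed) to categorical ones, by pCR status. `welch_t_from_summaries()`
accepts published per-group (n, mean, sd) triplets so that summary tables
can be re-tested without raw data; the Welch–Satterthwaite degrees of
freedom are left non-integer. Correlation screens use Spearman rank
correlation with average ranks.

## Feature reduction

The radiomic block is reduced by L1-penalized logistic regression:
minimize `(1/n) * negative log-likelihood + lambda * sum(|beta|)` with an
unpenalized intercept, over 100 log-spaced penalties from the analytic
`lambda_max` (where the solution is all-zero) down to `1e-3 * lambda_max`.
Covariates are standardized with the population (n-denominator) standard
deviation, recorded in the output. `lambda` is chosen by the minimum mean
leave-one-out cross-validated binomial deviance — strictly the minimizer,
no one-standard-error rule. Solutions are verified against the KKT
conditions of the penalized objective in the test suite. The reduction is
run on the radiomic features alone (the analysis treats clinical and
histological covariates as given); a joint reduction can be obtained by
passing any covariate matrix to `lasso_reduce()`.

## The exhaustive model search

For a variable group (the five published groups are `G1` clinical +
radiological, `Rad` = F1–F5, `Hist`, `NoRad = G1 + Hist`,
`All = G1 + Rad + Hist`), `run_group_search()` enumerates every non-empty
covariate subset — a categorical covariate moves with all of its dummy
columns, which is what makes 18 covariates yield `2^18` subsets — and
evaluates each with one of three classifiers: logistic regression, linear
support-vector regression on the 0/1 outcome (score = raw regression
output), or random forest (score = out-of-fold vote fraction).

* **Dual cross-validation.** The model AUC is the mean of the
  leave-one-out AUC and the AUC of one fixed, seeded, unstratified
  partition into folds of two. Averaging two schemes stabilises the
  estimate.
* **Hyperparameters** (SVR cost over `2^-5 … 2^5`, RF tree count over
  100–1000) are tuned once on the full-group model by LOOCV AUC and then
  frozen for the whole search; ties go to the smaller value.
* **Inference.** The DeLong variance of the pooled leave-one-out scores
  gives the confidence interval; significance against AUC = 0.5 uses the
  Mason–Graham identity between the AUC and the Mann–Whitney U statistic
  (exact rank-sum null for `n1*n0 <= 1e4` without ties, tie-corrected
  normal approximation otherwise). All p-values of a run are
  Benjamini–Hochberg adjusted together.
* **Ranking** is by mean AUC, ties broken by smaller subsets then
  lexicographic subset label, so reports are deterministic. The six best
  models define the per-covariate inclusion frequencies used as feature
  importance.
* **Coefficient aggregation.** Each evaluated subset also receives a
  full-data logistic fit; for each design column the coefficients are
  combined as `m_j = sum(m_ij / s_ij^2) / sum(1 / s_ij)` — a weighted
  mean of the standardized ratios `m_ij / s_ij`, the convention this
  analysis standardizes on, with `|m_j| > 1` read as a relevant signed
  association. The textbook inverse-variance mean
  (`aggregation = "inverse_variance"`) is provided as an alternative.
* **Subset cap.** Beyond `subset_cap` (default `2^14`) subsets, a seeded
  uniform sample of that size is evaluated and the report is flagged
  `truncated`. An exhaustive `2^18`-subset sweep per classifier is
  possible but disproportionate for the package's test cohorts; the cap
  makes the cost explicit and reproducible.

### The null behaviour of pooled leave-one-out scores

A property worth knowing when reading the reports: when the outcome is
independent of all covariates, pooled leave-one-out scores are *anti*-
concordant with the outcome. Leaving out a positive subject lowers the
training prevalence, hence that subject's out-of-fold score; with no
signal to dominate this leakage the LOO AUC falls well below 0.5, and the
two-sided Mason–Graham p legitimately flags the anti-concordance. The
acceptance checks therefore calibrate the Mason–Graham test on
exchangeable scores (where its p-value is verifiably uniform) and bound
the null search one-sidedly: no null model may approach the AUC regime of
a planted signal. Real signal reverses the picture quickly — in the
planted-signal cohorts the informative covariates dominate the best-model
frequencies.

## The synthetic cohort generator

`generate_cohort()` emulates a 20-responder / 40-non-responder cohort.
Group-conditional means and standard deviations of the six
clinical/histological continuous covariates, and the category frequencies
of all seven categorical covariates, reproduce the published per-group
summaries of the motivating cohort. The five radiomic features are not
summarized per group in the source; their defaults are lesion-scale
values chosen once — sphericity near 0.7, kurtosis near 3, dependence
variance in the teens, long-run emphasis around 10^2, zone emphasis
around 10 — with group contrasts following the signs of the reported
aggregated coefficients (responders: higher F1/F2, lower F3/F4).

Deliberate simplifications, and what they imply for the tests:

* Continuous covariates are Gaussian per group, even the bounded
  percentage scales (an optional `truncate` clamps them); categorical
  covariates are multinomial. Real marginals are skewed and bounded.
* Covariates are independent within group by default (the motivating
  analysis found its continuous covariates effectively independent); an
  optional correlation matrix can be supplied. Real radiomic features are
  correlated with each other and with shape descriptors.
* With a planted `outcome_model`, covariates are drawn from the pooled
  distribution and the outcome follows a logistic model on standardized
  covariates — the ground truth used by the recovery tests.

Passing tests on these cohorts demonstrates that the chain recovers known
planted structure under idealised sampling; it does not certify
performance on real images, where segmentation, scanner effects and
inter-feature correlation intervene.

Lesion phantoms (`generate_phantom()`) are ellipsoids (centre-of-voxel
inclusion) on anisotropic grids with constant, linear-gradient or
Gaussian-correlated textures plus i.i.d. noise, and a paired
dynamic/subtracted channel layout. They exercise the geometry-sensitive
code (resampling, meshing, run/zone statistics): a longer texture
correlation length must raise F4, a sphere must out-score a rod on F1.

## Numerical choices

* Logistic fits inside the search run in compiled code (IRLS with a
  relative ridge of `1e-9` on the normal equations and the linear
  predictor clamped to ±15, so separable subsets converge to a finite
  effectively-0/1 fit); `stats::glm` reproduces its solutions to the
  reported tolerance in the tests and serves as the per-fold oracle.
* The Mason–Graham exact/approximate switchover at `n1*n0 = 1e4` keeps
  cohorts of the package's scale exact.
* Standardization conventions: population sd inside the LASSO and the
  generator's planted model; per-fold standardization inside SVR (its
  training-fold scaling); logistic regression and random forests are
  invariant to affine covariate scaling, so no per-fold scaling is
  applied there.
* Problem sizes in the test suite and acceptance script are scaled to the
  package's cohort scale: 100 randomized ROIs for the texture oracles, 50
  planted-recovery seeds at n = 200 for the LASSO, 500 simulations for
  the null calibration, searches capped at `2^10` subsets.

## Limitations

* Only the five retained radiomic features are implemented, not a full
  feature catalogue; no wavelet/LoG filtered variants, no 2D features.
* DICOM ingestion, segmentation, SUVmax and ADC computation are out of
  scope; volumes and masks enter as NIfTI/NRRD-style grids.
* The sphericity mesh smoothing trades thin-structure fidelity for
  staircase removal (see above).
* The published headline AUCs of the motivating study depend on its
  private images; the package reproduces the statistical layout and the
  printed univariate table, and validates the modelling chain on
  synthetic data with known truth.
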