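# pcrradiomics

Predictive modelling of **pathologic complete response (pCR) to
neoadjuvant chemotherapy** in breast cancer, from DCE-MRI radiomics
combined with clinical, radiological and histological covariates.

Before treatment, each patient contributes a lesion image pair (a
post-contrast *dynamic* volume and a pre/post *subtracted* volume), a
segmentation mask, and a covariate table: Age, ADC, PET SUVmax, Ki-67,
ER, PgR (continuous), plus Grade, HER2, BI-RADS Shape / Margin / internal
enhancement / kinetic curve type, and lesion type (categorical). The
package implements the full analysis chain as reusable, tested
components:

* **Radiomics** — preprocessing (normalization to mean 0 / sd 100,
  isotropic 0.90 mm cubic B-spline resampling, fixed-bin-count
  discretization to 8 gray levels) and five features:
  mesh **sphericity** `(36πV²)^{1/3}/A` (F1), Pearson **kurtosis**
  `m₄/m₂²` (F2), GLDM **dependence variance** (F3), GLRLM **long-run
  high-gray-level emphasis** `mean₁₃ Σ P(i,j) i²j² / Nr` (F4) and GLSZM
  **high-gray-level zone emphasis** `Σ P(i,s) i² / Nz` (F5).
* **Univariate screening** — Welch t-tests (also directly from published
  n/mean/sd summaries) and two-sided Fisher exact tests on r×c tables.
* **Feature reduction** — L1-penalized logistic regression
  (`(1/n)·negloglik + λΣ|β|`), λ chosen by minimum mean LOOCV binomial
  deviance.
* **Exhaustive model search** — every covariate subset of a variable
  group (G1 clinical/radiological, Rad = F1–F5, Hist, NoRad, All) ×
  three classifiers (logistic regression, linear SVR, random forest),
  scored by the mean of leave-one-out and fixed leave-two-out
  cross-validated AUC; DeLong confidence intervals; Mason–Graham
  significance of AUC vs 0.5 via the Mann–Whitney identity;
  Benjamini–Hochberg correction; best-6 inclusion frequencies; and
  precision-weighted coefficient aggregation
  `m_j = Σᵢ m_{ij}/σ_{ij}² / Σᵢ 1/σ_{ij}`.
* **Synthetic data** — a cohort generator reproducing the published
  20-responder / 40-non-responder group summaries (or planting a known
  logistic signal), and textured ellipsoid lesion phantoms — so every
  stage is testable without patient data.

## Worked example

```r
library(pcrradiomics)

coh <- generate_cohort(synthetic_config(seed = 7))   # 20 pCR / 40 non-pCR

head(make_table1_report(coh)[, c("covariate", "summary_pos",
                                 "summary_neg", "test", "p")], 4)
#>   covariate    summary_pos    summary_neg    test       p
#> 1       Age 49.6 (+/-8.78) 53.9 (+/-11.6) Welch t 0.11120
#> 2       ADC   801 (+/-283)   823 (+/-176) Welch t 0.75514
#> 3   PET_SUV 7.42 (+/-3.89) 7.43 (+/-5.47) Welch t 0.99259
#> 4      Ki67   43.5 (+/-24) 22.2 (+/-12.3) Welch t 0.00104
```

Per-covariate summaries by response group with the appropriate test:
here Ki-67 separates responders strongly (p ≈ 0.001), Age does not —
the expected pattern for this disease setting.

```r
red <- lasso_reduce(as.matrix(coh[paste0("F", 1:5)]), coh$pCR)
red$selected
#> [1] "F1" "F2" "F3" "F4"
```

The L1 path at the LOOCV-optimal penalty keeps four of the five radiomic
features of this synthetic cohort (F5 carries almost no group contrast by
construction).

```r
r <- run_group_search(coh, "Hist", classifier = "Logit", seed = 7)
r
#> search_report: Hist / Logit - 15 subsets (exhaustive)
#> best model: ER+Ki67+PgR auc_mean = 0.867
#> mean adjusted p (best 6): 0.00011
round(r$frequency, 2)
#> Ki67   ER  PgR HER2
#> 1.00 0.67 0.67 0.50
```

All 2⁴−1 subsets of the histological block are ranked by dual-CV AUC;
Ki-67 appears in every one of the six best models. Feature extraction
runs on images (here a phantom):

```r
ph <- generate_phantom(phantom_spec(texture = "correlated",
                                    corr_length = 3, seed = 2))
round(extract_features(ph$dynamic, ph$subtracted, ph$mask), 3)
#>      F1      F2      F3      F4      F5
#>   0.907   6.357  51.275 306.457  20.344
```

A shell entry point wrapping the same functions is installed at
`inst/scripts/pcr_pipeline.R` (subcommands `run`, `simulate`, `table1`,
`reduce`, `search`, `extract`).

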