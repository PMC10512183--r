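# fibrospec

FTIR spectral phenotyping of cultured cells in R: from hyperspectral
absorbance images to band-ratio statistics and sparse PLS-DA
classification, with a synthetic three-group cohort generator that
provides ground truth for every stage.

## Who this is for

Vibrational-spectroscopy and chemometrics researchers who profile
patient-derived cell cultures (e.g. skin fibroblasts from
neurodegenerative-disease cohorts) by FTIR microspectroscopy and need a
reproducible, testable version of the standard analysis chain:

1. **Pre-processing** (`preprocess_sample()`): excision of the CO₂ region
   (2700–2000 cm⁻¹) → rubber-band (lower convex hull) baseline → k-means
   cell/background segmentation → spectral binning → EMSC scatter
   correction with a van de Hulst Mie extinction basis → Savitzky–Golay
   smoothing → per-sample averaging → vector normalization → SG second
   derivative → vector normalization.
2. **Band quantification** (`integrate_band()`, `compute_ratio_panel()`,
   `locate_band_minima()`, `compare_peak_positions()`): trapezoidal areas
   over the 14 standard mid-IR band regions (amide A/B/I/II/III, the C–H
   stretches, carbonyl ester, acyl chain, mixed region), a 12-ratio panel,
   and second-derivative peak positions/counts.
3. **Group statistics** (`ratio_panel_stats()`): per-ratio one-way ANOVA
   with Tukey HSD (studentized-range p-values), Shapiro–Wilk and
   Brown–Forsythe diagnostics, star annotations (`*`/`**`/`***` at
   0.05/0.01/0.001).
4. **Classification** (`splsda_fit()`, `tune_splsda()`, `cv_auroc()`):
   sparse PLS-DA on second-derivative spectra — per-component
   soft-thresholded variable selection (`keepX`), centroid-distance
   prediction, stratified repeated cross-validated tuning by balanced
   error rate, one-vs-rest AUROC by Mann–Whitney concordance.

The core model: per component `h`, the X-weight is the dominant singular
vector of `XᵀY` soft-thresholded to exactly `keepX[h]` nonzero entries,
scores `t = Xw`, and both `X` and `Y` are deflated by regression on `t`
(PLS2 regression mode). With `keepX = p` this is exactly dense PLS-DA.

Because raw patient spectra are typically unavailable, the
`synthetic_cohort_config()` / `generate_cohort()` generator builds
three-group cohorts of cell images with known injected effects (band
amplitude multipliers, center shifts, dropped sub-peaks, baseline, CO₂
band, Mie-like ripple, noise) so that accuracy, calibration and power are
all measurable.

## Worked example

```r
library(fibrospec)

cfg    <- synthetic_cohort_config(seed = 42)   # 3 x 10 samples, default effects
cohort <- generate_sample_spectra(cfg)         # per-sample spectra (fast mode)

panel <- compute_ratio_panel(cohort)
stats <- ratio_panel_stats(panel)
head(stats$anova[, c("ratio", "F", "p", "stars")], 4)
#>                         ratio      F        p stars
#> 1 carbonyl_ester/total_lipids  50228 6.24e-49   ***
#> 2   carbonyl_ester/acyl_chain  28974 1.05e-45   ***
#> 3     carbonyl_ester/ch3_asym  44457 3.24e-48   ***
#> 4            amide_I/amide_II 449073 8.98e-62   ***

subset(stats$tukey, ratio == "carbonyl_ester/total_lipids")[
  , c("group1", "group2", "diff", "p_adj", "stars")]
#>   group1 group2    diff    p_adj stars
#> 1    ALS   CTRL  0.0209 4.22e-15   ***
#> 2    ALS     MS -0.0071 4.22e-15   ***
#> 3   CTRL     MS -0.0280 4.22e-15   ***

compare_peak_positions(cohort, "amide_I")$shifts   # injected: +4 cm^-1
#> ALS  MS
#>   4   4

roc <- cv_auroc(cohort_matrix(cohort, "second_derivative"),
                cohort_groups(cohort),
                n_components = 3, keepX = c(60, 40, 20),
                folds = 3, repeats = 10, seed = 1)
round(roc$auc, 3)
#>  ALS CTRL   MS
#>    1    1    1
```

Reading the output: the carbonyl-ester/total-lipids ratio is lower in the
MS-like group (`diff` CTRL→MS negative) and higher in CTRL — the injected
×0.8 carbonyl reduction; the amide I second-derivative minimum sits
4 cm⁻¹ higher in both disease-like groups (the injected α-helix shift);
and cross-validated one-vs-rest AUROC is 1 for every group under the
default effect sizes. F statistics are large because fast-mode cohorts
carry only pixel-averaged noise; the full image pipeline
(`generate_cohort()` + `preprocess_sample()`, or `run_pipeline()`) adds
baseline, ripple and CO₂ artifacts.

The end-to-end driver writes every intermediate table plus a run report:

```r
report <- run_pipeline(list(seed = 1), outdir = "fibrospec_out")
```

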