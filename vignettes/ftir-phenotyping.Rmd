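---
title: "FTIR spectral phenotyping of cultured fibroblasts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FTIR spectral phenotyping of cultured fibroblasts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrospec)
```

# The problem

FTIR microspectroscopy records, at every pixel of a cell culture image, a
mid-infrared absorbance spectrum (here 3500–950 cm⁻¹). Protein backbone
vibrations (the amide A/B/I/II/III bands), lipid C–H stretches
(3000–2800 cm⁻¹), the lipid carbonyl ester (~1740 cm⁻¹), the acyl-chain
scissoring/deformation region (1470–1430 cm⁻¹) and a mixed
carbohydrate/phosphate region (1300–1000 cm⁻¹) carry quantitative
biochemical information. Comparing patient-derived fibroblast lines across
diagnostic groups then reduces to three statistical tasks, all implemented
here:

1. **Pre-processing** raw hyperspectral images into one representative
   absorbance spectrum and one second-derivative spectrum per sample.
2. **Band quantification**: integrating named band regions, forming ratio
   panels, testing group differences (one-way ANOVA, Tukey HSD), and
   reading peak positions/counts off the second derivative.
3. **Classification**: sparse PLS-DA on the second-derivative spectra with
   cross-validated tuning, centroid-distance prediction and one-vs-rest
   AUROC.

Because raw patient spectra are generally not public, the package ships a
synthetic cohort generator that emulates the statistical structure of such
a study; every pipeline stage can therefore be validated against known
injected effects.

# The synthetic cohort generator

`synthetic_cohort_config()` describes a three-group cohort (CTRL/MS/ALS-like
labels) of hyperspectral images. Defaults, chosen once as the study
conditions:

* axis 950–3500 cm⁻¹ at 4 cm⁻¹ spacing (instrument-typical resolution is
  ~8 cm⁻¹; the point spacing is a modeling choice, exposed in the config);
* 10 samples per group, 16 × 16-pixel images, 40% background pixels
  (`round(0.4 * 256) = 102`);
* a 15-band Gaussian band library (`default_band_library()`) with amide I
  (~1652 cm⁻¹) dominant, matching real cell spectra;
* artifacts: a linear-in-wavenumber baseline with per-image jitter, a CO₂
  band at 2350 cm⁻¹, a per-pixel sinusoidal Mie-like ripple
  (amplitude 0.02 AU, period 900 cm⁻¹, random phase), white noise
  (SD 0.005 AU), and a per-sample log-normal intensity factor
  (SD 0.1 on the log scale) for biological between-sample variability;
* group effects (`default_group_effects()`): the disease-like templates
  reduce the carbonyl ester (×0.8 MS-like, ×0.85 ALS-like), raise amide I
  (×1.15 / ×1.10) and shift it +4 cm⁻¹, drop the ~1435 cm⁻¹ acyl sub-peak
  (two acyl peaks in CTRL, one in disease), and raise/shift amide A; the
  ALS-like template additionally perturbs the mixed-region phosphate band
  so that all three groups are mutually separable, mirroring the reported
  structure of such cohorts.

The whole cohort is a pure function of the config seed: per-sample seeds
are drawn once from it, and truth records store the group band model
(noise-free and biological-factor-free), so truth is identical across
seeds while noise differs.

Effect sizes are qualitative templates for validation and power studies,
not estimates of real biology — published studies report directions and
significance, not band-model amplitudes.

**Fast cohort mode.** `generate_sample_spectra()` skips the image stage and
draws per-sample mean spectra directly (group truth × biological factor +
pixel-averaged noise, `noise_sd / sqrt(n_cell_pixels)`). It emulates the
output of an ideal pre-processing chain and is used for the large
calibration and power simulations (hundreds of cohorts), where image-level
artifacts would only add runtime; the image path itself is validated
end-to-end separately. Fast-mode spectra have no baseline, ripple or CO₂
artifacts — conclusions about artifact *correction* never rest on them.

# The pre-processing chain

`preprocess_sample()` applies, in order: excision of 2700–2000 cm⁻¹ (CO₂
region, low biological signal) → rubber-band baseline per pixel → k-means
segmentation (cell vs background) → spectral binning → EMSC scatter
correction → Savitzky–Golay smoothing → averaging over cell pixels →
vector normalization → Savitzky–Golay second derivative → vector
normalization. Parameters live in `preprocess_params()`.

Notable numerical choices:

* **Axis orientation and segments.** Axes are stored ascending regardless
  of file order. Excision splits the axis into retained segments; the
  baseline, binning, filtering and integration all operate per segment, so
  no operation ever bridges the excised gap (a property test asserts
  this).
* **Rubber-band baseline** = lower convex hull of each segment,
  interpolated between support points. The hull comes from
  `grDevices::chull` with a lower-boundary extraction; correctness is
  tested against an O(n²) gift-wrapping oracle. Corrected spectra are
  nonnegative with at least two exact zeros per segment.
* **Segmentation** clusters pixel spectra with seeded `stats::kmeans`
  (restarts make it deterministic given the seed); the cluster with the
  higher mean total absorbance is labeled "cell", since cells absorb more
  than near-background. `k = 2` by default (the cluster count is not
  dictated by the underlying method; it is a config value). Identical
  pixels degenerate to a single warned "cell" cluster.
* **Binning** averages `bin_factor = 2` adjacent axis points (axis mean,
  intensity mean), remainder kept as a smaller bin. Binning is spectral,
  applied to cell-pixel spectra after selection; note that on a 4 cm⁻¹
  axis this halves resolution to 8 cm⁻¹, below what is needed to resolve
  the 1455/1435 cm⁻¹ acyl sub-peaks — peak-counting analyses should use
  `bin_factor = 1` or the fast cohort mode.
* **Scatter correction** is a one-pass clustered EMSC: spectra are k-means
  clustered (interface parity with clustered-correction toolchains; the
  fitted design is identical in every cluster, so clustering does not
  change the output), then each spectrum `s` is fit as
  `s ≈ a·reference + polynomial(ν) + Mie components` and corrected to
  `(s − polynomial − Mie)/a`. The Mie basis is the PCA compression (7
  components) of van de Hulst extinction curves
  `Q = 2 − (4/ρ)sin ρ + (4/ρ²)(1 − cos ρ)`, `ρ = 4πr(m−1)ν`, over a grid
  of radii (2–10 µm) and refractive indices (1.1–1.5). Spectra whose
  fitted `a` is non-positive are flagged uncorrectable and passed through
  with a warning. The full iterative resonant-Mie refinement is out of
  scope.

  *Known limitation (measured):* with a protein/carbohydrate reference
  that lacks the lipid bands, the flexible Mie basis absorbs part of the
  narrow-band lipid structure, and does so group-dependently — on
  noise-free synthetic cohorts the injected carbonyl/total-lipids contrast
  of 0.80 is measured as ~0.61 through the `emsc_mie` pipeline, while
  `emsc_poly` recovers it within ~2% (orthogonalizing the basis against
  the reference does not help; the absorbed structure is orthogonal to the
  reference). Effect *directions* and significance are preserved, but
  absolute ratio contrasts from the Mie mode carry this bias; use
  `emsc_poly` when no oscillatory distortion is present.
* **Savitzky–Golay** filters are implemented as per-segment local
  polynomial least squares with truncated-window fits at the edges, so
  they are exact on polynomials up to the fit order everywhere (including
  edges). Derivatives are scaled by the physical axis step
  (second-derivative units AU·cm²), making magnitudes comparable across
  binning factors. Defaults: smoothing window 5 / order 2; derivative
  window 7 / order 2 / derivative 2, with an alternative window 15 /
  order 5 preset for robustness re-analysis. Note that a 7-point window on
  a 4 cm⁻¹ axis *attenuates* narrow bands: the second-derivative amplitude
  of a Gaussian band is recovered within 2% only for widths σ ≳ 45 cm⁻¹,
  with attenuation growing as 1/σ² (≈30% at σ = 10). Peak *positions* are
  unaffected; derivative band *amplitudes* should be compared only across
  spectra filtered with identical settings.
* **Vector normalization** divides by the Euclidean norm (applied after
  averaging, and again after differentiation — in that order).

# Band quantification and group statistics

`default_band_table()` fixes the fourteen standard band regions
(closed intervals, snapped to measured axis points — no endpoint
interpolation, since region bounds are coarser than the point spacing).
`integrate_band()` uses the trapezoidal rule within one segment.
`default_ratio_panel()` defines the eight primary ratios (carbonyl ester
over total lipids / acyl chain / asymmetric CH₃ / mixed region; amide I
over amide II / amide A / total lipids / carbonyl ester) plus four
supplementary lipid-order ratios (membrane polarity, chain packing,
saturation degree, chain length). The supplementary ratios are written in
the literature as point ratios ("~2920/2870"); they are implemented as
ratios of integrated areas of the C–H stretch regions containing those
wavenumbers, consistent with how the primary ratios are integrated.

Per ratio, `ratio_panel_stats()` runs a one-way ANOVA (classical
between/within decomposition) with Tukey HSD post-hoc comparisons
(Tukey–Kramer standard errors for unbalanced groups; adjusted p from
`stats::ptukey`, which evaluates the studentized-range distribution by
deterministic numeric integration), plus Shapiro–Wilk normality per group
and a Brown–Forsythe homoscedasticity test (ANOVA on absolute deviations
from group medians). Diagnostics are reported, never used to gate the
ANOVA. No multiplicity correction across the panel by default — each ratio
is reported per-ratio, as is conventional in this literature; a
Benjamini–Hochberg column is available via `p_adjust = "BH"`. Stars follow
the strict thresholds ns / * / ** / *** at 0.05 / 0.01 / 0.001.

Second-derivative peaks: band centers are negative local minima of the
second derivative. `locate_band_minima()` requires a minimum to be lower
than both neighbors, negative (this excludes the dips between positive
side lobes of adjacent bands), and topographically prominent above 5% of
the region's dynamic range (a noise guard; configurable).
`compare_peak_positions()` tracks the deepest minimum per sample (ties
toward the lower wavenumber), summarizes positions per group, and reports
shifts against the reference group (positive = toward higher wavenumbers).
Peaks are located per sample and then group-summarized, rather than on the
group-average spectrum; per-sample positions give a dispersion estimate
and are robust to a single outlying sample.

# Sparse PLS-DA

`splsda_fit()` implements PLS2 regression-mode sPLS-DA: the class vector
is dummy-coded, X columns centered and unit-variance scaled (scaling is a
toggle; on by default), Y columns centered. Per component the dominant
singular pair of `XᵀY` gives the X-weight, which is soft-thresholded so
exactly `keepX[h]` entries are nonzero (threshold = the (keepX+1)-th
largest magnitude; exact ties resolved toward the lower variable index),
renormalized, and both X and Y are deflated by regression on the scores.
Each weight vector's largest-magnitude entry is made positive so loadings
are reproducible. With `keepX = p` this reduces exactly to dense NIPALS
PLS-DA (tested to 1e-8), and the dense scores match the mixOmics reference
implementation.

Prediction projects new samples through `W(PᵀW)⁻¹` and assigns the nearest
class centroid in Euclidean score distance (ties to the lexicographically
first class). `splsda_predict()` returns three score sets: latent
coordinates, indicator predictions (`yhat`), and per-class decision values
(negative centroid distances). Cross-validated ROC analysis ranks the
decision values: with few components a class whose centroid lies between
the others is not rankable by its indicator prediction even when
classification is perfect, whereas centroid distances always are.

`tune_splsda()` chooses keepX per component sequentially (earlier
components frozen at their chosen values) by stratified M-fold
cross-validation repeated with re-drawn folds, scoring the balanced error
rate (mean over classes of within-class error — with balanced groups this
equals overall error, but the balanced criterion is the declared one).
Ties go to fewer retained variables, then fewer components. The default
grid {5, 10, 20, 40, 60, 80} spans the usual range for spectral data; the
number of folds (3) suits 10 samples per class. On the default synthetic
cohort the tuned model is deliberately small (often a single component at
`keepX = 5` reaches zero cross-validated error — the injected effects are
strong and low-rank); the published-scale shape
(`n_components = 3, keepX = c(60, 40, 20)`) is accepted whenever the
variable count allows and is used for the AUROC acceptance check.

`auroc()` computes one-vs-rest AUROC as the Mann–Whitney concordance
probability via mid-ranks (ties count ½) — verified against explicit
pairwise counting and against pROC.

# Pipeline, reproducibility and problem sizes

`run_pipeline()` executes simulate → preprocess → quantify → stats →
classify from a single config (YAML/JSON or list; `validate_config()`
fills defaults and collects all violations). Every random stage consumes a
stage-specific child seed of the global seed; two runs with the same
config are bit-identical (asserted on the CSV outputs). The CV repeat
default is 50 (the published-scale 200 is one config value away).

Simulation sizes used by the test and acceptance suites, chosen to make
each check statistically informative at interactive runtimes: 500 null
cohorts (fast mode) for ANOVA type-I calibration, 200 label permutations
for chance-level AUROC, 200 noisy cohorts for effect-detection power, 100
random spectra for the baseline hull oracle, 10⁶ draws for the
studentized-range Monte-Carlo check, and the full 30-sample image pipeline
(default config) for the end-to-end runs.

# What passing the tests does and does not show

The synthetic generator emulates band structure, additive baselines, a
sinusoidal Mie-like ripple, cohort structure and biological scaling. It
does not emulate atmospheric water vapor, detector nonlinearity, resonant
(absorption-coupled) Mie dispersion, within-sample cell heterogeneity, or
confounders such as age/sex/passage. Green tests therefore demonstrate
algorithmic correctness and statistical calibration under the stated
generative model — not that any particular biological conclusion from real
spectra is correct.
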