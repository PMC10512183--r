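# Synthetic three-group cohort generator.
#
# Cell spectra are sums of Gaussian/Lorentzian bands placed at the
# characteristic mid-IR positions of cellular protein and lipid vibrations,
# with group-specific amplitude multipliers, center shifts and dropped
# sub-peaks as the injected ground truth. Images add a polynomial baseline,
# an atmospheric CO2 band near 2350 cm^-1, a smooth Mie-like sinusoidal
# ripple per pixel, per-sample log-normal biological scaling, and white
# measurement noise. Everything is a pure function of the config seed.

#' Describe one synthetic vibrational band
#'
#' @param name Band name (used by group effects to target the band).
#' @param center Band center, cm^-1.
#' @param width Gaussian sigma (or Lorentzian half-width), cm^-1, > 0.
#' @param amplitude Peak height, AU, >= 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A one-row data frame.
#' @export
band_spec <- function(name, center, width, amplitude, shape = "gaussian") {
  stopifnot(width > 0, amplitude >= 0, shape %in% c("gaussian", "lorentzian"))
  data.frame(name = name, center = center, width = width,
             amplitude = amplitude, shape = shape, stringsAsFactors = FALSE)
}

#' Default synthetic band library
#'
#' Fifteen bands covering the amide backbone region (A, B, I, II, the
#' choline-associated amide II shoulder, III), the four C-H stretches of
#' the 3000-2800 cm^-1 lipid region, the lipid carbonyl ester, the two
#' acyl-chain sub-peaks (CH2 scissoring ~1455, CH3 deformation ~1435), and
#' two bands in the mixed carbohydrate/phosphate region (1300-1000 cm^-1).
#' Amide I is the dominant band, as in typical cell absorbance spectra.
#'
#' @return Data frame of [band_spec()] rows.
#' @export
default_band_library <- function() {
  rbind(
    band_spec("amide_A",        3290, 32, 0.85),
    band_spec("amide_B",        3065, 22, 0.20),
    band_spec("amide_I",        1652, 16, 1.00),
    band_spec("amide_II",       1545, 14, 0.60),
    band_spec("amide_II_choline", 1492, 5, 0.08),
    band_spec("amide_III",      1242, 24, 0.22),
    band_spec("ch3_asym",       2960,  8, 0.28),
    band_spec("ch2_asym",       2925,  9, 0.38),
    band_spec("ch3_sym",        2872,  6, 0.14),
    band_spec("ch2_sym",        2852,  6, 0.20),
    band_spec("carbonyl_ester", 1740,  8, 0.16),
    band_spec("acyl_ch2_scissor", 1455, 7, 0.16),
    band_spec("acyl_ch3_deform",  1435, 6, 0.11),
    band_spec("carbohydrate_co",  1155, 16, 0.14),
    band_spec("phosphate_sym",    1085, 18, 0.24)
  )
}

#' Default group effect templates
#'
#' CTRL-like samples carry no effect. The disease-like templates follow the
#' qualitative pattern seen in patient fibroblast studies: reduced lipid
#' carbonyl-ester intensity, raised amide I, the amide I alpha-helix center
#' shifted to higher wavenumbers, loss of the ~1435 cm^-1 acyl-chain
#' sub-peak (a single acyl peak instead of two), and an amide A rise with a
#' shift toward lower wavenumbers. The two disease-like groups share those
#' directions but differ in magnitude, and the ALS-like template adds a
#' mixed-region (phosphate) change, so all three groups are mutually
#' separable as in the emulated study design.
#'
#' @return Named list of group effects; each effect is a list with
#'   `amplitude_multipliers` (named positive factors), `center_shifts`
#'   (named offsets, cm^-1, |shift| <= 15) and `drop_bands`.
#' @export
default_group_effects <- function() {
  list(
    CTRL = list(amplitude_multipliers = numeric(0),
                center_shifts = numeric(0), drop_bands = character(0)),
    MS = list(
      amplitude_multipliers = c(carbonyl_ester = 0.8, amide_I = 1.15,
                                amide_A = 1.10),
      center_shifts = c(amide_I = 4, amide_A = -3),
      drop_bands = "acyl_ch3_deform"),
    ALS = list(
      amplitude_multipliers = c(carbonyl_ester = 0.85, amide_I = 1.10,
                                amide_A = 1.25, phosphate_sym = 1.15),
      center_shifts = c(amide_I = 4, amide_A = -6),
      drop_bands = "acyl_ch3_deform")
  )
}

#' Build a synthetic cohort configuration
#'
#' Defaults describe a desk-scale analog of a three-group fibroblast study:
#' 10 samples per group, 950-3500 cm^-1 at 4 cm^-1 spacing, 16x16-pixel
#' images with 40% background pixels.
#'
#' @param axis_lo,axis_hi,axis_step Wavenumber axis span and spacing, cm^-1.
#' @param n_per_group Samples per group.
#' @param groups Group labels; must be names of `effects`.
#' @param band_library Data frame of [band_spec()] rows.
#' @param effects Named list of group effects (see
#'   [default_group_effects()]).
#' @param n_rows,n_cols Image geometry in pixels.
#' @param background_fraction Fraction of pixels that are background, in
#'   (0, 1); the background pixel count is `round(fraction * n_pixels)`.
#' @param baseline_coef Polynomial baseline coefficients in the scaled
#'   variable `u = (wavenumber - axis_lo) / (axis_hi - axis_lo)`,
#'   lowest order first.
#' @param baseline_jitter_sd Per-image SD of a random additive offset and
#'   slope perturbation on the baseline.
#' @param mie_amplitude,mie_period,mie_phase_jitter Sinusoidal Mie-like
#'   ripple `amplitude * sin(2*pi*wavenumber/period + phase)` applied per
#'   cell pixel; the phase is drawn uniformly within `phase_jitter` radians.
#' @param co2_band [band_spec()] row for the atmospheric CO2 artifact.
#' @param noise_sd Additive white-noise SD per pixel spectrum, AU.
#' @param between_sample_sd SD (log scale) of the per-sample log-normal
#'   biological intensity factor.
#' @param seed Integer seed fixing the entire cohort.
#' @return A list of class `ftir_synth_config`.
#' @export
synthetic_cohort_config <- function(axis_lo = 950, axis_hi = 3500, axis_step = 4,
                                    n_per_group = 10,
                                    groups = c("CTRL", "MS", "ALS"),
                                    band_library = default_band_library(),
                                    effects = default_group_effects(),
                                    n_rows = 16, n_cols = 16,
                                    background_fraction = 0.4,
                                    baseline_coef = c(0.05, 0.04),
                                    baseline_jitter_sd = 0.01,
                                    mie_amplitude = 0.02, mie_period = 900,
                                    mie_phase_jitter = 2 * pi,
                                    co2_band = band_spec("co2", 2350, 12, 0.06),
                                    noise_sd = 0.005,
                                    between_sample_sd = 0.1,
                                    seed = 1L) {
  stopifnot(axis_lo < axis_hi, axis_step > 0,
            background_fraction > 0, background_fraction < 1,
            noise_sd >= 0, between_sample_sd >= 0,
            all(groups %in% names(effects)))
  for (e in effects) {
    if (length(e$amplitude_multipliers) && any(e$amplitude_multipliers <= 0))
      stop("amplitude multipliers must be positive", call. = FALSE)
    if (length(e$center_shifts) && any(abs(e$center_shifts) > 15))
      stop("center shifts are bounded by +/- 15 cm^-1", call. = FALSE)
  }
  structure(list(
    axis_lo = axis_lo, axis_hi = axis_hi, axis_step = axis_step,
    n_per_group = as.integer(n_per_group), groups = groups,
    band_library = band_library, effects = effects,
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    background_fraction = background_fraction,
    baseline_coef = baseline_coef, baseline_jitter_sd = baseline_jitter_sd,
    mie_amplitude = mie_amplitude, mie_period = mie_period,
    mie_phase_jitter = mie_phase_jitter,
    co2_band = co2_band, noise_sd = noise_sd,
    between_sample_sd = between_sample_sd, seed = as.integer(seed)
  ), class = "ftir_synth_config")
}

config_axis <- function(config) {
  seq(config$axis_lo, config$axis_hi, by = config$axis_step)
}

#' Evaluate a band model on an axis
#'
#' Sum of the peak shapes of `bands` evaluated at each wavenumber.
#'
#' @param wavenumber Ascending numeric axis, cm^-1.
#' @param bands Data frame of [band_spec()] rows (possibly empty).
#' @return An absorbance [spectrum()].
#' @export
band_model <- function(wavenumber, bands) {
  y <- numeric(length(wavenumber))
  if (!is.null(bands) && nrow(bands)) {
    for (i in seq_len(nrow(bands))) {
      b <- bands[i, ]
      y <- y + if (b$shape == "lorentzian") {
        b$amplitude * b$width^2 / ((wavenumber - b$center)^2 + b$width^2)
      } else {
        b$amplitude * exp(-(wavenumber - b$center)^2 / (2 * b$width^2))
      }
    }
  }
  spectrum(wavenumber, y)
}

apply_group_effect <- function(bands, effect) {
  if (is.null(effect)) return(bands)
  bands <- bands[!(bands$name %in% effect$drop_bands), , drop = FALSE]
  m <- effect$amplitude_multipliers
  if (length(m)) {
    idx <- match(names(m), bands$name)
    ok <- !is.na(idx)
    bands$amplitude[idx[ok]] <- bands$amplitude[idx[ok]] * m[ok]
  }
  s <- effect$center_shifts
  if (length(s)) {
    idx <- match(names(s), bands$name)
    ok <- !is.na(idx)
    bands$center[idx[ok]] <- bands$center[idx[ok]] + s[ok]
  }
  bands
}

#' Group-level noise-free truth spectrum
#'
#' The band model after applying a group's effect template: the target the
#' pre-processing chain should recover up to scale.
#'
#' @param config An `ftir_synth_config`.
#' @param group Group label.
#' @return An absorbance [spectrum()].
#' @export
group_truth_spectrum <- function(config, group) {
  if (!group %in% config$groups) stop("unknown group: ", group, call. = FALSE)
  band_model(config_axis(config),
             apply_group_effect(config$band_library, config$effects[[group]]))
}

#' Generate the scatter-correction reference spectrum
#'
#' A smooth, noise-free protein/carbohydrate-dominated spectrum emulating a
#' reference measured from an extracellular-matrix gel: amide bands plus the
#' mixed-region carbohydrate/phosphate bands, without the cell lipid bands
#' that carry the group effects.
#'
#' @param wavenumber Ascending axis, cm^-1.
#' @param seed Integer seed (small reproducible amplitude perturbations).
#' @return An absorbance [spectrum()].
#' @export
generate_reference_spectrum <- function(wavenumber, seed = 1L) {
  bands <- default_band_library()
  keep <- c("amide_A", "amide_B", "amide_I", "amide_II", "amide_III",
            "carbohydrate_co", "phosphate_sym")
  bands <- bands[bands$name %in% keep, , drop = FALSE]
  withr::with_seed(seed, {
    bands$amplitude <- bands$amplitude * exp(stats::rnorm(nrow(bands), 0, 0.05))
  })
  band_model(wavenumber, bands)
}

baseline_curve <- function(wavenumber, coef, lo, hi) {
  u <- (wavenumber - lo) / (hi - lo)
  drop(outer(u, seq_along(coef) - 1, "^") %*% coef)
}

#' Generate one synthetic cell image
#'
#' Background pixels carry baseline + CO2 band + noise; cell pixels
#' additionally carry the group-modified band model scaled by a per-sample
#' log-normal biological factor, plus a per-pixel sinusoidal Mie-like
#' ripple. `round(background_fraction * n_pixels)` pixels (base-R
#' `round()`) are background, placed uniformly at random.
#'
#' @param config An `ftir_synth_config`.
#' @param group Group label, one of `config$groups`.
#' @param sample_seed Integer seed for this sample's random draws.
#' @param sample_id Sample identifier stored with the image.
#' @return List with `image` (an [spectral_image()] carrying the true mask)
#'   and `truth` (list: `mean_spectrum`, the noise-free group band model;
#'   `mask`; `bio_factor`; `group`; `sample_id`).
#' @export
generate_cell_image <- function(config, group, sample_seed,
                                sample_id = paste0(group, "_", sample_seed)) {
  if (!group %in% config$groups) stop("unknown group: ", group, call. = FALSE)
  wn <- config_axis(config)
  npx <- config$n_rows * config$n_cols
  n_bg <- round(config$background_fraction * npx)
  truth_spec <- group_truth_spectrum(config, group)

  withr::with_seed(sample_seed, {
    bio <- exp(stats::rnorm(1, 0, config$between_sample_sd))
    bg_idx <- sample.int(npx, n_bg)
    base <- baseline_curve(wn, config$baseline_coef, config$axis_lo, config$axis_hi)
    if (config$baseline_jitter_sd > 0 && any(config$baseline_coef != 0)) {
      jit <- stats::rnorm(2, 0, config$baseline_jitter_sd)
      base <- base + jit[1] + jit[2] * (wn - config$axis_lo) / (config$axis_hi - config$axis_lo)
    }
    co2 <- band_model(wn, config$co2_band)$intensity
    common <- base + co2
    cube <- matrix(rep(common, each = npx), nrow = npx)
    cell_idx <- setdiff(seq_len(npx), bg_idx)
    if (length(cell_idx)) {
      cell_block <- matrix(rep(bio * truth_spec$intensity, each = length(cell_idx)),
                           nrow = length(cell_idx))
      if (config$mie_amplitude > 0) {
        phases <- stats::runif(length(cell_idx), 0, config$mie_phase_jitter)
        ripple <- config$mie_amplitude *
          sin(outer(rep(2 * pi / config$mie_period, length(cell_idx)), wn) +
                phases)
        cell_block <- cell_block + ripple
      }
      cube[cell_idx, ] <- cube[cell_idx, ] + cell_block
    }
    if (config$noise_sd > 0) {
      cube <- cube + matrix(stats::rnorm(length(cube), 0, config$noise_sd),
                            nrow = npx)
    }
  })
  mask <- rep("cell", npx)
  mask[bg_idx] <- "background"
  img <- spectral_image(wn, cube, config$n_rows, config$n_cols, mask = mask)
  attr(img, "sample_id") <- sample_id
  attr(img, "group") <- group
  list(image = img,
       truth = list(sample_id = sample_id, group = group,
                    mean_spectrum = truth_spec, mask = mask, bio_factor = bio))
}

#' Generate a full synthetic cohort of images
#'
#' `n_per_group` images per group; per-sample seeds are drawn once from the
#' config seed, so the whole cohort is a pure function of the config.
#'
#' @param config An `ftir_synth_config`.
#' @return List with `samples` (list of [generate_cell_image()] results),
#'   `metadata` (data frame: sample_id, group, seed) and `config`.
#' @export
generate_cohort <- function(config) {
  n <- config$n_per_group * length(config$groups)
  seeds <- withr::with_seed(config$seed, sample.int(.Machine$integer.max, n))
  grp <- rep(config$groups, each = config$n_per_group)
  ids <- sprintf("%s_%02d", grp, sequence(rep(config$n_per_group,
                                              length(config$groups))))
  samples <- lapply(seq_len(n), function(i) {
    generate_cell_image(config, grp[i], seeds[i], sample_id = ids[i])
  })
  list(samples = samples,
       metadata = data.frame(sample_id = ids, group = grp, seed = seeds,
                             stringsAsFactors = FALSE),
       config = config)
}

#' Generate per-sample mean spectra directly (no pixel images)
#'
#' Fast cohort mode for simulation studies: each sample's mean absorbance
#' spectrum is the group truth scaled by its log-normal biological factor
#' plus pixel-averaged noise (`noise_sd / sqrt(n_cell_pixels)`), then
#' vector normalized; second derivatives use the given Savitzky-Golay
#' settings. This skips the image-level artifacts (baseline, CO2, ripple),
#' emulating the output of a perfect pre-processing chain.
#'
#' @param config An `ftir_synth_config`.
#' @param deriv Savitzky-Golay settings for the second derivative, a list
#'   with `window` and `polyorder`, or `NULL` to skip the derivative stage
#'   (faster when only the absorbance ratios are needed).
#' @return An [cohort_table()].
#' @export
generate_sample_spectra <- function(config, deriv = list(window = 7, polyorder = 2)) {
  wn <- config_axis(config)
  n <- config$n_per_group * length(config$groups)
  grp <- rep(config$groups, each = config$n_per_group)
  ids <- sprintf("%s_%02d", grp, sequence(rep(config$n_per_group,
                                              length(config$groups))))
  n_cell <- config$n_rows * config$n_cols -
    round(config$background_fraction * config$n_rows * config$n_cols)
  sd_mean <- config$noise_sd / sqrt(max(n_cell, 1))
  truth <- lapply(config$groups, function(g) group_truth_spectrum(config, g)$intensity)
  names(truth) <- config$groups
  records <- withr::with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      bio <- exp(stats::rnorm(1, 0, config$between_sample_sd))
      y <- bio * truth[[grp[i]]] + stats::rnorm(length(wn), 0, sd_mean)
      mean_abs <- vector_normalize(spectrum(wn, y))
      d2 <- if (is.null(deriv)) NULL else {
        vector_normalize(savgol(mean_abs, window = deriv$window,
                                polyorder = deriv$polyorder, deriv_order = 2))
      }
      sample_record(ids[i], grp[i], mean_abs, d2)
    })
  })
  cohort_table(records)
}
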