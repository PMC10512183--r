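test_that("excise_region drops the interval and tracks segments", {
  wn <- seq(950, 3500, 4)
  sp <- spectrum(wn, sin(wn / 200))
  ex <- excise_region(sp, 2000, 2700)
  expect_false(any(ex$wavenumber >= 2000 & ex$wavenumber <= 2700))
  expect_equal(length(ex$wavenumber),
               length(wn) - sum(wn >= 2000 & wn <= 2700))
  expect_equal(length(unique(ex$segments)), 2)
  # identity when the interval misses the axis
  expect_equal(excise_region(sp, 5000, 6000), sp)
})

test_that("filtering after excision never bridges the gap", {
  wn <- seq(950, 3500, 4)
  sp <- spectrum(wn, exp(-(wn - 1650)^2 / 800) + exp(-(wn - 2900)^2 / 800))
  ex <- excise_region(sp, 2000, 2700)
  d2 <- savgol(ex, 7, 2, 2)
  # same result as filtering each retained side separately
  left <- slice_region(ex, min(wn), 1999)
  right <- slice_region(ex, 2701, max(wn))
  expect_equal(d2$intensity,
               c(savgol(left, 7, 2, 2)$intensity,
                 savgol(right, 7, 2, 2)$intensity))
})

test_that("rubber-band baseline handles affine and single-band cases", {
  wn <- seq(1000, 1635, 5)
  aff <- spectrum(wn, 0.002 * wn + 1)
  rb <- rubberband_baseline(aff)
  expect_equal(rb$corrected$intensity, numeric(length(wn)), tolerance = 1e-12)

  gauss <- spectrum(wn, exp(-(wn - 1300)^2 / (2 * 20^2)))
  rb2 <- rubberband_baseline(gauss)
  expect_equal(rb2$corrected$intensity, gauss$intensity, tolerance = 1e-6)
})

test_that("rubber-band correction equals the O(n^2) hull oracle", {
  withr::with_seed(7, {
    for (case in 1:20) {
      n <- sample(10:200, 1)
      x <- sort(stats::runif(n, 1000, 3000))
      x <- x + seq_len(n) * 1e-6   # ensure strictly increasing
      y <- stats::rnorm(n) + 0.001 * x
      sp <- spectrum(x, y, strict = FALSE)
      rb <- rubberband_baseline(sp)
      expect_equal(rb$baseline$intensity, oracle_lower_hull_baseline(x, y),
                   tolerance = 1e-10)
      expect_true(all(rb$corrected$intensity >= -1e-9))
      # >= 2 exact zeros at hull support points
      expect_gte(sum(abs(rb$corrected$intensity) < 1e-12), 2)
    }
  })
})

test_that("k-means segmentation recovers a strong-contrast truth mask", {
  cfg <- synthetic_cohort_config(n_rows = 8, n_cols = 8, noise_sd = 0.001,
                                 mie_amplitude = 0, baseline_coef = 0,
                                 baseline_jitter_sd = 0, seed = 2)
  out <- generate_cell_image(cfg, "CTRL", 3)
  mask <- segment_pixels(out$image, k = 2, seed = 5)
  expect_equal(mask, out$truth$mask)
  expect_equal(segment_pixels(out$image, k = 2, seed = 5), mask)
  expect_equal(segment_pixels(out$image, k = 1), rep("cell", 64))
})

test_that("identical pixels collapse to one warned cell cluster", {
  img <- spectral_image(seq(1000, 1070, 10), matrix(1, 4, 8), 2, 2)
  expect_warning(mask <- segment_pixels(img, k = 2, seed = 1), "indistinguishable")
  expect_equal(mask, rep("cell", 4))
})

test_that("binning averages adjacent points and keeps remainders", {
  sp <- spectrum(c(1000, 1004, 1008, 1012), c(1, 3, 5, 7), strict = FALSE)
  b <- bin_spectra(sp, 2)
  expect_equal(b$wavenumber, c(1002, 1010))
  expect_equal(b$intensity, c(2, 6))

  expect_equal(bin_spectra(sp, 1), sp)
  const <- spectrum(seq(1000, 1035, 5), rep(2, 8))
  expect_true(all(bin_spectra(const, 3)$intensity == 2))
  # remainder bin: 8 points by 3 -> sizes 3,3,2
  expect_length(bin_spectra(const, 3)$wavenumber, 3)
  expect_error(bin_spectra(sp, 10), "exceeds")
})

test_that("Mie basis is orthonormal with monotone reconstruction gains", {
  wn <- seq(950, 3500, 8)
  B <- build_mie_basis(wn, c(2, 10), c(1.1, 1.5), n_components = 7)
  expect_equal(crossprod(B), diag(ncol(B)), tolerance = 1e-8, ignore_attr = TRUE)

  # held-out curves reconstruct monotonically better with more components
  hold <- build_mie_basis(wn, c(3.3, 8.7), c(1.17, 1.44), n_components = 1,
                          n_grid = 4)
  curves <- attr(hold, "curves")
  curves_c <- sweep(curves, 2, colMeans(attr(B, "curves")))
  errs <- vapply(1:7, function(k) {
    Bk <- B[, 1:k, drop = FALSE]
    resid <- curves_c - curves_c %*% Bk %*% t(Bk)
    sqrt(mean(resid^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))

  single <- build_mie_basis(wn, c(5, 5), c(1.3, 1.3), n_components = 1, n_grid = 1)
  expect_equal(sum(single^2), 1)
})

test_that("EMSC correction is exact on constructed linear mixtures", {
  wn <- seq(950, 3500, 4)
  ref <- generate_reference_spectrum(wn, seed = 1)
  # s = reference
  out <- scatter_correct(ref, ref, mode = "emsc_poly")
  expect_equal(out$intensity, ref$intensity, tolerance = 1e-8)
  cf <- attr(out, "emsc_coef")
  expect_equal(unname(cf[1, "a"]), 1, tolerance = 1e-8)
  expect_equal(max(abs(cf[1, -1])), 0, tolerance = 1e-8)

  # s = 2 * reference + 0.1
  s2 <- spectrum(wn, 2 * ref$intensity + 0.1)
  out2 <- scatter_correct(s2, ref, mode = "emsc_poly")
  expect_equal(out2$intensity, ref$intensity, tolerance = 1e-8)
  cf2 <- attr(out2, "emsc_coef")
  expect_equal(unname(cf2[1, "a"]), 2, tolerance = 1e-8)
  expect_equal(unname(cf2[1, "poly0"]), 0.1, tolerance = 1e-8)
})

test_that("EMSC removes the synthesis ripple (correlation >= 0.99)", {
  wn <- seq(950, 3500, 4)
  ref <- generate_reference_spectrum(wn, seed = 1)
  withr::with_seed(11, {
    X <- do.call(rbind, lapply(1:12, function(i) {
      a <- stats::runif(1, 0.7, 1.4)
      ripple <- 0.05 * sin(2 * pi * wn / 900 + stats::runif(1, 0, 2 * pi))
      a * ref$intensity + ripple + 0.02 * (wn / 3500)^2
    }))
  })
  cor_raw <- apply(X, 1, stats::cor, ref$intensity)
  corr <- scatter_correct(X, ref$intensity, wavenumber = wn,
                          mode = "emsc_mie", n_clusters = 3, seed = 4)
  cor_fix <- apply(corr, 1, stats::cor, ref$intensity)
  expect_true(all(cor_fix >= 0.99))
  expect_true(all(cor_fix >= cor_raw - 1e-12))
})

test_that("EMSC is idempotent in emsc_poly mode", {
  wn <- seq(950, 3500, 4)
  ref <- generate_reference_spectrum(wn, seed = 1)
  s <- spectrum(wn, 1.7 * ref$intensity + 0.3 - 0.1 * (wn / 3500))
  once <- scatter_correct(s, ref, mode = "emsc_poly")
  twice <- scatter_correct(once, ref, mode = "emsc_poly")
  cf <- attr(twice, "emsc_coef")
  expect_equal(unname(cf[1, "a"]), 1, tolerance = 1e-6)
  expect_equal(twice$intensity, once$intensity, tolerance = 1e-6)
})

test_that("uncorrectable spectra pass through with a warning", {
  wn <- seq(950, 3500, 4)
  ref <- generate_reference_spectrum(wn, seed = 1)
  bad <- matrix(-ref$intensity, nrow = 1)
  expect_warning(out <- scatter_correct(bad, ref$intensity, wavenumber = wn,
                                        mode = "emsc_poly"),
                 "uncorrectable")
  expect_equal(out[1, ], bad[1, ], ignore_attr = TRUE)
  expect_true(attr(out, "uncorrectable")[1])
})

test_that("Savitzky-Golay is exact on polynomials and linear", {
  wn <- seq(1000, 1995, 5)
  # constant -> zero second derivative
  expect_equal(savgol(spectrum(wn, rep(3, length(wn))), 7, 2, 2)$intensity,
               numeric(length(wn)))
  # quadratic a*x^2 -> second derivative 2a everywhere (incl. edges)
  a <- 0.37
  q <- savgol(spectrum(wn, a * wn^2), 7, 2, 2)
  expect_equal(q$intensity, rep(2 * a, length(wn)), tolerance = 1e-8)
  # linearity to 1e-10
  withr::with_seed(3, {
    x1 <- stats::rnorm(length(wn)); x2 <- stats::rnorm(length(wn))
  })
  lhs <- savgol(spectrum(wn, 2 * x1 - 3 * x2), 9, 3, 2)$intensity
  rhs <- 2 * savgol(spectrum(wn, x1), 9, 3, 2)$intensity -
    3 * savgol(spectrum(wn, x2), 9, 3, 2)$intensity
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("Savitzky-Golay matches the per-window regression oracle", {
  wn <- seq(1000, 1236, 4)
  withr::with_seed(5, y <- stats::rnorm(length(wn)))
  for (par in list(c(7, 2, 2), c(5, 2, 0), c(15, 5, 2))) {
    got <- savgol(spectrum(wn, y), par[1], par[2], par[3])$intensity
    expect_equal(got, oracle_savgol(wn, y, par[1], par[2], par[3]),
                 tolerance = 1e-8)
  }
})

test_that("SG second-derivative attenuation shrinks for broad bands", {
  wn <- seq(950, 3500, 4)
  rel_err <- vapply(c(10, 20, 45), function(sig) {
    g <- exp(-(wn - 1650)^2 / (2 * sig^2))
    d2 <- savgol(spectrum(wn, g), 7, 2, 2)
    abs(d2$intensity[which.min(abs(wn - 1650))] / (-1 / sig^2) - 1)
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))   # bias ~ 1/sigma^2
  expect_lt(rel_err[3], 0.02)           # broad bands recovered within 2%
})

test_that("vector normalization yields unit norm and rejects zero input", {
  expect_equal(vector_normalize(c(3, 4)), c(0.6, 0.8))
  u <- vector_normalize(stats::rnorm(50))
  expect_equal(vector_normalize(u), u)
  withr::with_seed(8, {
    for (i in 1:10) {
      expect_equal(sum(vector_normalize(stats::rnorm(30))^2), 1)
    }
  })
  expect_error(vector_normalize(numeric(10)), "zero")
})

test_that("preprocess_sample matches an independent stage-oracle chain", {
  cfg <- synthetic_cohort_config(noise_sd = 0, mie_amplitude = 0,
                                 baseline_coef = 0, baseline_jitter_sd = 0,
                                 between_sample_sd = 0,
                                 co2_band = band_spec("co2", 2350, 12, 0),
                                 n_rows = 4, n_cols = 4, seed = 1)
  out <- generate_cell_image(cfg, "MS", 2)
  wn <- seq(950, 3500, 4)
  ref <- generate_reference_spectrum(wn, seed = 1)
  pp <- preprocess_params(scatter = list(mode = "emsc_poly", n_clusters = 1,
                                         poly_order = 2, seed = 13L))
  rec <- preprocess_sample(out$image, ref, pp)

  # oracle: hand-built chain on the noise-free truth spectrum
  truth <- group_truth_spectrum(cfg, "MS")
  keep <- !(wn >= 2000 & wn <= 2700)
  xs <- wn[keep]; ys <- truth$intensity[keep]
  seg <- cumsum(c(TRUE, diff(which(keep)) > 1))
  y_rb <- ys
  for (s in unique(seg)) {
    i <- seg == s
    y_rb[i] <- ys[i] - oracle_lower_hull_baseline(xs[i], ys[i])
  }
  grpidx <- unlist(lapply(unique(seg), function(s) {
    i <- which(seg == s)
    split(i, ceiling(seq_along(i) / 2))
  }), recursive = FALSE)
  xb <- vapply(grpidx, function(i) mean(xs[i]), numeric(1))
  yb <- vapply(grpidx, function(i) mean(y_rb[i]), numeric(1))
  ord <- order(xb); xb <- xb[ord]; yb <- yb[ord]
  segb <- cumsum(c(TRUE, diff(xb) > 10))
  refb <- bin_spectra(excise_region(ref, 2000, 2700), 2)
  u <- (xb - min(xb)) / diff(range(xb))
  D <- cbind(refb$intensity, 1, u, u^2)
  cf <- stats::lm.fit(D, yb)$coefficients
  y_emsc <- (yb - D[, -1] %*% cf[-1]) / cf[1]
  y_sm <- numeric(length(xb))
  for (s in unique(segb)) {
    i <- segb == s
    y_sm[i] <- oracle_savgol(xb[i], y_emsc[i], 5, 2, 0)
  }
  y_norm <- y_sm / sqrt(sum(y_sm^2))
  cosine <- sum(rec$mean_absorbance$intensity * y_norm)
  expect_gte(cosine, 0.999)

  # determinism: identical images give identical records
  rec2 <- preprocess_sample(out$image, ref, pp)
  expect_equal(rec, rec2)
  # both outputs are unit vectors
  expect_equal(sum(rec$mean_absorbance$intensity^2), 1)
  expect_equal(sum(rec$second_derivative$intensity^2), 1)
})

test_that("noise-free group ratios are recovered within 5% (polynomial EMSC)", {
  # injected carbonyl/total-lipids contrast is 0.8; the polynomial-EMSC
  # pipeline must recover it within 5% on noise-free samples. The Mie-basis
  # mode absorbs part of the narrow-band structure missing from the
  # reference and is documented to bias this contrast (vignette).
  cfg <- synthetic_cohort_config(noise_sd = 0, between_sample_sd = 0,
                                 n_per_group = 1, seed = 21)
  ref <- generate_reference_spectrum(seq(950, 3500, 4), seed = 1)
  pp <- preprocess_params(scatter = list(mode = "emsc_poly", n_clusters = 5,
                                         poly_order = 2, seed = 13L))
  ratio_of <- function(group) {
    img <- generate_cell_image(cfg, group, 22)$image
    rec <- preprocess_sample(img, ref, pp)
    integrate_band(rec$mean_absorbance, "carbonyl_ester") /
      integrate_band(rec$mean_absorbance, "total_lipids")
  }
  contrast <- ratio_of("MS") / ratio_of("CTRL")
  truth <- integrate_band(group_truth_spectrum(cfg, "MS"), "carbonyl_ester") /
    integrate_band(group_truth_spectrum(cfg, "MS"), "total_lipids") /
    (integrate_band(group_truth_spectrum(cfg, "CTRL"), "carbonyl_ester") /
       integrate_band(group_truth_spectrum(cfg, "CTRL"), "total_lipids"))
  expect_lt(abs(contrast / truth - 1), 0.05)
})

test_that("alternative derivative preset changes only the derivative", {
  cfg <- synthetic_cohort_config(n_rows = 4, n_cols = 4, seed = 3)
  out <- generate_cell_image(cfg, "CTRL", 4)
  ref <- generate_reference_spectrum(seq(950, 3500, 4), seed = 1)
  r1 <- preprocess_sample(out$image, ref)
  r2 <- preprocess_sample(out$image, ref, use_alt_deriv = TRUE)
  expect_equal(r1$mean_absorbance, r2$mean_absorbance)
  expect_false(isTRUE(all.equal(r1$second_derivative$intensity,
                                r2$second_derivative$intensity)))
  expect_equal(sum(r2$second_derivative$intensity^2), 1)
})
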