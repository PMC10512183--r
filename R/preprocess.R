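# Pre-processing chain for hyperspectral absorbance images, in pipeline
# order: region excision -> rubber-band baseline -> k-means cell/background
# segmentation -> spectral binning -> clustered EMSC scatter correction ->
# Savitzky-Golay smoothing -> averaging -> vector normalization -> second
# derivative -> vector normalization.

#' Default pre-processing parameters
#'
#' @param excise_lo,excise_hi Wavenumber interval removed from the axis
#'   (CO2 region with low biological signal), cm^-1.
#' @param kmeans_k Number of k-means clusters for cell/background
#'   segmentation.
#' @param kmeans_seed Seed for the segmentation k-means.
#' @param bin_factor Spectral binning factor (adjacent axis points averaged).
#' @param scatter Scatter-correction settings: `mode` (`"emsc_mie"` or
#'   `"emsc_poly"`), `n_clusters`, `poly_order`, `n_mie_components`,
#'   `mie_radius_range` (microns), `mie_refidx_range`, `seed`.
#' @param smooth Savitzky-Golay smoothing settings (`window`, `polyorder`).
#' @param deriv Savitzky-Golay derivative settings (`window`, `polyorder`,
#'   `order`).
#' @param alt_deriv Alternative derivative preset (wider window, higher
#'   polynomial order) kept for robustness re-analysis.
#' @return A list of class `ftir_preprocess_params`.
#' @export
preprocess_params <- function(excise_lo = 2000, excise_hi = 2700,
                              kmeans_k = 2, kmeans_seed = 11L,
                              bin_factor = 2,
                              scatter = list(mode = "emsc_mie", n_clusters = 5,
                                             poly_order = 2, n_mie_components = 7,
                                             mie_radius_range = c(2, 10),
                                             mie_refidx_range = c(1.1, 1.5),
                                             seed = 13L),
                              smooth = list(window = 5, polyorder = 2),
                              deriv = list(window = 7, polyorder = 2, order = 2),
                              alt_deriv = list(window = 15, polyorder = 5, order = 2)) {
  stopifnot(excise_lo < excise_hi, bin_factor >= 1,
            smooth$window %% 2 == 1, smooth$window > smooth$polyorder,
            deriv$window %% 2 == 1, deriv$window > deriv$polyorder)
  structure(list(excise_lo = excise_lo, excise_hi = excise_hi,
                 kmeans_k = kmeans_k, kmeans_seed = kmeans_seed,
                 bin_factor = bin_factor, scatter = scatter,
                 smooth = smooth, deriv = deriv, alt_deriv = alt_deriv),
            class = "ftir_preprocess_params")
}

recompute_segments <- function(old_segments, kept_idx) {
  # new segment starts where kept points were non-adjacent in the original
  # axis or crossed an old segment boundary
  if (!length(kept_idx)) return(integer(0))
  brk <- c(TRUE, diff(kept_idx) > 1L | diff(old_segments[kept_idx]) != 0L)
  cumsum(brk)
}

#' Remove a wavenumber interval from the axis
#'
#' Drops all axis points with `lo <= wavenumber <= hi` and records the two
#' retained runs as separate segments, so downstream derivatives and
#' integrals never bridge the gap. An interval outside the axis leaves the
#' object unchanged.
#'
#' @param obj An `ftir_spectrum` or `ftir_image`.
#' @param lo,hi Excision bounds, cm^-1.
#' @return Object of the same class on the reduced axis.
#' @export
excise_region <- function(obj, lo = 2000, hi = 2700) {
  wn <- obj$wavenumber
  drop <- wn >= lo & wn <= hi
  if (!any(drop)) return(obj)
  keep_idx <- which(!drop)
  n_left <- sum(wn < lo)
  n_right <- sum(wn > hi)
  if ((n_left > 0 && n_left < 8) || (n_right > 0 && n_right < 8)) {
    stop("excision would leave fewer than 8 points on one side", call. = FALSE)
  }
  segs <- recompute_segments(obj$segments, keep_idx)
  if (inherits(obj, "ftir_spectrum")) {
    spectrum(wn[keep_idx], obj$intensity[keep_idx], kind = obj$kind,
             segments = segs, strict = FALSE)
  } else if (inherits(obj, "ftir_image")) {
    spectral_image(wn[keep_idx], obj$cube[, keep_idx, drop = FALSE],
                   obj$n_rows, obj$n_cols, mask = obj$mask, segments = segs)
  } else {
    stop("excise_region expects a spectrum or image", call. = FALSE)
  }
}

# lower convex hull of (x, y) with x strictly increasing, via grDevices::chull;
# returns indices in increasing x
lower_hull_idx <- function(x, y) {
  n <- length(x)
  if (n <= 2L) return(seq_len(n))
  h <- grDevices::chull(x, y)
  s <- which(h == 1L)
  h <- c(h[s:length(h)], h[seq_len(s - 1L)])   # cyclic rotate: start at leftmost
  e <- which(h == n)
  p1 <- h[1:e]                                  # one side, 1 -> n
  p2 <- c(1L, rev(h[seq.int(e, length(h))]))    # complementary side, 1 -> n
  pick_lower <- function(p, q) {
    xm <- mean(range(x))
    y_at <- function(p) stats::approx(x[p], y[p], xout = xm)$y
    if (y_at(p) <= y_at(q)) p else q
  }
  sort(unique(pick_lower(p1, p2)))
}

#' Rubber-band baseline correction
#'
#' Estimates the baseline per retained segment as the lower convex hull of
#' the (wavenumber, intensity) points, linearly interpolated between hull
#' support points, and subtracts it. The corrected spectrum is nonnegative
#' (up to floating point) and exactly zero at every hull support point.
#'
#' @param spec An absorbance `ftir_spectrum` with >= 3 points per segment.
#' @return List with `baseline` and `corrected` spectra.
#' @export
rubberband_baseline <- function(spec) {
  stopifnot(inherits(spec, "ftir_spectrum"))
  base <- numeric(length(spec$intensity))
  for (s in unique(spec$segments)) {
    i <- which(spec$segments == s)
    if (length(i) < 3L) {
      stop("rubber-band baseline needs >= 3 points per segment", call. = FALSE)
    }
    x <- spec$wavenumber[i]; y <- spec$intensity[i]
    idx <- lower_hull_idx(x, y)
    base[i] <- stats::approx(x[idx], y[idx], xout = x)$y
  }
  corrected <- spec$intensity - base
  list(baseline = spectrum(spec$wavenumber, base, kind = spec$kind,
                           segments = spec$segments, strict = FALSE),
       corrected = spectrum(spec$wavenumber, corrected, kind = spec$kind,
                            segments = spec$segments, strict = FALSE))
}

# rubber-band every pixel row of a cube; returns corrected cube
rubberband_cube <- function(cube, wavenumber, segments) {
  t(apply(cube, 1, function(y) {
    sp <- spectrum(wavenumber, y, segments = segments, strict = FALSE)
    rubberband_baseline(sp)$corrected$intensity
  }))
}

#' Segment pixels into cell and background by k-means
#'
#' Lloyd's k-means (seeded, multiple restarts) on the pixel spectra; the
#' cluster with the highest mean total absorbance is labeled `"cell"`, all
#' others `"background"`. With `k = 1`, or when all pixels are identical,
#' every pixel is labeled cell (with a warning in the degenerate case).
#'
#' @param image An `ftir_image` (ideally baseline-corrected).
#' @param k Number of clusters.
#' @param seed Integer seed making the clustering deterministic.
#' @return Character mask vector, one of `"cell"`/`"background"` per pixel.
#' @export
segment_pixels <- function(image, k = 2, seed = 11L) {
  stopifnot(inherits(image, "ftir_image"))
  npx <- nrow(image$cube)
  if (npx < k) stop("image must have at least k pixels", call. = FALSE)
  if (k == 1) return(rep("cell", npx))
  km <- withr::with_seed(seed, tryCatch(
    stats::kmeans(image$cube, centers = k, nstart = 5, iter.max = 100),
    error = function(e) NULL))
  if (is.null(km)) {
    warning("pixels indistinguishable; labeling all pixels as cell")
    return(rep("cell", npx))
  }
  total <- rowSums(image$cube)
  cl_mean <- tapply(total, km$cluster, mean)
  cell_cl <- as.integer(names(cl_mean)[which.max(cl_mean)])
  ifelse(km$cluster == cell_cl, "cell", "background")
}

bin_indices <- function(segments, factor) {
  # list of index groups: `factor` adjacent points per bin within a segment,
  # trailing remainder kept as a smaller bin
  out <- list()
  for (s in unique(segments)) {
    i <- which(segments == s)
    g <- split(i, ceiling(seq_along(i) / factor))
    out <- c(out, g)
  }
  out
}

#' Spectral binning
#'
#' Averages non-overlapping groups of `factor` adjacent axis points within
#' each segment (axis mean, intensity mean); a trailing remainder is kept
#' as a smaller bin. `factor = 1` is the identity.
#'
#' @param obj An `ftir_spectrum` or `ftir_image`.
#' @param factor Integer binning factor, >= 1.
#' @return Object of the same class on the binned axis.
#' @export
bin_spectra <- function(obj, factor = 2) {
  factor <- as.integer(factor)
  if (factor < 1) stop("bin factor must be >= 1", call. = FALSE)
  if (factor > length(obj$wavenumber)) {
    stop("bin factor exceeds axis length", call. = FALSE)
  }
  if (factor == 1) return(obj)
  groups <- bin_indices(obj$segments, factor)
  wn <- vapply(groups, function(i) mean(obj$wavenumber[i]), numeric(1))
  segs <- vapply(groups, function(i) obj$segments[i[1]], integer(1))
  ord <- order(wn)
  if (inherits(obj, "ftir_spectrum")) {
    y <- vapply(groups, function(i) mean(obj$intensity[i]), numeric(1))
    spectrum(wn[ord], y[ord], kind = obj$kind, segments = segs[ord],
             strict = FALSE)
  } else if (inherits(obj, "ftir_image")) {
    cube <- matrix(vapply(groups, function(i) rowMeans(obj$cube[, i, drop = FALSE]),
                          numeric(nrow(obj$cube))), nrow = nrow(obj$cube))
    spectral_image(wn[ord], cube[, ord, drop = FALSE], obj$n_rows, obj$n_cols,
                   mask = obj$mask, segments = segs[ord])
  } else {
    stop("bin_spectra expects a spectrum or image", call. = FALSE)
  }
}

#' Build a Mie extinction basis for scatter correction
#'
#' Van de Hulst extinction curves
#' `Q(v) = 2 - (4/rho) sin(rho) + (4/rho^2) (1 - cos(rho))` with
#' `rho = 4 pi r (m - 1) v` are evaluated over a grid of sphere radii `r`
#' and refractive indices `m`, and compressed to their first
#' `n_components` principal directions (orthonormal columns).
#'
#' @param wavenumber Axis, cm^-1.
#' @param radius_range Sphere radius range, microns.
#' @param refidx_range Refractive-index range (m > 1).
#' @param n_components Number of principal directions retained.
#' @param n_grid Grid points per parameter.
#' @return Matrix `length(wavenumber) x n_components` with orthonormal
#'   columns; attribute `"curves"` carries the raw extinction curves.
#' @export
build_mie_basis <- function(wavenumber, radius_range = c(2, 10),
                            refidx_range = c(1.1, 1.5), n_components = 7,
                            n_grid = 10) {
  stopifnot(length(radius_range) == 2, length(refidx_range) == 2)
  r <- unique(seq(radius_range[1], radius_range[2], length.out = n_grid)) * 1e-4  # um -> cm
  m <- unique(seq(refidx_range[1], refidx_range[2], length.out = n_grid))
  grid <- expand.grid(r = r, m = m)
  Q <- function(rho) {
    q <- 2 - (4 / rho) * sin(rho) + (4 / rho^2) * (1 - cos(rho))
    q[rho < 1e-6] <- 0
    q
  }
  curves <- t(apply(grid, 1, function(g) Q(4 * pi * g[["r"]] * (g[["m"]] - 1) * wavenumber)))
  if (nrow(grid) == 1L) {
    v <- curves[1, ]
    basis <- matrix(v / sqrt(sum(v^2)), ncol = 1)
  } else {
    centered <- sweep(curves, 2, colMeans(curves))
    sv <- svd(centered)
    k <- min(n_components, sum(sv$d > sv$d[1] * 1e-10))
    basis <- sv$v[, seq_len(k), drop = FALSE]
  }
  structure(basis, curves = curves)
}

#' EMSC-style scatter correction against a reference spectrum
#'
#' Spectra are k-means clustered (`n_clusters`, seeded) and, within each
#' cluster, each spectrum `s` is modeled by least squares as
#' `s = a * reference + polynomial baseline + Mie extinction components`;
#' the corrected spectrum is `(s - baseline - Mie part) / a`. Mode
#' `"emsc_poly"` omits the Mie basis. Spectra whose fitted reference
#' coefficient `a` is at or below a small threshold are flagged
#' uncorrectable and passed through unchanged with a warning.
#'
#' @param spectra Numeric matrix (spectra in rows) or a single
#'   `ftir_spectrum`.
#' @param reference An `ftir_spectrum` on the same axis, or a numeric
#'   vector.
#' @param wavenumber Axis (required when `spectra` is a bare matrix and
#'   `reference` is a bare vector).
#' @param mode `"emsc_mie"` or `"emsc_poly"`.
#' @param n_clusters,poly_order,n_mie_components,mie_radius_range,mie_refidx_range
#'   See [preprocess_params()].
#' @param seed Seed for the clustering.
#' @param a_threshold Minimum usable reference coefficient.
#' @return Corrected spectra, same shape as the input, with attributes
#'   `"emsc_coef"` (fit coefficients) and `"uncorrectable"` (logical per
#'   spectrum).
#' @export
scatter_correct <- function(spectra, reference, wavenumber = NULL,
                            mode = c("emsc_mie", "emsc_poly"),
                            n_clusters = 5, poly_order = 2,
                            n_mie_components = 7,
                            mie_radius_range = c(2, 10),
                            mie_refidx_range = c(1.1, 1.5),
                            seed = 13L, a_threshold = 1e-6) {
  mode <- match.arg(mode)
  single <- inherits(spectra, "ftir_spectrum")
  if (single) {
    wavenumber <- spectra$wavenumber
    X <- matrix(spectra$intensity, nrow = 1)
  } else {
    X <- as.matrix(spectra)
  }
  if (inherits(reference, "ftir_spectrum")) {
    if (is.null(wavenumber)) wavenumber <- reference$wavenumber
    if (!isTRUE(all.equal(reference$wavenumber, wavenumber))) {
      stop("reference must share the spectra's axis", call. = FALSE)
    }
    ref <- reference$intensity
  } else {
    ref <- as.numeric(reference)
  }
  if (is.null(wavenumber)) stop("wavenumber axis required", call. = FALSE)
  if (length(ref) != ncol(X)) stop("reference length must match axis", call. = FALSE)

  u <- (wavenumber - min(wavenumber)) / diff(range(wavenumber))
  D <- cbind(ref, outer(u, 0:poly_order, "^"))
  colnames(D) <- c("a", paste0("poly", 0:poly_order))
  if (mode == "emsc_mie") {
    mie <- build_mie_basis(wavenumber, mie_radius_range, mie_refidx_range,
                           n_mie_components)
    colnames(mie) <- paste0("mie", seq_len(ncol(mie)))
    D <- cbind(D, mie)
  }

  k <- min(n_clusters, nrow(X))
  cl <- if (k > 1) {
    withr::with_seed(seed, tryCatch(
      stats::kmeans(X, centers = k, nstart = 3, iter.max = 100)$cluster,
      error = function(e) rep(1L, nrow(X))))
  } else rep(1L, nrow(X))

  qrD <- qr(D)
  corrected <- X
  coefs <- matrix(NA_real_, nrow(X), ncol(D),
                  dimnames = list(NULL, colnames(D)))
  bad <- logical(nrow(X))
  for (g in unique(cl)) {
    idx <- which(cl == g)
    B <- qr.coef(qrD, t(X[idx, , drop = FALSE]))   # ncol(D) x length(idx)
    coefs[idx, ] <- t(B)
    for (j in seq_along(idx)) {
      a <- B[1, j]
      if (!is.finite(a) || a <= a_threshold) {
        bad[idx[j]] <- TRUE
      } else {
        interf <- D[, -1, drop = FALSE] %*% B[-1, j]
        corrected[idx[j], ] <- (X[idx[j], ] - interf) / a
      }
    }
  }
  if (any(bad)) {
    warning(sum(bad), " spectra uncorrectable (reference coefficient <= ",
            a_threshold, "); passed through")
  }
  if (single) {
    out <- spectrum(wavenumber, corrected[1, ], kind = spectra$kind,
                    segments = spectra$segments, strict = FALSE)
  } else {
    out <- corrected
  }
  attr(out, "emsc_coef") <- coefs
  attr(out, "uncorrectable") <- bad
  out
}

# Savitzky-Golay coefficient row: least-squares polynomial of order
# `polyorder` over the given integer offsets, derivative `deriv` at offset 0
sg_coef <- function(offsets, polyorder, deriv) {
  A <- outer(offsets, 0:polyorder, "^")
  C <- solve(crossprod(A), t(A))
  C[deriv + 1, ] * factorial(deriv)
}

.sg_cache <- new.env(parent = emptyenv())

# dense n x n Savitzky-Golay operator for a uniformly spaced segment; edge
# rows use the polynomial fit on the truncated window
sg_operator <- function(n, window, polyorder, deriv) {
  key <- paste(n, window, polyorder, deriv, sep = "_")
  if (!is.null(.sg_cache[[key]])) return(.sg_cache[[key]])
  h <- (window - 1L) %/% 2L
  S <- matrix(0, n, n)
  central <- sg_coef(-h:h, polyorder, deriv)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (lo == i - h && hi == i + h) {
      S[i, lo:hi] <- central
    } else {
      S[i, lo:hi] <- sg_coef(seq(lo, hi) - i, polyorder, deriv)
    }
  }
  .sg_cache[[key]] <- S
  S
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Local least-squares polynomial filtering per retained segment.
#' Derivatives are scaled by the physical axis step (`AU * cm^2` for the
#' second derivative), so magnitudes are comparable across binning factors.
#' Edge points are handled by fitting the polynomial on the truncated
#' window.
#'
#' @param spec An `ftir_spectrum` (or numeric matrix with spectra in rows,
#'   in which case `wavenumber` and `segments` must be given).
#' @param window Odd window length, > `polyorder`.
#' @param polyorder Polynomial order.
#' @param deriv_order Derivative order (0 = smoothing, 2 = second
#'   derivative).
#' @param wavenumber,segments Axis and segment ids for matrix input.
#' @return Filtered object of the same shape. A second derivative gets
#'   `kind = "second_derivative"`.
#' @export
savgol <- function(spec, window = 7, polyorder = 2, deriv_order = 2,
                   wavenumber = NULL, segments = NULL) {
  if (window %% 2 != 1 || window <= polyorder) {
    stop("window must be odd and greater than polyorder", call. = FALSE)
  }
  is_spec <- inherits(spec, "ftir_spectrum")
  if (is_spec) {
    wavenumber <- spec$wavenumber
    segments <- spec$segments
    X <- matrix(spec$intensity, nrow = 1)
  } else {
    X <- as.matrix(spec)
    if (is.null(wavenumber)) stop("wavenumber required for matrix input", call. = FALSE)
    if (is.null(segments)) segments <- rep.int(1L, length(wavenumber))
  }
  out <- X
  for (s in unique(segments)) {
    i <- which(segments == s)
    if (length(i) < window) {
      stop(sprintf("segment %d shorter than the filter window (%d < %d)",
                   s, length(i), window), call. = FALSE)
    }
    step <- mean(diff(wavenumber[i]))
    S <- sg_operator(length(i), window, polyorder, deriv_order)
    out[, i] <- X[, i, drop = FALSE] %*% t(S) / step^deriv_order
  }
  if (is_spec) {
    kind <- if (deriv_order == 2) "second_derivative" else spec$kind
    spectrum(wavenumber, out[1, ], kind = kind, segments = segments,
             strict = FALSE)
  } else {
    out
  }
}

#' Scale a spectrum to unit Euclidean norm
#'
#' @param spec An `ftir_spectrum` or numeric vector with nonzero norm.
#' @return Object of the same shape with `sqrt(sum(x^2)) = 1`.
#' @export
vector_normalize <- function(spec) {
  y <- if (inherits(spec, "ftir_spectrum")) spec$intensity else as.numeric(spec)
  nrm <- sqrt(sum(y^2))
  if (nrm == 0) stop("cannot vector-normalize a zero spectrum", call. = FALSE)
  if (inherits(spec, "ftir_spectrum")) {
    spectrum(spec$wavenumber, y / nrm, kind = spec$kind,
             segments = spec$segments, strict = FALSE)
  } else {
    y / nrm
  }
}

#' Run the full pre-processing chain on one sample image
#'
#' Applies, in order: region excision, rubber-band baseline correction per
#' pixel, k-means segmentation (cell pixels kept), spectral binning, EMSC
#' scatter correction against the reference, Savitzky-Golay smoothing,
#' averaging over cell pixels and vector normalization (the mean absorbance
#' spectrum); then the Savitzky-Golay second derivative and a second vector
#' normalization (the second-derivative spectrum).
#'
#' @param image An `ftir_image`.
#' @param reference Reference `ftir_spectrum` on the image's original axis.
#' @param params An [preprocess_params()] list.
#' @param sample_id,group Metadata; default to the image's attributes.
#' @param use_alt_deriv Use the `alt_deriv` preset for the derivative stage.
#' @return A [sample_record()].
#' @export
preprocess_sample <- function(image, reference, params = preprocess_params(),
                              sample_id = attr(image, "sample_id"),
                              group = attr(image, "group"),
                              use_alt_deriv = FALSE) {
  stopifnot(inherits(image, "ftir_image"))
  if (is.null(sample_id)) sample_id <- "sample"
  if (is.null(group)) group <- NA_character_

  img <- excise_region(image, params$excise_lo, params$excise_hi)
  cube <- rubberband_cube(img$cube, img$wavenumber, img$segments)
  corrected_img <- spectral_image(img$wavenumber, cube, img$n_rows, img$n_cols,
                                  segments = img$segments)
  mask <- segment_pixels(corrected_img, k = params$kmeans_k,
                         seed = params$kmeans_seed)
  if (!any(mask == "cell")) stop("no cell pixels after segmentation", call. = FALSE)
  cells <- spectral_image(img$wavenumber, cube[mask == "cell", , drop = FALSE],
                          1L, sum(mask == "cell"), segments = img$segments)
  cells <- bin_spectra(cells, params$bin_factor)

  ref <- excise_region(reference, params$excise_lo, params$excise_hi)
  ref <- bin_spectra(ref, params$bin_factor)
  if (!isTRUE(all.equal(ref$wavenumber, cells$wavenumber))) {
    stop("reference axis does not match the image axis", call. = FALSE)
  }
  sc <- params$scatter
  cormat <- scatter_correct(cells$cube, ref$intensity,
                            wavenumber = cells$wavenumber,
                            mode = sc$mode, n_clusters = sc$n_clusters,
                            poly_order = sc$poly_order,
                            n_mie_components = sc$n_mie_components,
                            mie_radius_range = sc$mie_radius_range,
                            mie_refidx_range = sc$mie_refidx_range,
                            seed = sc$seed)
  smoothed <- savgol(cormat, window = params$smooth$window,
                     polyorder = params$smooth$polyorder, deriv_order = 0,
                     wavenumber = cells$wavenumber, segments = cells$segments)
  mean_abs <- vector_normalize(spectrum(cells$wavenumber, colMeans(smoothed),
                                        segments = cells$segments,
                                        strict = FALSE))
  dpar <- if (use_alt_deriv) params$alt_deriv else params$deriv
  d2 <- vector_normalize(savgol(mean_abs, window = dpar$window,
                                polyorder = dpar$polyorder,
                                deriv_order = dpar$order))
  sample_record(sample_id, group, mean_abs, d2)
}
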