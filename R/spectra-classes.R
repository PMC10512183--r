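# Core domain objects: spectra, spectral images, sample records, cohorts.
#
# All spectra carry their wavenumber axis in strictly ascending order,
# whatever the order of the source file (FTIR instruments conventionally
# print high-to-low). A `segments` vector marks contiguous runs of the axis;
# region excision splits the axis into segments, and segment-aware
# operations (baseline, derivatives, integration) never bridge a gap.

#' Construct a spectrum
#'
#' A spectrum pairs a wavenumber axis (cm^-1) with one intensity value per
#' axis point. The axis is stored in ascending order; descending input is
#' reversed together with its intensities.
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1), strictly
#'   monotonic, finite, positive, length >= 8 (shorter axes are allowed
#'   only via `strict = FALSE`, used internally for sliced regions).
#' @param intensity Numeric vector, same length as `wavenumber`.
#' @param kind Either `"absorbance"` or `"second_derivative"`.
#' @param segments Optional integer vector of contiguous-segment ids
#'   (non-decreasing along the ascending axis). Defaults to a single segment.
#' @param strict If `TRUE` (default) enforce the minimum axis length of 8.
#' @return An object of class `ftir_spectrum` with fields `wavenumber`,
#'   `intensity`, `kind`, `segments`.
#' @export
spectrum <- function(wavenumber, intensity, kind = c("absorbance", "second_derivative"),
                     segments = NULL, strict = TRUE) {
  kind <- match.arg(kind)
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have equal length", call. = FALSE)
  }
  if (strict && length(wavenumber) < 8) {
    stop("axis must have at least 8 points", call. = FALSE)
  }
  if (length(wavenumber) < 1) stop("axis must be non-empty", call. = FALSE)
  if (!all(is.finite(wavenumber)) || any(wavenumber <= 0)) {
    stop("wavenumbers must be finite and positive", call. = FALSE)
  }
  if (!all(is.finite(intensity))) stop("intensities must be finite", call. = FALSE)
  d <- diff(wavenumber)
  if (length(d) && all(d < 0)) {
    wavenumber <- rev(wavenumber)
    intensity <- rev(intensity)
    if (!is.null(segments)) segments <- rev(segments)
    d <- -rev(d)
  }
  if (length(d) && any(d <= 0)) {
    stop("wavenumber axis must be strictly monotonic", call. = FALSE)
  }
  if (is.null(segments)) segments <- rep.int(1L, length(wavenumber))
  segments <- as.integer(segments)
  if (length(segments) != length(wavenumber) || is.unsorted(segments)) {
    stop("segments must be a non-decreasing id per axis point", call. = FALSE)
  }
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 kind = kind, segments = segments),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum: %s, %d points, %.0f-%.0f cm^-1, %d segment(s)>\n",
              x$kind, length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              length(unique(x$segments))))
  invisible(x)
}

#' Construct a hyperspectral image
#'
#' One spectrum per pixel on a rectangular grid, all sharing one axis.
#' Pixels are stored row-major: pixel index `(r, c)` maps to cube row
#' `(r - 1) * n_cols + c`.
#'
#' @param wavenumber Ascending wavenumber axis (cm^-1).
#' @param cube Numeric matrix, `n_rows * n_cols` rows (pixels) by
#'   `length(wavenumber)` columns.
#' @param n_rows,n_cols Pixel grid dimensions.
#' @param mask Optional character vector, one of `"cell"`, `"background"`,
#'   `"unassigned"` per pixel.
#' @param segments Optional segment ids (see [spectrum()]).
#' @return An object of class `ftir_image`.
#' @export
spectral_image <- function(wavenumber, cube, n_rows, n_cols, mask = NULL,
                           segments = NULL) {
  wavenumber <- as.numeric(wavenumber)
  cube <- as.matrix(cube)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (nrow(cube) != n_rows * n_cols) {
    stop("cube must have n_rows * n_cols pixel rows", call. = FALSE)
  }
  if (ncol(cube) != length(wavenumber)) {
    stop("cube columns must match axis length", call. = FALSE)
  }
  d <- diff(wavenumber)
  if (length(d) && all(d < 0)) {
    wavenumber <- rev(wavenumber)
    cube <- cube[, rev(seq_len(ncol(cube))), drop = FALSE]
    if (!is.null(segments)) segments <- rev(segments)
  } else if (length(d) && any(d <= 0)) {
    stop("wavenumber axis must be strictly monotonic", call. = FALSE)
  }
  if (!is.null(mask)) {
    if (length(mask) != nrow(cube) ||
        !all(mask %in% c("cell", "background", "unassigned"))) {
      stop("mask must label every pixel as cell/background/unassigned",
           call. = FALSE)
    }
  }
  if (is.null(segments)) segments <- rep.int(1L, length(wavenumber))
  structure(list(wavenumber = wavenumber, cube = cube,
                 n_rows = n_rows, n_cols = n_cols, mask = mask,
                 segments = as.integer(segments)),
            class = "ftir_image")
}

#' @export
print.ftir_image <- function(x, ...) {
  cat(sprintf("<ftir_image: %dx%d pixels, %d axis points%s>\n",
              x$n_rows, x$n_cols, length(x$wavenumber),
              if (is.null(x$mask)) "" else
                sprintf(", %d cell px", sum(x$mask == "cell"))))
  invisible(x)
}

#' Construct a per-sample record
#'
#' Holds the fully pre-processed outputs for one sample: the vector-normalized
#' mean absorbance spectrum and its vector-normalized second derivative, both
#' on one shared axis.
#'
#' @param sample_id Character scalar.
#' @param group Group label (e.g. `"CTRL"`, `"MS"`, `"ALS"`), or `NA`.
#' @param mean_absorbance An absorbance [spectrum()].
#' @param second_derivative A second-derivative [spectrum()] (may be `NULL`
#'   before the derivative stage has run).
#' @return An object of class `ftir_sample`.
#' @export
sample_record <- function(sample_id, group, mean_absorbance,
                          second_derivative = NULL) {
  stopifnot(inherits(mean_absorbance, "ftir_spectrum"))
  if (!is.null(second_derivative)) {
    stopifnot(inherits(second_derivative, "ftir_spectrum"))
    if (second_derivative$kind != "second_derivative") {
      stop("second_derivative spectrum must have kind 'second_derivative'",
           call. = FALSE)
    }
    if (!isTRUE(all.equal(mean_absorbance$wavenumber,
                          second_derivative$wavenumber))) {
      stop("both spectra of a sample must share one axis", call. = FALSE)
    }
  }
  structure(list(sample_id = as.character(sample_id),
                 group = as.character(group),
                 mean_absorbance = mean_absorbance,
                 second_derivative = second_derivative),
            class = "ftir_sample")
}

#' Construct a cohort table
#'
#' An ordered collection of [sample_record()]s with unique sample ids and a
#' single shared axis.
#'
#' @param records List of `ftir_sample` objects.
#' @return An object of class `ftir_cohort`.
#' @export
cohort_table <- function(records) {
  if (!length(records)) stop("cohort must contain at least one sample", call. = FALSE)
  stopifnot(all(vapply(records, inherits, logical(1), "ftir_sample")))
  ids <- vapply(records, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  ax <- records[[1]]$mean_absorbance$wavenumber
  for (r in records) {
    if (!isTRUE(all.equal(r$mean_absorbance$wavenumber, ax))) {
      stop("all cohort samples must share one wavenumber axis", call. = FALSE)
    }
  }
  names(records) <- ids
  structure(list(records = records), class = "ftir_cohort")
}

#' @export
print.ftir_cohort <- function(x, ...) {
  g <- cohort_groups(x)
  cat(sprintf("<ftir_cohort: %d samples (%s)>\n", length(x$records),
              paste(sprintf("%s: %d", names(table(g)), table(g)), collapse = ", ")))
  invisible(x)
}

#' Group labels of a cohort, in sample order
#' @param cohort An `ftir_cohort`.
#' @return Character vector of group labels.
#' @export
cohort_groups <- function(cohort) {
  vapply(cohort$records, function(r) r$group, character(1))
}

#' Cohort spectra as a samples-by-wavenumbers matrix
#'
#' @param cohort An `ftir_cohort`.
#' @param which `"mean_absorbance"` or `"second_derivative"`.
#' @return Numeric matrix with sample ids as row names and wavenumbers as
#'   column names.
#' @export
cohort_matrix <- function(cohort, which = c("mean_absorbance", "second_derivative")) {
  which <- match.arg(which)
  sp <- lapply(cohort$records, `[[`, which)
  if (any(vapply(sp, is.null, logical(1)))) {
    stop("some samples lack a ", which, " spectrum", call. = FALSE)
  }
  m <- do.call(rbind, lapply(sp, `[[`, "intensity"))
  rownames(m) <- names(cohort$records)
  colnames(m) <- format(sp[[1]]$wavenumber, trim = TRUE)
  m
}

axis_of <- function(obj) {
  if (inherits(obj, "ftir_cohort")) obj$records[[1]]$mean_absorbance$wavenumber
  else obj$wavenumber
}
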