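# Plain-text interchange: CSV spectral matrices (wavenumber axis in the
# first column, one column per pixel or sample) with an optional JSON
# sidecar declaring image geometry and sample metadata. No proprietary
# instrument formats are read.

#' Read a spectral matrix from CSV
#'
#' The file holds wavenumbers in its first column and one intensity column
#' per pixel (image) or per sample (cohort). Leading `#` comment lines are
#' skipped. A JSON sidecar with fields `n_rows` / `n_cols` declares image
#' geometry; without one the columns are read as per-sample mean absorbance
#' spectra and returned as a cohort. Axes are normalized to ascending order,
#' so high-to-low instrument exports load identically to low-to-high ones.
#'
#' @param path CSV file path.
#' @param sidecar Optional path to a JSON sidecar. Defaults to
#'   `<path>.json` when that file exists.
#' @param metadata Optional data frame (or CSV path) with columns
#'   `sample_id` and `group`, used to label cohort columns.
#' @return An [spectral_image()] when geometry is declared, otherwise an
#'   [cohort_table()] whose records carry the file columns as
#'   `mean_absorbance`.
#' @export
read_spectral_matrix <- function(path, sidecar = NULL, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged row in %s: data line %d has %d fields, expected %d",
                 path, bad, widths[bad], widths[1]), call. = FALSE)
  }
  header <- parts[[1]]
  data_rows <- parts[-1]
  if (!length(data_rows)) stop("no data rows in ", path, call. = FALSE)
  num <- vapply(data_rows, function(p) suppressWarnings(as.numeric(p)),
                numeric(length(header)))
  num <- if (is.null(dim(num))) matrix(num, nrow = length(header)) else num
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell in %s at data line %d, column %d",
                 path, idx[2] + 1L, idx[1]), call. = FALSE)
  }
  wn <- num[1, ]
  vals <- num[-1, , drop = FALSE]      # file columns as rows, axis along columns
  ord <- order(wn)
  wn <- wn[ord]
  if (anyDuplicated(wn) || any(diff(wn) <= 0)) {
    stop("wavenumber axis is not strictly monotonic after sorting: ", path,
         call. = FALSE)
  }
  vals <- vals[, ord, drop = FALSE]
  ids <- header[-1]
  rownames(vals) <- ids

  if (is.null(sidecar) && file.exists(paste0(path, ".json"))) {
    sidecar <- paste0(path, ".json")
  }
  meta <- if (!is.null(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL

  if (!is.null(meta) && !is.null(meta$n_rows) && !is.null(meta$n_cols)) {
    img <- spectral_image(wn, vals, meta$n_rows, meta$n_cols,
                          mask = if (!is.null(meta$mask)) unlist(meta$mask) else NULL)
    attr(img, "sample_id") <- meta$sample_id
    attr(img, "group") <- meta$group
    return(img)
  }

  if (is.character(metadata)) metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  grp <- rep(NA_character_, length(ids))
  if (!is.null(metadata)) {
    grp <- metadata$group[match(ids, metadata$sample_id)]
  }
  records <- lapply(seq_along(ids), function(i) {
    sample_record(ids[i], grp[i], spectrum(wn, vals[i, ]))
  })
  cohort_table(records)
}

#' Write a spectrum, image or cohort to CSV
#'
#' Output is deterministic: columns sorted by id, a fixed `%.12g` decimal
#' format declared in the header comment, and the ascending internal axis.
#' Images additionally get a JSON sidecar (`<path>.json`) with their
#' geometry and, when present, mask and sample metadata.
#'
#' @param obj An `ftir_spectrum`, `ftir_image` or `ftir_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectral_matrix <- function(obj, path) {
  fmt <- function(x) sprintf("%.12g", x)
  if (inherits(obj, "ftir_spectrum")) {
    mat <- matrix(obj$intensity, ncol = 1, dimnames = list(NULL, "intensity"))
    wn <- obj$wavenumber
  } else if (inherits(obj, "ftir_image")) {
    mat <- t(obj$cube)
    colnames(mat) <- sprintf("px%04d", seq_len(nrow(obj$cube)))
    wn <- obj$wavenumber
  } else if (inherits(obj, "ftir_cohort")) {
    if (!length(obj$records)) stop("refusing to write an empty cohort", call. = FALSE)
    ids <- sort(names(obj$records))
    mat <- sapply(ids, function(id) obj$records[[id]]$mean_absorbance$intensity)
    wn <- obj$records[[1]]$mean_absorbance$wavenumber
  } else {
    stop("unsupported object type for write_spectral_matrix", call. = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# fibrospec spectral matrix; numeric format %.12g",
               paste(c("wavenumber", colnames(mat)), collapse = ",")), con)
  body <- apply(cbind(fmt(wn), matrix(fmt(mat), nrow = nrow(mat))), 1,
                paste, collapse = ",")
  writeLines(body, con)
  if (inherits(obj, "ftir_image")) {
    side <- list(n_rows = obj$n_rows, n_cols = obj$n_cols)
    if (!is.null(obj$mask)) side$mask <- obj$mask
    if (!is.null(attr(obj, "sample_id"))) side$sample_id <- attr(obj, "sample_id")
    if (!is.null(attr(obj, "group"))) side$group <- attr(obj, "group")
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Extract a closed wavenumber region from a spectrum
#'
#' Keeps exactly the measured axis points with `lo <= wavenumber <= hi`
#' (closed interval, no endpoint interpolation).
#'
#' @param spec An `ftir_spectrum`.
#' @param lo,hi Region bounds in cm^-1, `lo < hi`.
#' @return An `ftir_spectrum` restricted to the region.
#' @export
slice_region <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "ftir_spectrum"))
  if (!(lo < hi)) stop("region bounds must satisfy lo < hi", call. = FALSE)
  keep <- spec$wavenumber >= lo & spec$wavenumber <= hi
  if (!any(keep)) {
    stop(sprintf("no axis point in region %g-%g cm^-1", lo, hi), call. = FALSE)
  }
  spectrum(spec$wavenumber[keep], spec$intensity[keep], kind = spec$kind,
           segments = spec$segments[keep], strict = FALSE)
}
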