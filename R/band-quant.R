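# Band-region library, trapezoidal band integration, ratio panels, and
# second-derivative peak-position analysis.

#' The standard mid-IR band-region table
#'
#' Fourteen named closed wavenumber regions covering the protein amide
#' bands, the C-H stretch lipid region and its four sub-bands, the lipid
#' carbonyl ester and acyl-chain bands, and the mixed
#' carbohydrate/phosphate region.
#'
#' @return Data frame with columns `name`, `lo`, `hi` (cm^-1) and
#'   `category` (`protein`/`lipid`/`mixed`).
#' @export
default_band_table <- function() {
  tb <- rbind(
    data.frame(name = "amide_A",          lo = 3260, hi = 3315, category = "protein"),
    data.frame(name = "amide_B",          lo = 3000, hi = 3120, category = "protein"),
    data.frame(name = "amide_I",          lo = 1580, hi = 1700, category = "protein"),
    data.frame(name = "amide_II",         lo = 1480, hi = 1580, category = "protein"),
    data.frame(name = "amide_II_choline", lo = 1485, hi = 1500, category = "protein"),
    data.frame(name = "amide_III",        lo = 1185, hi = 1300, category = "protein"),
    data.frame(name = "total_lipids",     lo = 2800, hi = 3000, category = "lipid"),
    data.frame(name = "ch3_asym",         lo = 2950, hi = 2972, category = "lipid"),
    data.frame(name = "ch2_asym",         lo = 2912, hi = 2936, category = "lipid"),
    data.frame(name = "ch3_sym",          lo = 2865, hi = 2880, category = "lipid"),
    data.frame(name = "ch2_sym",          lo = 2843, hi = 2860, category = "lipid"),
    data.frame(name = "carbonyl_ester",   lo = 1725, hi = 1750, category = "lipid"),
    data.frame(name = "acyl_chain",       lo = 1430, hi = 1470, category = "lipid"),
    data.frame(name = "mixed",            lo = 1000, hi = 1300, category = "mixed")
  )
  tb
}

get_region <- function(name, band_table = default_band_table()) {
  r <- band_table[band_table$name == name, ]
  if (!nrow(r)) stop("unknown band region: ", name, call. = FALSE)
  r[1, ]
}

#' Integrate a spectrum over a band region
#'
#' Trapezoidal rule over the measured axis points inside the closed region
#' `[lo, hi]`. The region must lie within a single retained segment (it may
#' not bridge an excised gap).
#'
#' @param spec An absorbance `ftir_spectrum`.
#' @param region A one-row band-table data frame, a region name, or a
#'   numeric `c(lo, hi)`.
#' @param band_table Lookup table used when `region` is a name.
#' @return Integrated area, AU * cm^-1.
#' @export
integrate_band <- function(spec, region, band_table = default_band_table()) {
  stopifnot(inherits(spec, "ftir_spectrum"))
  if (spec$kind != "absorbance") {
    stop("band integration expects an absorbance spectrum", call. = FALSE)
  }
  if (is.character(region)) region <- get_region(region, band_table)
  if (is.data.frame(region)) region <- c(region$lo, region$hi)
  sl <- slice_region(spec, region[1], region[2])
  if (length(unique(sl$segments)) > 1) {
    stop(sprintf("region %g-%g cm^-1 bridges an excised gap",
                 region[1], region[2]), call. = FALSE)
  }
  if (length(sl$wavenumber) < 2) {
    stop("region contains fewer than 2 axis points", call. = FALSE)
  }
  pracma::trapz(sl$wavenumber, sl$intensity)
}

#' The standard band-ratio panel
#'
#' Eight primary ratios (carbonyl ester over total lipids, acyl chain,
#' asymmetric CH3 and mixed region; amide I over amide II, amide A, total
#' lipids and carbonyl ester) plus four supplementary lipid-order ratios:
#' membrane polarity (asym CH2 / sym CH3), chain packing (sym CH2 / sym
#' CH3), saturation degree (asym CH2 / asym CH3) and phospholipid chain
#' length (asym CH2 / total lipids). Ratios are of integrated band areas,
#' using the standard band-table regions.
#'
#' @return Data frame with columns `name`, `numerator`, `denominator`.
#' @export
default_ratio_panel <- function() {
  rbind(
    data.frame(name = "carbonyl_ester/total_lipids", numerator = "carbonyl_ester", denominator = "total_lipids"),
    data.frame(name = "carbonyl_ester/acyl_chain",   numerator = "carbonyl_ester", denominator = "acyl_chain"),
    data.frame(name = "carbonyl_ester/ch3_asym",     numerator = "carbonyl_ester", denominator = "ch3_asym"),
    data.frame(name = "amide_I/amide_II",            numerator = "amide_I",        denominator = "amide_II"),
    data.frame(name = "amide_I/amide_A",             numerator = "amide_I",        denominator = "amide_A"),
    data.frame(name = "amide_I/total_lipids",        numerator = "amide_I",        denominator = "total_lipids"),
    data.frame(name = "amide_I/carbonyl_ester",      numerator = "amide_I",        denominator = "carbonyl_ester"),
    data.frame(name = "carbonyl_ester/mixed",        numerator = "carbonyl_ester", denominator = "mixed"),
    data.frame(name = "membrane_polarity",           numerator = "ch2_asym",       denominator = "ch3_sym"),
    data.frame(name = "chain_packing",               numerator = "ch2_sym",        denominator = "ch3_sym"),
    data.frame(name = "saturation_degree",           numerator = "ch2_asym",       denominator = "ch3_asym"),
    data.frame(name = "chain_length",                numerator = "ch2_asym",       denominator = "total_lipids")
  )
}

#' Compute the ratio panel for a cohort
#'
#' Each panel cell is the ratio of the two integrated band areas on that
#' sample's mean absorbance spectrum. A non-positive denominator area flags
#' the cell as `NA` (with a warning); the run continues.
#'
#' @param cohort An `ftir_cohort` whose records carry `mean_absorbance`.
#' @param panel Ratio definitions (see [default_ratio_panel()]).
#' @param band_table Band-region lookup table.
#' @return List of class `ftir_ratio_panel`: `values` (samples x ratios
#'   matrix), `groups`, and `summary` (per group x ratio mean and SD).
#' @export
compute_ratio_panel <- function(cohort, panel = default_ratio_panel(),
                                band_table = default_band_table()) {
  stopifnot(inherits(cohort, "ftir_cohort"))
  ids <- names(cohort$records)
  vals <- matrix(NA_real_, length(ids), nrow(panel),
                 dimnames = list(ids, panel$name))
  n_flagged <- 0L
  for (i in seq_along(ids)) {
    sp <- cohort$records[[i]]$mean_absorbance
    needed <- unique(c(panel$numerator, panel$denominator))
    areas <- vapply(needed, function(nm) integrate_band(sp, nm, band_table),
                    numeric(1))
    for (j in seq_len(nrow(panel))) {
      num <- areas[[panel$numerator[j]]]
      den <- areas[[panel$denominator[j]]]
      if (!is.finite(den) || den <= 0) {
        n_flagged <- n_flagged + 1L
      } else {
        vals[i, j] <- num / den
      }
    }
  }
  if (n_flagged) warning(n_flagged, " ratio cells had non-positive denominators; set NA")
  groups <- cohort_groups(cohort)
  summ <- do.call(rbind, lapply(unique(groups), function(g) {
    sub <- vals[groups == g, , drop = FALSE]
    data.frame(group = g, ratio = colnames(vals),
               mean = colMeans(sub, na.rm = TRUE),
               sd = apply(sub, 2, stats::sd, na.rm = TRUE),
               row.names = NULL)
  }))
  structure(list(values = vals, groups = groups, summary = summ),
            class = "ftir_ratio_panel")
}

# local minima of y with topographic-style prominence; returns indices
local_minima <- function(y, prominence_frac = 0.05) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] < y[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  rng <- diff(range(y))
  if (rng == 0) return(integer(0))
  keep <- vapply(cand, function(i) {
    left_max <- max(y[1:i]); right_max <- max(y[i:n])
    (min(left_max, right_max) - y[i]) >= prominence_frac * rng
  }, logical(1))
  cand[keep]
}

#' Locate second-derivative band minima in a region
#'
#' In second-derivative spectra, absorbance band centers appear as
#' negative-valued local minima. A minimum qualifies when it is lower than
#' both neighbors, negative (band curvature, not the dip between two
#' positive side lobes), and its prominence (height of the lower enclosing
#' maximum above it) exceeds `prominence_frac` of the region's dynamic
#' range.
#'
#' @param record An `ftir_sample` with a `second_derivative` spectrum.
#' @param region Region name, band-table row, or `c(lo, hi)`.
#' @param prominence_frac Noise guard, fraction of the region range.
#' @param band_table Lookup table for named regions.
#' @return List: `region` bounds, `positions` (cm^-1, ascending),
#'   `depths` (second-derivative values at the minima), `count`.
#' @export
locate_band_minima <- function(record, region, prominence_frac = 0.05,
                               band_table = default_band_table()) {
  stopifnot(inherits(record, "ftir_sample"))
  if (is.null(record$second_derivative)) {
    stop("sample has no second-derivative spectrum", call. = FALSE)
  }
  if (is.character(region)) region <- get_region(region, band_table)
  if (is.data.frame(region)) region <- c(region$lo, region$hi)
  sl <- slice_region(record$second_derivative, region[1], region[2])
  idx <- local_minima(sl$intensity, prominence_frac)
  idx <- idx[sl$intensity[idx] < 0]
  list(region = region, positions = sl$wavenumber[idx],
       depths = sl$intensity[idx], count = length(idx))
}

#' Compare second-derivative peak positions across groups
#'
#' Tracks the most prominent (deepest) minimum per sample in the region
#' (ties broken toward the lower wavenumber), averages positions per group,
#' and reports each non-reference group's shift relative to the reference
#' group (positive = shifted to higher wavenumbers). Samples with no
#' qualifying minimum are excluded with a warning.
#'
#' @param cohort An `ftir_cohort` with second derivatives.
#' @param region Region name, band-table row, or `c(lo, hi)`.
#' @param ref_group Reference group for shifts (default `"CTRL"`, else the
#'   first group present).
#' @param prominence_frac Passed to [locate_band_minima()].
#' @param band_table Lookup table for named regions.
#' @return List: `per_sample` data frame (sample_id, group, position,
#'   count), `group_means`, `shifts` (named, cm^-1).
#' @export
compare_peak_positions <- function(cohort, region, ref_group = "CTRL",
                                   prominence_frac = 0.05,
                                   band_table = default_band_table()) {
  stopifnot(inherits(cohort, "ftir_cohort"))
  rows <- lapply(cohort$records, function(r) {
    pk <- locate_band_minima(r, region, prominence_frac, band_table)
    if (!pk$count) return(NULL)
    deepest <- which(pk$depths == min(pk$depths))[1]   # tie -> lower wavenumber
    data.frame(sample_id = r$sample_id, group = r$group,
               position = pk$positions[deepest], count = pk$count,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped) warning(dropped, " sample(s) had no qualifying minimum; excluded")
  per_sample <- do.call(rbind, rows)
  if (is.null(per_sample) || !nrow(per_sample)) {
    stop("no sample yielded a minimum in the region", call. = FALSE)
  }
  gm <- tapply(per_sample$position, per_sample$group, mean)
  if (!ref_group %in% names(gm)) ref_group <- names(gm)[1]
  shifts <- gm[setdiff(names(gm), ref_group)] - gm[[ref_group]]
  list(per_sample = per_sample, group_means = gm, shifts = shifts,
       ref_group = ref_group)
}
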