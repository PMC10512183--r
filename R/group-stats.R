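# Univariate group statistics for the ratio panel: one-way ANOVA with
# Tukey HSD post-hoc comparisons, Brown-Forsythe homoscedasticity and
# Shapiro-Wilk normality diagnostics, and star-style significance labels.

as_group_list <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (!is.list(groups)) stop("groups must be a list of numeric vectors", call. = FALSE)
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (!all(vapply(groups, function(x) all(is.finite(x)), logical(1)))) {
    stop("group values must be finite", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way ANOVA
#'
#' Classical between/within sum-of-squares decomposition with the p-value
#' from the F distribution.
#'
#' @param groups Named list of numeric vectors (one per group), each with
#'   n >= 2.
#' @return List: `F`, `df_between`, `df_within`, `p`, `ms_within`,
#'   `group_means`, `group_n`.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  k <- length(groups); n <- length(x)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(lengths(groups) * (means - mean(x))^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- k - 1; df_w <- n - k
  if (ss_within == 0 && ss_between == 0) {
    stop("all observations identical: F undefined", call. = FALSE)
  }
  ms_b <- ss_between / df_b; ms_w <- ss_within / df_w
  f <- ms_b / ms_w
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  list(F = f, df_between = df_b, df_within = df_w, p = p,
       ms_within = ms_w, group_means = means, group_n = lengths(groups))
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise group comparisons after one-way ANOVA, using the
#' studentized-range distribution (Tukey-Kramer standard errors for
#' unequal group sizes). Adjusted p-values come from `stats::ptukey`.
#'
#' @param groups Named list of numeric vectors.
#' @return Data frame: `group1`, `group2`, `diff` (mean2 - mean1), `q`,
#'   `p_adj`, `stars`.
#' @export
tukey_hsd <- function(groups) {
  groups <- as_group_list(groups)
  an <- one_way_anova(groups)
  if (an$ms_within == 0) stop("zero within-group variance: Tukey q undefined", call. = FALSE)
  k <- length(groups)
  pairs <- utils::combn(names(groups), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- an$group_means[[b]] - an$group_means[[a]]
    se <- sqrt(an$ms_within * (1 / an$group_n[[a]] + 1 / an$group_n[[b]]) / 2)
    q <- abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = an$df_within, lower.tail = FALSE)
    data.frame(group1 = a, group2 = b, diff = d, q = q, p_adj = p,
               stringsAsFactors = FALSE)
  }))
  out$stars <- annotate_significance(out$p_adj)
  out
}

#' Brown-Forsythe homoscedasticity test
#'
#' One-way ANOVA applied to the absolute deviations from each group's
#' median.
#'
#' @param groups Named list of numeric vectors.
#' @return List: `stat` (F on the deviations), `df_between`, `df_within`,
#'   `p`.
#' @export
brown_forsythe <- function(groups) {
  groups <- as_group_list(groups)
  z <- lapply(groups, function(v) abs(v - stats::median(v)))
  an <- one_way_anova(z)
  list(stat = an$F, df_between = an$df_between, df_within = an$df_within,
       p = an$p)
}

#' Shapiro-Wilk normality test
#'
#' Wrapper around `stats::shapiro.test` (Royston's AS R94 approximation).
#'
#' @param sample Numeric vector, 3 <= n <= 5000, not constant.
#' @return List: `W`, `p`.
#' @export
shapiro_wilk <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 3 || length(sample) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(sample) == 0) stop("constant sample: W undefined", call. = FALSE)
  ht <- stats::shapiro.test(sample)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Star-style significance labels
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001 (strict inequalities).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
annotate_significance <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Per-ratio ANOVA, Tukey and diagnostics for a ratio panel
#'
#' Runs one-way ANOVA with Tukey HSD on every ratio of a panel result,
#' plus per-group Shapiro-Wilk and Brown-Forsythe diagnostics. The
#' diagnostics are reported but never gate the ANOVA. No multiplicity
#' correction is applied across ratios by default; `p_adjust = "BH"`
#' adds Benjamini-Hochberg-adjusted ANOVA p-values as an extra column.
#'
#' @param panel_result An `ftir_ratio_panel` from [compute_ratio_panel()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return List: `anova` (data frame: ratio, F, dfs, p, stars), `tukey`
#'   (data frame with one row per ratio x pair), `diagnostics` (data frame:
#'   ratio, group, shapiro_W, shapiro_p, plus Brown-Forsythe stat/p per
#'   ratio).
#' @export
ratio_panel_stats <- function(panel_result, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(panel_result, "ftir_ratio_panel"))
  vals <- panel_result$values
  groups <- panel_result$groups
  anova_rows <- list(); tukey_rows <- list(); diag_rows <- list()
  for (ratio in colnames(vals)) {
    v <- vals[, ratio]
    ok <- is.finite(v)
    gl <- split(v[ok], groups[ok])
    an <- one_way_anova(gl)
    tk <- tukey_hsd(gl)
    bf <- brown_forsythe(gl)
    anova_rows[[ratio]] <- data.frame(
      ratio = ratio, F = an$F, df_between = an$df_between,
      df_within = an$df_within, p = an$p,
      stars = annotate_significance(an$p), stringsAsFactors = FALSE)
    tk$ratio <- ratio
    tukey_rows[[ratio]] <- tk
    sw <- do.call(rbind, lapply(names(gl), function(g) {
      s <- shapiro_wilk(gl[[g]])
      data.frame(ratio = ratio, group = g, shapiro_W = s$W, shapiro_p = s$p,
                 bf_stat = bf$stat, bf_p = bf$p, stringsAsFactors = FALSE)
    }))
    diag_rows[[ratio]] <- sw
  }
  anova_df <- do.call(rbind, anova_rows)
  rownames(anova_df) <- NULL
  if (p_adjust == "BH") anova_df$p_bh <- stats::p.adjust(anova_df$p, "BH")
  list(anova = anova_df,
       tukey = do.call(rbind, c(tukey_rows, make.row.names = FALSE)),
       diagnostics = do.call(rbind, c(diag_rows, make.row.names = FALSE)))
}
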