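# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# O(n^2) lower convex hull by gift wrapping: from each support point, the
# next support point is the one with the minimal slope.
oracle_lower_hull_baseline <- function(x, y) {
  n <- length(x)
  idx <- 1L
  i <- 1L
  while (i < n) {
    slopes <- (y[(i + 1):n] - y[i]) / (x[(i + 1):n] - x[i])
    j <- i + which.min(slopes)
    idx <- c(idx, j)
    i <- j
  }
  stats::approx(x[idx], y[idx], xout = x)$y
}

# Savitzky-Golay by explicit per-point polynomial regression (lm), with
# truncated windows at the edges; derivative scaled by the axis step.
oracle_savgol <- function(x, y, window, polyorder, deriv) {
  n <- length(y)
  h <- (window - 1) %/% 2
  step <- mean(diff(x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    off <- (lo:hi) - i
    fit <- stats::lm(y[lo:hi] ~ poly(off, polyorder, raw = TRUE))
    out[i] <- unname(stats::coef(fit)[deriv + 1]) * factorial(deriv) / step^deriv
  }
  out
}

# dense PLS2 (regression mode) by iterative NIPALS
oracle_nipals_pls2 <- function(X, y, ncomp, scale = TRUE) {
  lev <- sort(unique(y))
  Y <- stats::model.matrix(~ 0 + factor(y, levels = lev))
  Xd <- scale(X, center = TRUE, scale = scale)
  Yd <- scale(Y, center = TRUE, scale = FALSE)
  Tm <- matrix(0, nrow(X), ncomp)
  for (h in seq_len(ncomp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    w_old <- rep(0, ncol(X))
    for (it in 1:500) {
      w <- drop(crossprod(Xd, u)); w <- w / sqrt(sum(w^2))
      t_h <- drop(Xd %*% w)
      c_h <- drop(crossprod(Yd, t_h)) / sum(t_h^2)
      u <- drop(Yd %*% c_h) / sum(c_h^2)
      if (sum((w - w_old)^2) < 1e-24) break
      w_old <- w
    }
    p_h <- drop(crossprod(Xd, t_h)) / sum(t_h^2)
    q_h <- drop(crossprod(Yd, t_h)) / sum(t_h^2)
    Xd <- Xd - tcrossprod(t_h, p_h)
    Yd <- Yd - tcrossprod(t_h, q_h)
    Tm[, h] <- t_h
  }
  Tm
}

# AUROC by explicit pairwise concordance counting (ties worth 1/2)
oracle_concordance_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# small fully separable 3-class dataset
make_separable <- function(n_per = 10, p = 30, sep = 4, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("A", "B", "C"), each = n_per)
    X <- matrix(stats::rnorm(3 * n_per * p), 3 * n_per, p)
    X[y == "B", 1] <- X[y == "B", 1] + sep
    X[y == "C", 2] <- X[y == "C", 2] + sep
    colnames(X) <- paste0("V", seq_len(p))
    list(X = X, y = y)
  })
}

# a null synthetic config: three groups, no injected effects
null_synth_config <- function(seed = 1L, ...) {
  no_eff <- list(amplitude_multipliers = numeric(0),
                 center_shifts = numeric(0), drop_bands = character(0))
  synthetic_cohort_config(
    effects = list(CTRL = no_eff, MS = no_eff, ALS = no_eff),
    seed = seed, ...)
}
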