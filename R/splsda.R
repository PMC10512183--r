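# Sparse partial least squares-discriminant analysis (sPLS-DA) on
# second-derivative spectra: per-component soft-thresholded variable
# selection, PLS2 regression-mode deflation of both X and Y, centroid
# -distance classification, stratified repeated cross-validated tuning by
# balanced error rate, and one-vs-rest AUROC.

# select exactly `keep` variables: top-|u| entries (ties toward the lower
# index), soft-shrunk by the (keep+1)-th largest magnitude
soft_select <- function(u, keep) {
  p <- length(u)
  au <- abs(u)
  if (keep >= p) return(u)
  idx <- order(au, decreasing = TRUE)[seq_len(keep)]
  lam <- sort(au, decreasing = TRUE)[keep + 1]
  mag <- au[idx] - lam
  mag[mag <= 0] <- 1e-12 * max(au)
  w <- numeric(p)
  w[idx] <- sign(u[idx]) * mag
  w
}

#' Fit an sPLS-DA model
#'
#' The class vector is dummy-coded to an indicator matrix; X columns are
#' centered (and unit-variance scaled by default) and Y columns centered.
#' Per component, the dominant singular pair of `t(X) %*% Y` gives the
#' X-weight vector, which is soft-thresholded so exactly `keepX[h]` entries
#' are nonzero, then renormalized; both X and Y are deflated by regression
#' on the component scores (PLS2 regression mode). Class centroids are the
#' class means of the score rows. Each weight vector's largest-magnitude
#' entry is made positive so loadings are reproducible.
#'
#' @param X Numeric matrix, samples x variables (no missing values).
#' @param y Class labels, one per row of X; every class needs >= 2 samples.
#' @param n_components Number of latent components, `<= min(n - 1, p)`.
#' @param keepX Integer vector (recycled to `n_components`): retained
#'   variables per component.
#' @param scale Unit-variance scale the X columns (default `TRUE`).
#' @return An object of class `ftir_splsda` with weights `W`, loadings
#'   `P`, `Q`, scores `T`, projection `Wstar`, centroids, centering/scaling
#'   vectors, class levels and the training variable map.
#' @export
splsda_fit <- function(X, y, n_components = 2, keepX = ncol(X), scale = TRUE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  y <- as.character(y)
  if (length(y) != nrow(X)) stop("y must have one label per row of X", call. = FALSE)
  lev <- sort(unique(y))
  if (any(table(y) < 2)) stop("every class needs at least 2 samples", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))

  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sum(const), " constant variable column(s) dropped")
    X <- X[, !const, drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  n_components <- as.integer(n_components)
  if (n_components > min(n - 1, p)) {
    stop("n_components must be <= min(n - 1, p)", call. = FALSE)
  }
  keepX <- as.integer(rep_len(keepX, n_components))
  if (any(keepX < 1)) stop("keepX entries must be >= 1", call. = FALSE)
  keepX <- pmin(keepX, p)

  Y <- stats::model.matrix(~ 0 + factor(y, levels = lev))
  colnames(Y) <- lev
  x_center <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  Xd <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- colMeans(Y)
  Yd <- sweep(Y, 2, y_center)
  X0 <- Xd

  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Q <- matrix(0, length(lev), n_components); Tm <- matrix(0, n, n_components)
  for (h in seq_len(n_components)) {
    M <- crossprod(Xd, Yd)
    sv <- svd(M, nu = 1, nv = 1)
    u <- sv$u[, 1]
    w <- soft_select(u, keepX[h])
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    t_h <- drop(Xd %*% w)
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(Xd, t_h)) / tt
    q_h <- drop(crossprod(Yd, t_h)) / tt
    Xd <- Xd - tcrossprod(t_h, p_h)
    Yd <- Yd - tcrossprod(t_h, q_h)
    W[, h] <- w; P[, h] <- p_h; Q[, h] <- q_h; Tm[, h] <- t_h
  }
  rownames(W) <- rownames(P) <- colnames(X)
  Wstar <- W %*% solve(crossprod(P, W))
  centroids <- do.call(rbind, lapply(lev, function(g) {
    colMeans(Tm[y == g, , drop = FALSE])
  }))
  rownames(centroids) <- lev
  structure(list(n_components = n_components, keepX = keepX,
                 W = W, P = P, Q = Q, T = Tm, Wstar = Wstar,
                 centroids = centroids, x_center = x_center,
                 x_scale = x_scale, y_center = y_center,
                 levels = lev, y = y, variables = colnames(X),
                 scale = scale),
            class = "ftir_splsda")
}

#' @export
print.ftir_splsda <- function(x, ...) {
  cat(sprintf("<ftir_splsda: %d components, keepX = %s, classes = %s>\n",
              x$n_components, paste(x$keepX, collapse = "/"),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict classes with a fitted sPLS-DA model
#'
#' New samples are centered/scaled with the training parameters, projected
#' through `W (P'W)^-1`, and assigned the class of the nearest centroid in
#' Euclidean score distance (ties go to the lexicographically first class).
#'
#' @param model An `ftir_splsda`.
#' @param X_new Matrix whose columns match the training variables (matched
#'   by name when column names are present, else by position).
#' @return List: `labels`, `scores` (latent coordinates), `yhat`
#'   (predicted class-indicator values), and `decision` (negative Euclidean
#'   centroid distances, the classifier's per-class decision values --
#'   the natural ranking score for one-vs-rest ROC analysis of a
#'   centroid-distance classifier).
#' @export
splsda_predict <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new))) {
    miss <- setdiff(model$variables, colnames(X_new))
    if (length(miss)) stop("missing variables: ", paste(utils::head(miss, 3), collapse = ", "),
                           call. = FALSE)
    X_new <- X_new[, model$variables, drop = FALSE]
  } else if (ncol(X_new) != length(model$variables)) {
    stop("X_new has ", ncol(X_new), " variables; model expects ",
         length(model$variables), call. = FALSE)
  }
  Xc <- sweep(sweep(X_new, 2, model$x_center), 2, model$x_scale, "/")
  S <- Xc %*% model$Wstar
  d2 <- outer(rowSums(S^2), rowSums(model$centroids^2), "+") -
    2 * S %*% t(model$centroids)
  labels <- model$levels[apply(d2, 1, which.min)]   # which.min: first = lexicographic
  yhat <- sweep(S %*% t(model$Q), 2, model$y_center, "+")
  colnames(yhat) <- model$levels
  decision <- -sqrt(pmax(d2, 0))
  colnames(decision) <- model$levels
  list(labels = labels, scores = S, yhat = yhat, decision = decision)
}

balanced_error <- function(truth, predicted, levels) {
  errs <- vapply(levels, function(g) {
    idx <- truth == g
    if (!any(idx)) return(NA_real_)
    mean(predicted[idx] != g)
  }, numeric(1))
  mean(errs, na.rm = TRUE)
}

stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (g in unique(y)) {
    idx <- sample(which(y == g))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Tune sPLS-DA by repeated stratified cross-validation
#'
#' keepX is chosen per component, sequentially: with earlier components
#' fixed at their chosen values, each candidate from `grid` is scored by
#' the mean balanced classification error over `folds`-fold stratified
#' cross-validation repeated `repeats` times (fold assignments re-drawn
#' each repeat from the seeded generator). Per component the candidate
#' with the smallest mean error wins (ties toward fewer variables); the
#' final number of components is the smallest one attaining the minimal
#' mean error.
#'
#' @param X,y Training data as in [splsda_fit()].
#' @param grid Candidate keepX values per component.
#' @param ncomp_max Maximum number of components examined.
#' @param folds Number of CV folds (every class needs >= `folds` members).
#' @param repeats Number of CV repetitions.
#' @param seed Integer seed.
#' @param scale Passed to [splsda_fit()].
#' @return List of class `ftir_splsda_tune`: `errors` (data frame:
#'   component, keepX, mean_error, sd_error), `chosen_keepX`,
#'   `chosen_ncomp`, `error_per_ncomp`, `seed`.
#' @export
tune_splsda <- function(X, y, grid = c(5, 10, 20, 40, 60, 80),
                        ncomp_max = 3, folds = 3, repeats = 50,
                        seed = 1L, scale = TRUE) {
  X <- as.matrix(X); y <- as.character(y)
  if (any(table(y) < folds)) stop("every class needs >= folds members", call. = FALSE)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  lev <- sort(unique(y))
  grid <- sort(unique(pmin(as.integer(grid), ncol(X))))
  ncomp_max <- min(ncomp_max, nrow(X) - 1, ncol(X))

  fold_sets <- withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) stratified_folds(y, folds))
  })
  chosen <- integer(0)
  err_rows <- list()
  best_per_ncomp <- numeric(ncomp_max)
  for (h in seq_len(ncomp_max)) {
    cand_err <- matrix(NA_real_, length(grid), repeats * folds)
    for (ci in seq_along(grid)) {
      keep <- c(chosen, grid[ci])
      col <- 0L
      for (r in seq_len(repeats)) {
        fl <- fold_sets[[r]]
        for (f in seq_len(folds)) {
          col <- col + 1L
          test <- fl == f
          fit <- splsda_fit(X[!test, , drop = FALSE], y[!test],
                            n_components = h, keepX = keep, scale = scale)
          pred <- splsda_predict(fit, X[test, , drop = FALSE])$labels
          cand_err[ci, col] <- balanced_error(y[test], pred, lev)
        }
      }
    }
    m <- rowMeans(cand_err)
    s <- apply(cand_err, 1, stats::sd)
    err_rows[[h]] <- data.frame(component = h, keepX = grid,
                                mean_error = m, sd_error = s)
    best <- which(m == min(m))[1]    # tie -> smaller keepX (grid sorted)
    chosen <- c(chosen, grid[best])
    best_per_ncomp[h] <- m[best]
  }
  ncomp <- which(best_per_ncomp == min(best_per_ncomp))[1]  # tie -> fewer comps
  structure(list(errors = do.call(rbind, err_rows),
                 chosen_keepX = chosen[seq_len(ncomp)],
                 chosen_ncomp = ncomp,
                 error_per_ncomp = best_per_ncomp, seed = seed),
            class = "ftir_splsda_tune")
}

#' One-vs-rest AUROC
#'
#' For each class, the area under the ROC curve of its predicted indicator
#' value against membership, computed as the Mann-Whitney concordance
#' probability (ties counted 1/2) via mid-ranks.
#'
#' @param scores Numeric matrix of per-sample predicted indicator values
#'   with one named column per class (e.g. `yhat` from
#'   [splsda_predict()]), or a vector for a binary problem.
#' @param y True class labels.
#' @return List of class `ftir_roc`: `auc` (named per class) and `curves`
#'   (per class data frame of false/true positive rates).
#' @export
auroc <- function(scores, y) {
  y <- as.character(y)
  if (is.null(dim(scores))) {
    lev <- sort(unique(y))
    if (length(lev) != 2) stop("vector scores require a binary y", call. = FALSE)
    scores <- cbind(-scores, scores)
    colnames(scores) <- lev
  }
  scores <- as.matrix(scores)
  auc <- numeric(ncol(scores)); names(auc) <- colnames(scores)
  curves <- list()
  for (g in colnames(scores)) {
    s <- scores[, g]
    pos <- y == g
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) stop("class ", g, " needs positives and negatives", call. = FALSE)
    r <- rank(s, ties.method = "average")
    auc[g] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- c(Inf, sort(unique(s), decreasing = TRUE))
    curves[[g]] <- data.frame(
      threshold = thr,
      fpr = vapply(thr, function(t) mean(s[!pos] >= t), numeric(1)),
      tpr = vapply(thr, function(t) mean(s[pos] >= t), numeric(1)))
  }
  structure(list(auc = auc, curves = curves), class = "ftir_roc")
}

#' Export numeric model artifacts
#'
#' Tables behind the standard sPLS-DA figures: per-sample score
#' coordinates, per-component loading tables restricted to the retained
#' variables, and Pearson correlations of each retained variable with each
#' component's scores.
#'
#' @param model A fitted `ftir_splsda`.
#' @param X The training matrix (for the correlation table).
#' @return List: `scores` (data frame), `loadings` (data frame), and
#'   `correlations` (data frame).
#' @export
export_model_artifacts <- function(model, X) {
  X <- as.matrix(X)[, model$variables, drop = FALSE]
  scores <- data.frame(sample_id = if (is.null(rownames(X)))
    seq_len(nrow(X)) else rownames(X),
    class = model$y, model$T, stringsAsFactors = FALSE)
  colnames(scores)[-(1:2)] <- paste0("comp", seq_len(model$n_components))
  loadings <- do.call(rbind, lapply(seq_len(model$n_components), function(h) {
    nz <- which(model$W[, h] != 0)
    data.frame(component = h, variable = model$variables[nz],
               weight = model$W[nz, h], stringsAsFactors = FALSE)
  }))
  correlations <- do.call(rbind, lapply(seq_len(model$n_components), function(h) {
    nz <- which(model$W[, h] != 0)
    data.frame(component = h, variable = model$variables[nz],
               correlation = as.numeric(stats::cor(X[, nz, drop = FALSE],
                                                   model$T[, h])),
               stringsAsFactors = FALSE)
  }))
  list(scores = scores, loadings = loadings, correlations = correlations)
}
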