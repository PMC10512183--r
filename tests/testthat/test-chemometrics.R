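test_that("model invariants hold: sparsity counts, unit weights, orthogonal scores", {
  d <- make_separable(seed = 2)
  m <- splsda_fit(d$X, d$y, n_components = 3, keepX = c(7, 4, 2))
  expect_equal(colSums(m$W != 0), c(7, 4, 2), ignore_attr = TRUE)
  expect_equal(colSums(m$W^2), rep(1, 3), ignore_attr = TRUE)
  G <- crossprod(m$T)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-6)
  # sign convention: dominant weight entry positive
  for (h in 1:3) expect_gt(m$W[which.max(abs(m$W[, h])), h], 0)
})

test_that("keepX = p reduces to dense NIPALS PLS-DA", {
  withr::with_seed(5, {
    for (case in 1:5) {
      n <- sample(12:30, 1); p <- sample(5:20, 1)
      y <- sample(rep(c("A", "B", "C"), length.out = n))
      while (min(table(y)) < 2) y <- sample(rep(c("A", "B", "C"), length.out = n))
      X <- matrix(stats::rnorm(n * p), n, p)
      ncomp <- 2
      m <- splsda_fit(X, y, n_components = ncomp, keepX = p)
      To <- oracle_nipals_pls2(X, y, ncomp)
      for (h in seq_len(ncomp)) {
        s <- sign(sum(m$T[, h] * To[, h]))
        expect_equal(m$T[, h], s * To[, h], tolerance = 1e-8)
      }
    }
  })
})

test_that("dense fit agrees with the mixOmics reference up to sign", {
  d <- make_separable(n_per = 8, p = 15, seed = 3)
  m <- splsda_fit(d$X, d$y, n_components = 2, keepX = 15)
  mo <- mixOmics::splsda(d$X, d$y, ncomp = 2, keepX = c(15, 15), scale = TRUE)
  cc <- abs(diag(stats::cor(m$T, mo$variates$X)))
  expect_equal(unname(cc), c(1, 1), tolerance = 1e-6)
})

test_that("keepX = 1 finds the single informative variable", {
  withr::with_seed(9, {
    for (case in 1:5) {
      n <- 40
      y <- rep(c("A", "B"), each = n / 2)
      X <- matrix(stats::rnorm(n * 50), n, 50)
      X[y == "B", 17] <- X[y == "B", 17] + 4
      m <- splsda_fit(X, y, n_components = 1, keepX = 1)
      expect_equal(which(m$W[, 1] != 0), 17, ignore_attr = TRUE)
    }
  })
})

test_that("prediction is exact on separable training data and equivariant", {
  d <- make_separable(seed = 4)
  m <- splsda_fit(d$X, d$y, n_components = 2, keepX = c(5, 5))
  pr <- splsda_predict(m, d$X)
  expect_equal(pr$labels, d$y)

  # the training sample nearest a centroid keeps that class
  bsample <- d$X[d$y == "B", , drop = FALSE][1, , drop = FALSE]
  expect_equal(splsda_predict(m, bsample)$labels, "B")

  # permuting named variables leaves predictions unchanged
  perm <- rev(seq_len(ncol(d$X)))
  expect_equal(splsda_predict(m, d$X[, perm])$labels, pr$labels)
})

test_that("tuning finds zero error on separable data, deterministically", {
  # wide-margin construction: class means 3 SD apart on two variables
  withr::with_seed(6, {
    y <- rep(c("A", "B", "C"), each = 6)
    X <- matrix(stats::rnorm(18 * 12, sd = 0.1), 18, 12)
    X[y == "B", 1] <- X[y == "B", 1] + 3
    X[y == "C", 2] <- X[y == "C", 2] + 3
  })
  d <- list(X = X, y = y)
  # unit-variance scaling would boost the pure-noise columns to signal
  # magnitude in this construction, so the raw-scale model is the separable one
  tr <- tune_splsda(d$X, d$y, grid = c(2, 4, 8), ncomp_max = 2,
                    folds = 3, repeats = 5, seed = 21, scale = FALSE)
  expect_equal(min(tr$errors$mean_error), 0)
  expect_equal(tr$error_per_ncomp[tr$chosen_ncomp], 0, ignore_attr = TRUE)
  # ties resolved toward fewer variables and fewer components
  expect_equal(tr$chosen_ncomp, 1L)
  expect_equal(tr$chosen_keepX, 2L)
  tr2 <- tune_splsda(d$X, d$y, grid = c(2, 4, 8), ncomp_max = 2,
                     folds = 3, repeats = 5, seed = 21, scale = FALSE)
  expect_equal(tr, tr2)
  tr3 <- tune_splsda(d$X, d$y, grid = c(2, 4, 8), ncomp_max = 2,
                     folds = 3, repeats = 5, seed = 22)
  expect_false(identical(tr$errors, tr3$errors))
})

test_that("label-permuted tuning error sits at chance for three classes", {
  withr::with_seed(31, {
    d <- make_separable(n_per = 10, p = 20, sep = 0)   # sep 0: pure noise
    y_perm <- sample(d$y)
  })
  tr <- tune_splsda(d$X, y_perm, grid = c(5, 10), ncomp_max = 1,
                    folds = 3, repeats = 30, seed = 7)
  expect_equal(min(tr$errors$mean_error), 2 / 3, tolerance = 0.08)
})

test_that("AUROC equals the concordance oracle, with ties at one half", {
  r <- auroc(cbind(A = c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)),
             c("A", "A", "A", "B", "B", "B"))
  expect_equal(unname(r$auc["A"]), 8 / 9, tolerance = 1e-12)

  expect_equal(unname(auroc(cbind(A = 1:6), rep(c("B", "A"), c(3, 3)))$auc["A"]), 1)
  expect_equal(unname(auroc(cbind(A = rep(1, 6)), rep(c("B", "A"), 3))$auc["A"]), 0.5)

  withr::with_seed(13, {
    for (case in 1:30) {
      n <- sample(4:12, 1)
      y <- c("P", "N", sample(c("P", "N"), n - 2, replace = TRUE))
      s <- sample(seq(0, 1, 0.25), n, replace = TRUE)   # heavy tie structure
      got <- unname(auroc(cbind(P = s), y)$auc["P"])
      expect_equal(got, oracle_concordance_auc(s, y == "P"), tolerance = 1e-12)
    }
  })
})

test_that("AUROC agrees with the pROC reference implementation", {
  withr::with_seed(17, {
    y <- rep(c("pos", "neg"), each = 15)
    s <- stats::rnorm(30, mean = ifelse(y == "pos", 1, 0))
  })
  got <- unname(auroc(cbind(pos = s), y)$auc["pos"])
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("ROC curves rise monotonically from (0,0) to (1,1)", {
  d <- make_separable(seed = 8)
  m <- splsda_fit(d$X, d$y, n_components = 2, keepX = c(5, 5))
  r <- auroc(splsda_predict(m, d$X)$yhat, d$y)
  for (cv in r$curves) {
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
    expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
    expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  }
})

test_that("exported artifacts have the declared shapes and correlations", {
  d <- make_separable(seed = 10)
  m <- splsda_fit(d$X, d$y, n_components = 3, keepX = c(6, 4, 2))
  arts <- export_model_artifacts(m, d$X)
  expect_equal(nrow(arts$scores), nrow(d$X))
  expect_equal(ncol(arts$scores), 2 + 3)
  expect_equal(unname(table(arts$loadings$component)), c(6L, 4L, 2L),
               ignore_attr = TRUE)
  # retained variables correlate with their component more than noise ones
  sel1 <- arts$correlations$variable[arts$correlations$component == 1]
  noise_vars <- setdiff(colnames(d$X), unique(arts$loadings$variable))
  cor_sel <- max(abs(arts$correlations$correlation[arts$correlations$component == 1]))
  cor_noise <- max(abs(stats::cor(d$X[, noise_vars], m$T[, 1])))
  expect_gt(cor_sel, cor_noise)
})

test_that("requesting the published model shape works when p allows it", {
  withr::with_seed(19, {
    y <- rep(c("A", "B", "C"), each = 10)
    X <- matrix(stats::rnorm(30 * 80), 30, 80)
    X[y == "B", 1:5] <- X[y == "B", 1:5] + 1.5
    X[y == "C", 6:10] <- X[y == "C", 6:10] + 1.5
  })
  m <- splsda_fit(X, y, n_components = 3, keepX = c(60, 40, 20))
  expect_equal(m$keepX, c(60L, 40L, 20L))
  expect_equal(colSums(m$W != 0), c(60, 40, 20), ignore_attr = TRUE)
})
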