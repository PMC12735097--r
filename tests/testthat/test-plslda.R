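test_that("an exact rank-one problem is fully explained by one component", {
  set.seed(1)
  t <- rnorm(10)
  t <- t - mean(t)
  p <- rnorm(6)
  X <- tcrossprod(t, p)
  fit <- fit_nipals_pls(X, 2 * t, ncomp = 1)
  expect_equal(fit$r2x_cum[1], 1, tolerance = 1e-10)
  expect_equal(fit$r2y_cum[1], 1, tolerance = 1e-10)
})

test_that("NIPALS agrees with the SVD-based oracle on random matrices", {
  set.seed(99)
  for (i in 1:10) {
    X <- matrix(rnorm(24), 6, 4)
    X <- scale(X, scale = FALSE)
    y <- rep(c(1, -1), 3)
    fit <- fit_nipals_pls(X, y, ncomp = 2)
    orc <- svd_pls_oracle(X, y, ncomp = 2)
    expect_lt(max_abs_diff_signfree(fit$scores, orc$scores), 1e-8)
    expect_lt(max_abs_diff_signfree(fit$weights, orc$weights), 1e-8)
    expect_lt(max_abs_diff_signfree(fit$x_loadings, orc$x_loadings), 1e-8)
  }
})

test_that("scores are orthogonal and cumulative R2 is monotone on every fit", {
  set.seed(12)
  for (i in 1:5) {
    X <- scale(matrix(rnorm(20 * 30), 20, 30), scale = FALSE)
    y <- rep(c(1, -1), each = 10)
    fit <- fit_nipals_pls(X, y, ncomp = 4)
    G <- crossprod(fit$scores)
    off <- abs(G[upper.tri(G)])
    norms <- sqrt(diag(G))
    lim <- 1e-8 * tcrossprod(norms)[upper.tri(G)]
    expect_true(all(off <= lim))
    expect_true(all(diff(fit$r2x_cum) >= -1e-12))
    expect_true(all(diff(fit$r2y_cum) >= -1e-12))
    expect_true(all(fit$r2x_cum >= 0 & fit$r2x_cum <= 1 + 1e-12))
  }
})

test_that("the regression vector reproduces the score-space prediction", {
  sc <- scale_features(default_fm(), "centre")
  fit <- fit_nipals_pls(sc, default_fm()$labels, ncomp = 3)
  yhat_b <- drop(fit$X %*% fit$coefficients)
  yhat_t <- drop(fit$scores %*% fit$y_loadings)
  expect_equal(yhat_b, yhat_t, tolerance = 1e-8)
})

test_that("ncomp limits and degenerate X are rejected", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(fit_nipals_pls(X, c(1, 1, -1, -1), ncomp = 4), "ncomp")
  expect_error(fit_nipals_pls(matrix(1, 4, 3), c(1, 1, -1, -1), 1), "zero variance")
})

test_that("VIP reduces to known values for uniform and single-bin weights", {
  t <- rnorm(12)
  p <- 5
  # all-equal weights: X = t * w' with w = 1/sqrt(p)
  X <- tcrossprod(t, rep(1 / sqrt(p), p))
  fit <- fit_nipals_pls(X, sign(t), ncomp = 1)
  expect_equal(vip(fit), rep(1, p), tolerance = 1e-8)
  # all weight on one bin
  X1 <- cbind(t, matrix(0, 12, p - 1))
  fit1 <- fit_nipals_pls(X1, sign(t), ncomp = 1)
  expect_equal(vip(fit1), c(sqrt(p), rep(0, p - 1)), tolerance = 1e-8)
})

test_that("VIP matches the hand-expanded formula and sums to the bin count", {
  set.seed(31)
  X <- scale(matrix(rnorm(16 * 12), 16, 12), scale = FALSE)
  y <- rep(c(1, -1), 8)
  fit <- fit_nipals_pls(X, y, ncomp = 3)
  v <- vip(fit)
  p <- ncol(X)
  ssy <- fit$ssy_comp
  manual <- vapply(seq_len(p), function(j) {
    sqrt(p * sum(ssy * (fit$weights[j, ] / sqrt(colSums(fit$weights^2)))^2) / sum(ssy))
  }, 1)
  expect_equal(v, manual, tolerance = 1e-10)
  expect_equal(sum(v^2), p, tolerance = 1e-6)
  fm_fit <- fit_nipals_pls(scale_features(default_fm(), "centre"),
                           default_fm()$labels, 3)
  vv <- vip(fm_fit)
  expect_equal(sum(vv^2), ncol(default_fm()$data), tolerance = 1e-6 * ncol(default_fm()$data))
})

test_that("target projection collapses to the component for A = 1 and is antisymmetric", {
  set.seed(5)
  X <- scale(matrix(rnorm(60), 10, 6), scale = FALSE)
  y <- rep(c(1, -1), 5)
  f1 <- fit_nipals_pls(X, y, ncomp = 1)
  tp1 <- tp_loadings(f1)
  expect_equal(abs(cor(tp1, f1$x_loadings[, 1])), 1, tolerance = 1e-10)
  f2 <- fit_nipals_pls(X, y, ncomp = 3)
  expect_equal(tp_loadings(fit_nipals_pls(X, -y, ncomp = 3)), -tp_loadings(f2),
               tolerance = 1e-10)
})

test_that("marker bins dominate the target-projection profile across seeds", {
  hits <- 0L
  for (sd in 1:20) {
    ch <- small_cohort(seed = sd)
    fm <- small_fm(ch)
    sc <- scale_features(fm, "centre")
    fit <- fit_nipals_pls(sc, fm$labels, ncomp = 3)
    mb <- marker_bins(fm, ch$truth$marker_ppm)
    top <- order(abs(tp_loadings(fit)), decreasing = TRUE)[1:40]
    if (all(mb %in% top)) hits <- hits + 1L
  }
  expect_gte(hits, 19)  # >= 95% of runs
})

test_that("the discriminant boundary respects symmetry and separability", {
  set.seed(21)
  Z <- matrix(rnorm(40), 20, 2) + 5
  T <- rbind(Z, -Z)
  labels <- rep(c(1, -1), each = 20)
  bd <- fit_discriminant(T, labels)
  expect_lt(abs(bd$intercept), 1e-8)
  d <- decision_values(bd, T)
  expect_equal(ifelse(d > 0, 1, -1), labels)  # separated: zero training error
  expect_identical(unname(bd$class_map["1"]), "A_lixula")
  expect_length(bd$boundary_lv12, 3)
})

test_that("equal-mean clouds classify at chance over seeds", {
  errs <- vapply(1:20, function(sd) {
    set.seed(sd)
    T <- matrix(rnorm(60), 30, 2)
    labels <- rep(c(1, -1), 15)
    bd <- fit_discriminant(T, labels)
    mean(ifelse(decision_values(bd, T) > 0, 1, -1) != labels)
  }, 1)
  expect_gt(mean(errs), 0.3)
  expect_lt(mean(errs), 0.7)
})

test_that("a singular score covariance is regularized rather than fatal", {
  T <- cbind(c(1, 1, 2, 2), c(2, 2, 4, 4))  # rank-1 covariance
  bd <- fit_discriminant(T, c(1, 1, -1, -1))
  expect_true(all(is.finite(bd$coefficients)))
})

test_that("midrank AUC follows pair counting, tie and symmetry conventions", {
  d <- c(0.9, 0.3, 0.8, 0.4)
  labels <- c(1, 1, -1, -1)
  expect_equal(auc_midrank(d, labels), 0.5)  # 2 of 4 concordant pairs
  expect_equal(auc_midrank(rep(1, 6), rep(c(1, -1), 3)), 0.5)
  set.seed(2)
  s <- rnorm(30); l <- rep(c(1, -1), 15)
  expect_equal(auc_midrank(exp(s), l), auc_midrank(s, l))  # monotone invariance
  expect_equal(auc_midrank(-s, l), 1 - auc_midrank(s, l))
})

test_that("cross-validation is stratified, seeded and guarded", {
  ch <- small_cohort(seed = 2)
  fm <- small_fm(ch)
  cv1 <- cross_validate(fm, ncomp = 2, folds = 3, repeats = 2, seed = 10)
  cv2 <- cross_validate(fm, ncomp = 2, folds = 3, repeats = 2, seed = 10)
  expect_identical(cv1$cv_scores, cv2$cv_scores)
  expect_equal(nrow(cv1$cv_scores), 2 * nrow(fm$data))
  expect_error(cross_validate(fm, folds = 7), "folds")  # > min class size
  expect_equal(cv1$error,
               mean(sign(cv1$cv_scores$decision) != cv1$cv_scores$label))
})

test_that("the permutation test is floored, seeded and calibrated on null data", {
  ch <- small_cohort(seed = 6)
  fm <- small_fm(ch)
  pt <- permutation_test_plslda(fm, ncomp = 2, n_perm = 99, seed = 1)
  expect_equal(pt$p_value, 1 / 100)  # AUC = 1 beats every permutation
  expect_error(permutation_test_plslda(fm, n_perm = 50), "n_perm")
  set.seed(17)
  Xnull <- matrix(rnorm(16 * 40), 16, 40)
  ynull <- rep(c(1, -1), 8)
  pn <- permutation_test_plslda(Xnull, ynull, ncomp = 2, n_perm = 99, seed = 3)
  expect_gt(pn$p_value, 0.01)
})

test_that("confidence ellipses use the chi-squared scale and rotate equivariantly", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  iso <- cbind(cos(th), sin(th))  # exactly isotropic
  e <- confidence_ellipse(iso, 0.95)
  expect_equal(e$radii[1] / e$radii[2], 1, tolerance = 1e-6)
  q_oracle <- uniroot(function(x) pchisq(x, df = 2) - 0.95, c(0.1, 50),
                      tol = 1e-12)$root
  aniso <- cbind(3 * cos(th), sin(th))
  ea <- confidence_ellipse(aniso, 0.95)
  expect_equal(ea$radii^2 / eigen(cov(aniso))$values, rep(q_oracle, 2),
               tolerance = 1e-8)
  phi <- pi / 6
  Rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  er <- confidence_ellipse(aniso %*% t(Rot), 0.95)
  ang <- (er$angle - ea$angle) %% pi
  expect_equal(min(ang, pi - ang), phi, tolerance = 1e-8)
  expect_error(confidence_ellipse(cbind(1:5, 2 * (1:5))), "degenerate")
})

test_that("LDA boundary agrees with an established reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(44)
  T <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  labels <- rep(c(1, -1), each = 20)
  bd <- fit_discriminant(T, labels)
  ref <- MASS::lda(T, grouping = factor(labels))
  pred <- predict(ref, T)$class
  expect_equal(ifelse(decision_values(bd, T) > 0, 1, -1),
               as.numeric(as.character(pred)))
})

test_that("midrank AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(13)
  d <- rnorm(40); l <- rep(c(1, -1), 20)
  ref <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = d,
                                        levels = c(-1, 1), direction = "<",
                                        quiet = TRUE)))
  expect_equal(auc_midrank(d, l), ref, tolerance = 1e-12)
})
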