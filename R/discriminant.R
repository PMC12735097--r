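#' Linear discriminant boundary in PLS score space
#'
#' Fits a two-class LDA with pooled covariance to the latent-variable
#' scores: decision value `d(t) = c't + c0`, boundary `d = 0`, and
#' `sign(d) = +1` assigns *A. lixula* (the +1 class). The intercept uses
#' log-proportion priors, so with balanced classes and centred symmetric
#' clouds the boundary passes through the origin. A singular pooled
#' covariance is ridge-regularized by `1e-8 * trace / A` on the diagonal.
#' When `A >= 2`, `boundary_lv12` holds the analogous `c(c1, c2, c0)` fit
#' in the LV1/LV2 plane for score-plot drawing.
#'
#' @param T Scores matrix (samples x A).
#' @param labels Numeric +1/-1 vector; both classes present.
#' @return A `discriminant_boundary`: `coefficients`, `intercept`,
#'   `class_map`, `boundary_lv12`.
#' @export
fit_discriminant <- function(T, labels) {
  T <- as.matrix(T)
  stopifnot(nrow(T) == length(labels), all(labels %in% c(-1, 1)),
            length(unique(labels)) == 2)
  fit <- lda_pooled(T, labels)
  b12 <- if (ncol(T) >= 2) {
    f <- lda_pooled(T[, 1:2, drop = FALSE], labels)
    c(c1 = f$coefficients[1], c2 = f$coefficients[2], c0 = f$intercept)
  } else NULL
  structure(list(coefficients = fit$coefficients, intercept = fit$intercept,
                 class_map = c(`1` = "A_lixula", `-1` = "P_lividus"),
                 boundary_lv12 = b12),
            class = "discriminant_boundary")
}

lda_pooled <- function(T, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  m1 <- colMeans(T[pos, , drop = FALSE])
  m0 <- colMeans(T[!pos, , drop = FALSE])
  c1 <- sweep(T[pos, , drop = FALSE], 2, m1)
  c0 <- sweep(T[!pos, , drop = FALSE], 2, m0)
  S <- (crossprod(c1) + crossprod(c0)) / max(n1 + n0 - 2, 1)
  cf <- tryCatch(solve(S, m1 - m0), error = function(e) {
    lambda <- 1e-8 * sum(diag(S)) / ncol(T) + 1e-300
    solve(S + diag(lambda, ncol(T)), m1 - m0)
  })
  list(coefficients = drop(cf),
       intercept = -sum(cf * (m1 + m0)) / 2 + log(n1 / n0))
}

#' Decision values of a discriminant boundary
#'
#' @param boundary A `discriminant_boundary`.
#' @param T Scores matrix.
#' @return Numeric decision values; positive values assign the +1 class.
#' @export
decision_values <- function(boundary, T) {
  drop(as.matrix(T) %*% boundary$coefficients + boundary$intercept)
}

#' Area under the ROC curve (midrank convention)
#'
#' Rank-based (Mann-Whitney) AUC with midranks for ties, so constant
#' scores give 0.5 and `auc(-d) = 1 - auc(d)`.
#'
#' @param d Decision values.
#' @param labels +1/-1 truth.
#' @return AUC in \[0, 1\].
#' @export
auc_midrank <- function(d, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(d)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

classification_metrics <- function(d, labels) {
  pred <- ifelse(d > 0, 1, -1)
  pos <- labels > 0
  list(error = mean(pred != labels),
       sensitivity = mean(pred[pos] == 1),
       specificity = mean(pred[!pos] == -1),
       auc = auc_midrank(d, labels))
}

stratified_folds <- function(labels, folds) {
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

#' Cross-validated PLS-LDA performance
#'
#' Stratified k-fold cross-validation, repeated; pretreatment parameters
#' are re-estimated inside every training fold. Held-out decision values
#' are pooled across folds and repeats, then summarized as
#' misclassification error, per-class sensitivity/specificity (against the
#' +1/-1 map, +1 = *A. lixula*), and midrank AUC.
#'
#' @param X Raw feature matrix (`feature_matrix` or samples x bins matrix);
#'   not pretreated.
#' @param y +1/-1 labels (taken from `X` if a `feature_matrix`).
#' @param ncomp Latent variables (default 3).
#' @param folds Folds (default 5); every training fold must keep both
#'   classes, so `folds <= min(class size)`.
#' @param repeats Repetitions with reshuffled folds (default 20).
#' @param scale_method Pretreatment re-estimated per fold
#'   (default `"centre"`).
#' @param seed Seed for fold assignment.
#' @return A `cv_metrics`: `error`, `sensitivity`, `specificity`, `auc`,
#'   `cv_scores` (data frame of pooled held-out decision values), `folds`,
#'   `repeats`, `seed`.
#' @export
cross_validate <- function(X, y = NULL, ncomp = 3, folds = 5, repeats = 20,
                           scale_method = "centre", seed = 1) {
  if (inherits(X, "feature_matrix")) {
    y <- y %||% X$labels
    X <- X$data
  }
  stopifnot(folds >= 2, length(y) == nrow(X),
            folds <= min(table(y)))
  out <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    set.seed(derive_seed(seed, rep_i))
    fold_id <- stratified_folds(y, folds)
    d <- numeric(length(y))
    for (k in seq_len(folds)) {
      te <- fold_id == k
      sc <- scale_features(X[!te, , drop = FALSE], scale_method)
      a <- min(ncomp, sum(!te) - 1, ncol(X))
      fit <- fit_nipals_pls(sc$data, y[!te], ncomp = a)
      bd <- fit_discriminant(fit$scores, y[!te])
      Tte <- project_scores(fit, apply_scaling(sc, X[te, , drop = FALSE]))
      d[te] <- decision_values(bd, Tte)
    }
    out[[rep_i]] <- data.frame(sample = seq_along(y), repeat_id = rep_i,
                               decision = d, label = y)
  }
  pooled <- do.call(rbind, out)
  m <- classification_metrics(pooled$decision, pooled$label)
  structure(c(m, list(cv_scores = pooled, folds = folds, repeats = repeats,
                      seed = seed)),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("<cv_metrics> error = %.3f, sensitivity = %.2f, specificity = %.2f, AUC = %.3f (%d-fold x %d)\n",
              x$error, x$sensitivity, x$specificity, x$auc, x$folds, x$repeats))
  invisible(x)
}

#' Permutation test of the cross-validated AUC
#'
#' Repeats cross-validation with permuted class labels and reports the
#' add-one permutation p-value
#' `p = (1 + #\{AUC_perm >= AUC_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams cross_validate
#' @param n_perm Number of permutations (>= 99).
#' @param repeats Cross-validation repeats used for the observed and each
#'   permuted model (default 1 to keep the null distribution affordable).
#' @return List with `p_value`, `observed_auc`, `permuted_auc`.
#' @export
permutation_test_plslda <- function(X, y = NULL, ncomp = 3, n_perm = 199,
                                    folds = 5, repeats = 1, seed = 1) {
  if (inherits(X, "feature_matrix")) {
    y <- y %||% X$labels
    X <- X$data
  }
  stopifnot(n_perm >= 99)
  obs <- cross_validate(X, y, ncomp, folds, repeats, seed = derive_seed(seed, 0))$auc
  perm <- vapply(seq_len(n_perm), function(k) {
    set.seed(derive_seed(seed, 2 * k))
    yp <- sample(y)
    cross_validate(X, yp, ncomp, folds, repeats,
                   seed = derive_seed(seed, 2 * k + 1))$auc
  }, 1)
  list(p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       observed_auc = obs, permuted_auc = perm)
}

#' Gaussian confidence ellipse for a score cluster
#'
#' Ellipse of the bivariate normal fitted to two score columns, scaled by
#' the chi-squared quantile with 2 degrees of freedom so the contour
#' encloses the requested probability mass.
#'
#' @param T2 Two-column score matrix (>= 3 samples).
#' @param level Coverage level (default 0.95).
#' @return List with `center`, `radii` (semi-axes, decreasing), `angle`
#'   (radians, orientation of the major axis), `vectors` (principal axes).
#' @export
confidence_ellipse <- function(T2, level = 0.95) {
  T2 <- as.matrix(T2)
  stopifnot(ncol(T2) == 2, nrow(T2) >= 3, level > 0, level < 1)
  S <- cov(T2)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 0) stop("degenerate score covariance")
  scale2 <- qchisq(level, df = 2)
  list(center = colMeans(T2),
       radii = sqrt(e$values * scale2),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       vectors = e$vectors)
}
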