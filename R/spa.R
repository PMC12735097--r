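#' Configuration for Subwindow Permutation Analysis
#'
#' Defaults follow the published settings: N = 1000 Monte-Carlo sub-models,
#' Q = 15 variables per sub-model, K = 3 internal cross-validation folds,
#' calibration fraction 0.7, Pareto scaling, and a COSS significance
#' threshold of 2 (p < 0.01). `max_lv` bounds the per-sub-model latent
#' variable search (components beyond a handful overfit calibration sets of
#' this size).
#'
#' @param N Monte-Carlo iterations (>= 100).
#' @param Q Variables sampled per sub-model.
#' @param K Internal cross-validation folds.
#' @param ratio Calibration fraction (0 < ratio < 1).
#' @param scaling Pretreatment for sub-models (default `"pareto"`).
#' @param coss_threshold Selection threshold on COSS (default 2).
#' @param max_lv Upper bound on latent variables searched per sub-model.
#' @param n_perm_rep Independent permutations of each variable per
#'   sub-model; replicates average out single-permutation luck in the
#'   permuted-error sample.
#' @param seed Integer seed.
#' @return An `spa_config` list.
#' @export
spa_config <- function(N = 1000, Q = 15, K = 3, ratio = 0.7,
                       scaling = "pareto", coss_threshold = 2,
                       max_lv = 5, n_perm_rep = 5, seed = 1) {
  stopifnot(N >= 100, Q >= 2, K >= 2, ratio > 0, ratio < 1, max_lv >= 1,
            n_perm_rep >= 1)
  structure(list(N = as.integer(N), Q = as.integer(Q), K = as.integer(K),
                 ratio = ratio, scaling = scaling,
                 coss_threshold = coss_threshold,
                 max_lv = as.integer(max_lv),
                 n_perm_rep = as.integer(n_perm_rep),
                 seed = as.integer(seed)),
            class = "spa_config")
}

#' Conditional Synergistic Score
#'
#' `COSS = -log10(p)`; with `n_iter` supplied, `p` is floored at
#' `1 / (n_iter + 1)` (the resolution of an N-iteration Monte-Carlo run),
#' keeping the score finite. `COSS > 2` corresponds to `p < 0.01`.
#'
#' @param p Permutation p-value(s) in (0, 1].
#' @param n_iter Optional Monte-Carlo iteration count for the floor.
#' @return COSS value(s) >= 0.
#' @export
#' @examples
#' coss_score(0.01)          # 2
#' coss_score(0, n_iter = 1000)  # -log10(1/1001)
coss_score <- function(p, n_iter = NULL) {
  if (!is.null(n_iter)) p <- pmax(p, 1 / (n_iter + 1))
  p <- pmin(p, 1)
  -log10(p)
}

#' One-sided rank-sum p-value (permuted errors greater than normal errors)
#'
#' Mann-Whitney test of the alternative that `permuted` values are
#' stochastically greater than `normal` values. Exact by full enumeration
#' of all assignments when both samples have at most 8 observations
#' (midranks for ties); otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param normal Numeric sample of normal prediction errors.
#' @param permuted Numeric sample of permuted prediction errors.
#' @return p-value in (0, 1].
#' @export
rank_sum_p <- function(normal, permuted) {
  stopifnot(length(normal) >= 1, length(permuted) >= 1)
  n1 <- length(permuted); n2 <- length(normal)
  comb <- c(permuted, normal)
  rk <- rank(comb)
  U_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8 && n2 <= 8) {
    sets <- combn(n1 + n2, n1)
    U_all <- colSums(matrix(rk[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    return(mean(U_all >= U_obs - 1e-9))
  }
  n <- n1 + n2
  ties <- table(comb)
  mu <- n1 * n2 / 2
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(if (U_obs > mu) 0.5 else 1)
  z <- (U_obs - mu - 0.5) / sqrt(v)
  min(1, pnorm(z, lower.tail = FALSE))
}

# Choose the number of latent variables for one sub-model by K-fold CV on
# the calibration block; smallest A on ties.
choose_ncomp_cv <- function(Xc, yc, K, a_max, scaling) {
  fold_id <- stratified_folds(yc, K)
  err <- numeric(a_max)
  cnt <- 0L
  for (k in seq_len(K)) {
    te <- fold_id == k
    if (length(unique(yc[!te])) < 2 || !any(te)) next
    sc <- scale_features(Xc[!te, , drop = FALSE], scaling)
    a_k <- min(a_max, sum(!te) - 1)
    fit <- fit_nipals_pls(sc$data, yc[!te], ncomp = a_k)
    Tte <- project_scores(fit, apply_scaling(sc, Xc[te, , drop = FALSE]))
    for (a in seq_len(a_max)) {
      aa <- min(a, a_k)
      bd <- fit_discriminant(fit$scores[, seq_len(aa), drop = FALSE], yc[!te])
      d <- decision_values(bd, Tte[, seq_len(aa), drop = FALSE])
      err[a] <- err[a] + sum(ifelse(d > 0, 1, -1) != yc[te])
    }
    cnt <- cnt + sum(te)
  }
  which.min(err)  # ties resolve to the smallest A
}

#' Subwindow Permutation Analysis
#'
#' Builds `N` Monte-Carlo PLS-LDA sub-models on random stratified
#' calibration subsets (`ratio` of the samples) and random subsets of `Q`
#' variables. Each sub-model's latent-variable count is optimized by
#' internal K-fold cross-validation; the test-block misclassification rate
#' is the *normal* prediction error, recorded for every variable in the
#' sub-model. Each variable is then permuted across the test block (the
#' trained sub-model stays fixed) to give its *permuted* error. Per
#' variable, `DMEAN` and `DSD` are the differences of the means and SDs of
#' the permuted vs normal error distributions, `p` is the one-sided
#' rank-sum probability that permuted errors exceed normal errors (floored
#' at `1/(N+1)`), and `COSS = -log10(p)`.
#'
#' Variables never drawn into any sub-model are reported with `p = 1`,
#' `COSS = 0` and flagged in `never_sampled`.
#'
#' @param fm A `feature_matrix` (typically total-area normalized and,
#'   for wide matrices, screened with [filter_bins()] so each variable is
#'   drawn often enough for the rank test to resolve small p-values).
#' @param config An [spa_config()].
#' @return An `spa_result` with a per-bin data frame `table`
#'   (`bin`, `ppm`, `n_normal`, `n_permuted`, `dmean`, `dsd`, `p`, `coss`,
#'   `selected`, `never_sampled`) plus `config`.
#' @export
run_spa <- function(fm, config = spa_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "spa_config"))
  X <- fm$data; y <- fm$labels
  n <- nrow(X); p <- ncol(X)
  if (config$Q > p) stop("Q exceeds the number of bins")
  n_cal <- ceiling(config$ratio * n)
  if (n - n_cal < 2) stop("calibration ratio leaves fewer than 2 test samples")

  R <- config$n_perm_rep
  it_vars <- matrix(0L, config$N, config$Q)
  it_err <- numeric(config$N)
  perm_err <- array(NA_real_, c(config$N, config$Q, R))

  idx_pos <- which(y > 0); idx_neg <- which(y < 0)
  n_cal_pos <- ceiling(config$ratio * length(idx_pos))
  n_cal_neg <- n_cal - n_cal_pos
  n_cal_neg <- max(1, min(n_cal_neg, length(idx_neg) - 1))

  for (it in seq_len(config$N)) {
    set.seed(derive_seed(config$seed, it))
    vars <- sample.int(p, config$Q)
    cal <- c(sample(idx_pos, n_cal_pos), sample(idx_neg, n_cal_neg))
    te <- setdiff(seq_len(n), cal)
    Xc <- X[cal, vars, drop = FALSE]; yc <- y[cal]
    a_max <- max(1, min(config$Q, length(cal) - config$K, config$max_lv))
    a_opt <- choose_ncomp_cv(Xc, yc, config$K, a_max, config$scaling)
    sc <- scale_features(Xc, config$scaling)
    fit <- fit_nipals_pls(sc$data, yc, ncomp = min(a_opt, length(cal) - 1))
    bd <- fit_discriminant(fit$scores, yc)
    Zte <- apply_scaling(sc, X[te, vars, drop = FALSE])
    Tte <- Zte %*% fit$projection
    d <- decision_values(bd, Tte)
    it_err[it] <- mean(ifelse(d > 0, 1, -1) != y[te])
    it_vars[it, ] <- vars
    # permute one scaled column at a time; scores shift by the column delta
    # times the corresponding projection row
    for (qi in seq_len(config$Q)) {
      for (rr in seq_len(R)) {
        delta <- sample(Zte[, qi]) - Zte[, qi]
        dq <- decision_values(bd, Tte + outer(delta, fit$projection[qi, ]))
        perm_err[it, qi, rr] <- mean(ifelse(dq > 0, 1, -1) != y[te])
      }
    }
  }

  flat_vars <- as.vector(it_vars)
  flat_norm <- rep(it_err, times = config$Q)
  norm_by_var <- split(flat_norm, factor(flat_vars, levels = seq_len(p)))
  perm_by_var <- split(as.vector(perm_err),
                       factor(rep(flat_vars, times = R), levels = seq_len(p)))

  res <- data.frame(bin = seq_len(p), ppm = fm$ppm_mid,
                    n_normal = lengths(norm_by_var),
                    n_permuted = lengths(perm_by_var),
                    dmean = NA_real_, dsd = NA_real_,
                    p = 1, coss = 0, never_sampled = lengths(norm_by_var) == 0)
  for (j in seq_len(p)) {
    nj <- norm_by_var[[j]]; pj <- perm_by_var[[j]]
    if (length(nj) == 0) next
    res$dmean[j] <- mean(pj) - mean(nj)
    res$dsd[j] <- (if (length(pj) > 1) sd(pj) else 0) -
      (if (length(nj) > 1) sd(nj) else 0)
    res$p[j] <- max(rank_sum_p(nj, pj), 1 / (config$N + 1))
    res$coss[j] <- coss_score(res$p[j])
  }
  res$selected <- res$coss > config$coss_threshold
  structure(list(table = res, config = config), class = "spa_result")
}

#' @export
print.spa_result <- function(x, ...) {
  cat(sprintf("<spa_result> %d bins, %d selected at COSS > %g (N = %d)\n",
              nrow(x$table), sum(x$table$selected), x$config$coss_threshold,
              x$config$N))
  invisible(x)
}

#' Select variables by COSS threshold
#'
#' @param res An `spa_result`.
#' @param threshold COSS cut-off; strictly greater-than (so p = 0.01 at
#'   threshold 2 is excluded).
#' @return Integer bin indices sorted by decreasing COSS.
#' @export
select_variables <- function(res, threshold = res$config$coss_threshold) {
  tab <- res$table
  idx <- tab$bin[tab$coss > threshold]
  idx[order(tab$coss[match(idx, tab$bin)], decreasing = TRUE)]
}
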