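#' NIPALS partial least squares regression on class labels
#'
#' Fits a PLS1 model by the NIPALS procedure: for each component, the weight
#' vector is `w = X'y / ||X'y||`, scores `t = X w`, x-loadings
#' `p = X't / t't`, y-loading `r = y't / t't`, after which `X` is deflated
#' by `t p'` and `y` by `t r`. `y` is centred internally (class labels are
#' +1/-1). Cumulative explained variances are
#' `R2X = 1 - ||X_res||^2 / ||X_0||^2` and analogously `R2Y`.
#'
#' @param X A `scaled_matrix` from [scale_features()] or a pretreated
#'   numeric matrix (samples x bins).
#' @param y Numeric +1/-1 class vector (two values required).
#' @param ncomp Number of latent variables `A`
#'   (`A <= min(samples - 1, bins)`).
#' @return A `pls_model`: `ncomp`, `weights` (W, columns unit norm),
#'   `scores` (T), `x_loadings` (P), `y_loadings` (r), `y_scores` (U,
#'   columns are the deflated y entering each component), `q` (y-loading
#'   scalar, 1 for PLS1), `projection` (`R = W (P'W)^{-1}`, so new scores
#'   are `X_new R`), `coefficients` (`b = R r`), `r2x_cum`, `r2y_cum`,
#'   `ss_t` (score sums of squares), `ssy_comp` (y-variance explained per
#'   component, used by [vip()]), `X` (the pretreated training matrix),
#'   `y_mean`, `pretreatment` (method/means/scales when a `scaled_matrix`
#'   was supplied).
#' @export
#' @examples
#' X <- scale_features(matrix(rnorm(40), 8, 5), "centre")
#' y <- rep(c(1, -1), each = 4)
#' fit <- fit_nipals_pls(X, y, ncomp = 2)
#' round(fit$r2y_cum, 3)
fit_nipals_pls <- function(X, y, ncomp = 3) {
  pre <- NULL
  if (inherits(X, "scaled_matrix")) {
    pre <- X[c("column_means", "column_scales", "method")]
    X <- X$data
  }
  stopifnot(is.matrix(X), nrow(X) == length(y), length(unique(y)) >= 2)
  n <- nrow(X); p <- ncol(X)
  if (ncomp > min(n - 1, p)) stop("ncomp exceeds min(samples - 1, bins)")
  if (all(abs(X - mean(X)) < .Machine$double.eps * 100)) stop("X has zero variance")
  y_mean <- mean(y)
  yr <- y - y_mean
  Xr <- X
  ssx0 <- sum(X^2)
  ssy0 <- sum(yr^2)
  W <- P <- matrix(0, p, ncomp)
  T <- U <- matrix(0, n, ncomp)
  r <- ss_t <- ssy_comp <- r2x <- r2y <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    wv <- drop(crossprod(Xr, yr))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-14) stop("X'y vanished at component ", a, "; reduce ncomp")
    wv <- wv / nw
    tv <- drop(Xr %*% wv)
    tt <- sum(tv^2)
    pv <- drop(crossprod(Xr, tv)) / tt
    rv <- sum(yr * tv) / tt
    U[, a] <- yr
    Xr <- Xr - tcrossprod(tv, pv)
    yr <- yr - tv * rv
    W[, a] <- wv; T[, a] <- tv; P[, a] <- pv; r[a] <- rv
    ss_t[a] <- tt
    ssy_comp[a] <- rv^2 * tt
    r2x[a] <- 1 - sum(Xr^2) / ssx0
    r2y[a] <- 1 - sum(yr^2) / ssy0
  }
  R <- W %*% solve(crossprod(P, W))
  structure(list(ncomp = ncomp, weights = W, scores = T, x_loadings = P,
                 y_loadings = r, y_scores = U, q = 1,
                 projection = R, coefficients = drop(R %*% r),
                 r2x_cum = r2x, r2y_cum = r2y,
                 ss_t = ss_t, ssy_comp = ssy_comp,
                 X = X, y = y, y_mean = y_mean, pretreatment = pre),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> A = %d, R2X = %.3f, R2Y = %.3f\n",
              x$ncomp, x$r2x_cum[x$ncomp], x$r2y_cum[x$ncomp]))
  invisible(x)
}

#' Project new samples into latent-variable space
#'
#' @param model A `pls_model`.
#' @param newdata Pretreated matrix with the training columns.
#' @return Scores matrix (samples x A).
#' @export
project_scores <- function(model, newdata) {
  stopifnot(inherits(model, "pls_model"))
  newdata %*% model$projection
}

#' Variable Importance in Projection
#'
#' Standard Wold VIP:
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with unit-norm
#' weight columns, where `SSY_a` is the y-variance explained by component
#' `a`. Satisfies `sum_j VIP_j^2 = p`.
#'
#' @param model A `pls_model`.
#' @return Per-bin VIP vector.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  p <- nrow(model$weights)
  w2 <- model$weights^2
  drop(sqrt(p * (w2 %*% model$ssy_comp) / sum(model$ssy_comp)))
}

#' Target-projection loadings
#'
#' Projects the pretreated data onto the normalized PLS regression vector:
#' `t_tp = X b / ||b||`, `tpLoading = X' t_tp / (t_tp' t_tp)`. The single
#' predictive direction concentrates the covariance between the spectral
#' variables and the class contrast, so discriminant bins carry the largest
#' absolute loadings.
#'
#' @param model A `pls_model`.
#' @return Per-bin target-projection loading vector.
#' @export
tp_loadings <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  b <- model$coefficients
  nb <- sqrt(sum(b^2))
  if (nb < 1e-14) stop("zero regression vector")
  t_tp <- drop(model$X %*% (b / nb))
  drop(crossprod(model$X, t_tp)) / sum(t_tp^2)
}
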