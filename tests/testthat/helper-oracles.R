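# Independent oracles, deliberately coded apart from the package internals.

# PLS1 via SVD of the cross-covariance at every step (the dominant singular
# vector of X'y is the component weight); deflation as in standard PLS.
svd_pls_oracle <- function(X, y, ncomp) {
  y <- y - mean(y)
  Xr <- X; yr <- y
  W <- P <- matrix(0, ncol(X), ncomp)
  T <- matrix(0, nrow(X), ncomp)
  r <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    s <- svd(crossprod(Xr, cbind(yr)))
    w <- s$u[, 1]
    t <- drop(Xr %*% w)
    p <- drop(crossprod(Xr, t)) / sum(t^2)
    r[a] <- sum(yr * t) / sum(t^2)
    Xr <- Xr - tcrossprod(t, p)
    yr <- yr - t * r[a]
    W[, a] <- w; T[, a] <- t; P[, a] <- p
  }
  list(weights = W, scores = T, x_loadings = P, y_loadings = r)
}

# Agreement up to per-column sign.
max_abs_diff_signfree <- function(A, B) {
  max(vapply(seq_len(ncol(A)), function(j) {
    min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
  }, 1))
}

# Upper hypergeometric tail P(X >= k) by exhaustive enumeration of all
# n-subsets of a universe of size N whose first m elements are the pathway.
hyper_tail_enum <- function(N, m, n, k) {
  sets <- combn(N, n)
  mean(colSums(sets <= m) >= k)
}

# One-sided Mann-Whitney p by enumeration, with the U statistic computed by
# direct pair counting (not ranks).
ranksum_enum <- function(normal, permuted) {
  comb <- c(permuted, normal)
  n1 <- length(permuted)
  u_stat <- function(idx) {
    a <- comb[idx]; b <- comb[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U_obs <- u_stat(seq_len(n1))
  sets <- combn(length(comb), n1)
  U_all <- apply(sets, 2, u_stat)
  mean(U_all >= U_obs - 1e-9)
}

# Tie-corrected normal approximation with continuity correction (the
# package's large-sample branch, recomputed independently).
ranksum_normal_approx <- function(normal, permuted) {
  n1 <- length(permuted); n2 <- length(normal); n <- n1 + n2
  comb <- c(permuted, normal)
  U <- sum(outer(permuted, normal, ">")) + 0.5 * sum(outer(permuted, normal, "=="))
  ties <- table(comb)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(if (U > n1 * n2 / 2) 0.5 else 1)
  min(1, pnorm((U - n1 * n2 / 2 - 0.5) / sqrt(v), lower.tail = FALSE))
}

# Mass of a Lorentzian line of unit area between lo and hi ppm.
lorentz_mass <- function(center, fwhm, lo, hi) {
  g <- fwhm / 2
  (atan((hi - center) / g) - atan((lo - center) / g)) / pi
}
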