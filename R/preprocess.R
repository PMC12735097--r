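#' Default excluded ppm regions
#'
#' Residual water (4.7-5.0 ppm) and the TSP reference region
#' (-0.05-0.05 ppm).
#'
#' @return A list of `c(lo, hi)` ppm intervals.
#' @export
default_exclusions <- function() list(water = c(4.7, 5.0), tsp = c(-0.05, 0.05))

# Interpolated cumulative trapezoidal integral evaluated at arbitrary ppm
# positions: F(x) = integral from x down to min(ppm).
cumulative_integral <- function(spectrum) {
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  n <- length(ppm)
  seg <- (y[-n] + y[-1]) / 2 * (ppm[-n] - ppm[-1])
  cum_top <- c(0, cumsum(seg))  # integral from max(ppm) down to each point
  total <- cum_top[n]
  xs <- rev(ppm)
  fs <- rev(total - cum_top)    # integral from each point down to min(ppm)
  function(x) approx(xs, fs, xout = x, rule = 2)$y
}

#' Bin spectra into a feature matrix
#'
#' Divides the shared ppm axis into uniform half-open `[hi, lo)` buckets of
#' `bin_width_ppm`, descending from the axis maximum. Each bin value is the
#' trapezoidal integral of the intensity over the bin (cumulative-integral
#' formulation, so binning is linear in the spectra and exact for piecewise
#' linear signals). Bins intersecting an exclusion interval are dropped.
#'
#' @param spectra List of `spectrum` objects sharing one axis.
#' @param labels Numeric +1/-1 class vector (or a character vector of
#'   species names, `"A_lixula"` mapping to +1).
#' @param bin_width_ppm Bucket width in ppm (default 0.01).
#' @param exclusions List of `c(lo, hi)` ppm intervals to drop.
#' @param sample_ids Optional sample identifiers.
#' @return A `feature_matrix`: `data` (samples x bins), `labels`,
#'   `bin_edges` data frame (`hi`, `lo`), `ppm_mid`, `sample_ids`.
#' @export
bin_spectra <- function(spectra, labels, bin_width_ppm = 0.01,
                        exclusions = default_exclusions(),
                        sample_ids = NULL) {
  stopifnot(length(spectra) >= 1, length(labels) == length(spectra))
  if (is.character(labels)) labels <- ifelse(labels == "A_lixula", 1, -1)
  ppm <- spectra[[1]]$ppm
  for (s in spectra) {
    if (!isTRUE(all.equal(s$ppm, ppm))) stop("spectra must share one ppm axis")
  }
  if (bin_width_ppm <= max(abs(diff(ppm)))) {
    stop("bin width must exceed the axis resolution")
  }
  hi <- seq(max(ppm), min(ppm) + bin_width_ppm, by = -bin_width_ppm)
  lo <- hi - bin_width_ppm
  keep <- rep(TRUE, length(hi))
  for (ex in exclusions) {
    keep <- keep & !(hi > min(ex) & lo < max(ex))
  }
  if (!any(keep)) stop("no bins remain after exclusions")
  hi <- hi[keep]; lo <- lo[keep]
  data <- matrix(NA_real_, nrow = length(spectra), ncol = length(hi))
  for (i in seq_along(spectra)) {
    F <- cumulative_integral(spectra[[i]])
    data[i, ] <- F(hi) - F(lo)
  }
  colnames(data) <- sprintf("ppm_%.3f", (hi + lo) / 2)
  new_feature_matrix(data, labels,
                     bin_edges = data.frame(hi = hi, lo = lo),
                     sample_ids = sample_ids %||% sprintf("S%02d", seq_along(spectra)))
}

#' Construct a feature matrix
#' @param data Samples x bins numeric matrix without missing values.
#' @param labels Numeric +1/-1 vector with both values present.
#' @param bin_edges Data frame with `hi`, `lo` columns (descending,
#'   non-overlapping).
#' @param sample_ids Character sample identifiers.
#' @return A `feature_matrix` object.
#' @export
new_feature_matrix <- function(data, labels, bin_edges, sample_ids = NULL) {
  stopifnot(is.matrix(data), !anyNA(data), nrow(data) == length(labels),
            all(labels %in% c(-1, 1)), length(unique(labels)) == 2,
            nrow(bin_edges) == ncol(data), all(bin_edges$hi > bin_edges$lo),
            !is.unsorted(rev(bin_edges$hi)))
  structure(list(data = data, labels = labels, bin_edges = bin_edges,
                 ppm_mid = (bin_edges$hi + bin_edges$lo) / 2,
                 sample_ids = sample_ids %||% sprintf("S%02d", seq_len(nrow(data)))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d bins (%.3f-%.3f ppm), classes +1: %d / -1: %d\n",
              nrow(x$data), ncol(x$data), max(x$bin_edges$hi), min(x$bin_edges$lo),
              sum(x$labels == 1), sum(x$labels == -1)))
  invisible(x)
}

#' Total-area normalization
#'
#' Scales each sample (row) to unit total integral, removing overall
#' intensity differences between spectra.
#'
#' @param fm A `feature_matrix`.
#' @return The normalized `feature_matrix`.
#' @export
normalize_total_area <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  totals <- rowSums(fm$data)
  if (any(totals <= 0)) stop("every sample must have a positive total area")
  fm$data <- fm$data / totals
  fm
}

#' Column pretreatment: centring and scaling
#'
#' `"centre"` subtracts the column mean; `"pareto"` additionally divides by
#' the square root of the column SD; `"auto"` divides by the SD; `"none"`
#' leaves data unchanged. Columns with zero SD get scale 1 and are flagged.
#'
#' @param x Numeric matrix or `feature_matrix` (>= 2 samples).
#' @param method One of `"centre"`, `"pareto"`, `"auto"`, `"none"`.
#' @return A `scaled_matrix`: `data`, `column_means`, `column_scales`,
#'   `method`, `zero_variance` (logical flags).
#' @export
scale_features <- function(x, method = c("centre", "pareto", "auto", "none")) {
  method <- match.arg(method)
  if (inherits(x, "feature_matrix")) x <- x$data
  stopifnot(is.matrix(x), nrow(x) >= 2)
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  zero <- sds == 0
  scl <- switch(method,
                centre = rep(1, ncol(x)),
                pareto = sqrt(ifelse(zero, 1, sds)),
                auto = ifelse(zero, 1, sds),
                none = rep(1, ncol(x)))
  if (method == "none") mu <- rep(0, ncol(x))
  structure(list(data = sweep(sweep(x, 2, mu), 2, scl, "/"),
                 column_means = mu, column_scales = scl,
                 method = method, zero_variance = zero),
            class = "scaled_matrix")
}

#' Apply stored pretreatment parameters to new data
#'
#' @param sm A `scaled_matrix` (the training pretreatment).
#' @param newdata Matrix with the same columns as the training data.
#' @return The transformed matrix.
#' @export
apply_scaling <- function(sm, newdata) {
  stopifnot(inherits(sm, "scaled_matrix"), ncol(newdata) == length(sm$column_means))
  sweep(sweep(newdata, 2, sm$column_means), 2, sm$column_scales, "/")
}

#' Invert a pretreatment
#'
#' @param sm A `scaled_matrix`.
#' @return The original data matrix.
#' @export
unscale <- function(sm) {
  sweep(sweep(sm$data, 2, sm$column_scales, "*"), 2, sm$column_means, "+")
}

#' Integrate a spectral window
#'
#' Trapezoidal integral of the (optionally total-area-normalized) intensity
#' over a ppm window.
#'
#' @param spectrum A `spectrum`.
#' @param window `c(lo, hi)` ppm interval; must overlap the axis.
#' @param normalized If `TRUE` (default), divide by the full-axis integral,
#'   so the full-axis window integrates to 1.
#' @return The integral (numeric scalar).
#' @export
integrate_window <- function(spectrum, window, normalized = TRUE) {
  stopifnot(inherits(spectrum, "spectrum"), length(window) == 2)
  lo <- min(window); hi <- max(window)
  if (hi <= min(spectrum$ppm) || lo >= max(spectrum$ppm)) {
    stop("window does not overlap the ppm axis")
  }
  F <- cumulative_integral(spectrum)
  val <- F(min(hi, max(spectrum$ppm))) - F(max(lo, min(spectrum$ppm)))
  if (normalized) {
    total <- F(max(spectrum$ppm)) - F(min(spectrum$ppm))
    if (total <= 0) stop("non-positive total area")
    val <- val / total
  }
  val
}

#' Screen out baseline-only bins
#'
#' Keeps bins whose across-sample median intensity exceeds `factor` times
#' the median bin level of the cohort — a light peak-region screen that
#' removes empty baseline regions before Monte-Carlo variable selection,
#' where they only dilute the per-variable sampling density.
#'
#' @param fm A `feature_matrix`.
#' @param factor Multiple of the median bin level (default 3).
#' @return The screened `feature_matrix`, with an attribute `kept`
#'   (indices into the original bins).
#' @export
filter_bins <- function(fm, factor = 3) {
  stopifnot(inherits(fm, "feature_matrix"))
  med <- apply(fm$data, 2, median)
  keep <- which(med > factor * median(med))
  if (length(keep) == 0) stop("no bins survive the intensity screen")
  out <- new_feature_matrix(fm$data[, keep, drop = FALSE], fm$labels,
                            fm$bin_edges[keep, , drop = FALSE], fm$sample_ids)
  attr(out, "kept") <- keep
  out
}

#' Map ppm positions to bin indices
#'
#' @param fm A `feature_matrix`.
#' @param ppm Numeric ppm positions (e.g. `truth$marker_ppm`).
#' @return Integer bin indices (`NA` where a position falls in an excluded
#'   region), named like `ppm`.
#' @export
marker_bins <- function(fm, ppm) {
  idx <- vapply(ppm, function(p) {
    j <- which(fm$bin_edges$hi > p & fm$bin_edges$lo <= p)
    if (length(j) == 1) j else NA_integer_
  }, 1L)
  names(idx) <- names(ppm)
  idx
}
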