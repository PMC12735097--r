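flat_spectrum <- function(value = 1, n = 2001, lo = 0, hi = 10) {
  new_spectrum(seq(hi, lo, length.out = n), rep(value, n))
}

test_that("constant unit intensity yields bin values equal to the bin width", {
  s <- flat_spectrum()
  fm <- bin_spectra(list(s, s), c(1, -1), bin_width_ppm = 0.5, exclusions = list())
  expect_equal(unname(fm$data[1, ]), rep(0.5, ncol(fm$data)), tolerance = 1e-9)
})

test_that("binning rejects degenerate inputs", {
  s <- flat_spectrum()
  expect_error(bin_spectra(list(s, s), c(1, -1), bin_width_ppm = 0.5,
                           exclusions = list(c(-1, 11))), "no bins remain")
  expect_error(bin_spectra(list(s, s), c(1, -1), bin_width_ppm = 1e-4), "resolution")
  s2 <- flat_spectrum(n = 1001)
  expect_error(bin_spectra(list(s, s2), c(1, -1)), "share")
})

test_that("an isolated narrow Lorentzian lands its closed-form area in one bin", {
  ppm <- seq(10, 0, length.out = 40001)
  g <- 0.0005  # hwhm; line fwhm 0.001 inside a 0.1-ppm bin
  y <- (1 / pi) * g / ((ppm - 5.05)^2 + g^2)  # unit-area Lorentzian
  s <- new_spectrum(ppm, y)
  fm <- bin_spectra(list(s, s), c(1, -1), bin_width_ppm = 0.1, exclusions = list())
  j <- marker_bins(fm, c(peak = 5.05))
  expect_equal(unname(fm$data[1, j]),
               lorentz_mass(5.05, 2 * g, 5.0, 5.1), tolerance = 0.01)
  neighbours <- fm$data[1, c(j - 1, j + 1)]
  expect_true(all(neighbours < 0.01))
})

test_that("binning is linear in the spectra", {
  set.seed(42)
  ppm <- seq(10, 0, length.out = 1501)
  y1 <- abs(rnorm(1501)); y2 <- abs(rnorm(1501))
  mix <- new_spectrum(ppm, 2 * y1 + 3 * y2)
  b <- function(y) bin_spectra(list(new_spectrum(ppm, y), new_spectrum(ppm, y)),
                               c(1, -1), bin_width_ppm = 0.25,
                               exclusions = list())$data[1, ]
  expect_equal(b(2 * y1 + 3 * y2), 2 * b(y1) + 3 * b(y2), tolerance = 1e-10)
})

test_that("total-area normalization is exact, idempotent and guarded", {
  fm <- new_feature_matrix(matrix(c(2, 2, 1, 3), 2, byrow = TRUE), c(1, -1),
                           data.frame(hi = c(2, 1), lo = c(1, 0)))
  nf <- normalize_total_area(fm)
  expect_equal(unname(nf$data[1, ]), c(0.5, 0.5))
  expect_equal(rowSums(nf$data), c(1, 1), tolerance = 1e-12)
  expect_equal(normalize_total_area(nf)$data, nf$data)
  bad <- fm; bad$data[1, ] <- c(-2, 1)
  expect_error(normalize_total_area(bad), "positive")
})

test_that("scaling matches hand-computed and two-pass oracle values", {
  x <- cbind(a = c(1, 2, 3), b = c(0, 0, 4))
  sc <- scale_features(x, "centre")
  expect_equal(unname(sc$data[, "a"]), c(-1, 0, 1))
  expect_equal(scale_features(x, "pareto")$data[, "a"], sc$data[, "a"],
               tolerance = 1e-12, ignore_attr = TRUE)  # sd = 1 so sqrt(sd) = 1
  two_pass_sd <- sqrt(sum((x[, "b"] - mean(x[, "b"]))^2) / 2)
  expect_equal(two_pass_sd, 4 / sqrt(3))
  au <- scale_features(x, "auto")
  expect_equal(unname(au$column_scales["b"]), two_pass_sd)
  expect_equal(unname(au$data[, "b"]), (x[, "b"] - mean(x[, "b"])) / two_pass_sd)
  expect_error(scale_features(x, "vast"))
})

test_that("zero-variance columns are flagged with unit scale", {
  x <- cbind(c(1, 1, 1), c(1, 2, 3))
  for (m in c("pareto", "auto")) {
    sc <- scale_features(x, m)
    expect_true(sc$zero_variance[1])
    expect_equal(unname(sc$column_scales[1]), 1)
    expect_true(all(is.finite(sc$data)))
  }
})

test_that("pretreatments are invertible and Pareto halves the log-SD", {
  set.seed(7)
  x <- matrix(rexp(60), 10, 6)
  for (m in c("centre", "pareto", "auto", "none")) {
    sc <- scale_features(x, m)
    expect_equal(unscale(sc), x, tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(sc$method, m)
  }
  pr <- scale_features(x, "pareto")
  expect_equal(apply(pr$data, 2, sd), sqrt(apply(x, 2, sd)), tolerance = 1e-9)
  centred <- scale_features(x, "centre")
  expect_equal(colMeans(centred$data), rep(0, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("apply_scaling reproduces the training transform on new data", {
  set.seed(8)
  x <- matrix(rnorm(50), 10, 5)
  sc <- scale_features(x, "pareto")
  expect_equal(apply_scaling(sc, x), sc$data, ignore_attr = TRUE)
})

test_that("window integration respects normalization and overlap rules", {
  s <- flat_spectrum()
  expect_equal(integrate_window(s, c(0, 10)), 1, tolerance = 1e-12)
  expect_equal(integrate_window(s, c(2, 4)), 0.2, tolerance = 1e-9)
  expect_error(integrate_window(s, c(11, 12)), "overlap")
})

test_that("excluded regions are dropped and marker lookup handles them", {
  ch <- small_cohort()
  fm <- small_fm(ch)
  expect_false(any(fm$ppm_mid > 4.7 & fm$ppm_mid < 5.0))
  expect_true(is.na(marker_bins(fm, c(water = 4.85))))
  mb <- marker_bins(fm, ch$truth$marker_ppm)
  expect_false(anyNA(mb))
  expect_true(all(fm$bin_edges$hi[mb] > ch$truth$marker_ppm &
                    fm$bin_edges$lo[mb] <= ch$truth$marker_ppm))
})

test_that("the intensity screen keeps peak regions and drops baseline", {
  fm <- default_fm()
  scr <- filter_bins(fm)
  expect_lt(ncol(scr$data), ncol(fm$data) / 2)
  mb <- marker_bins(scr, default_cohort()$truth$marker_ppm)
  expect_false(anyNA(mb))
})
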