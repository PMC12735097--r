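#' Metabolite template library for synthetic gonadal spectra
#'
#' Reads the packaged chemical-shift fixture and returns one template per
#' metabolite. Each template carries 1-3 Lorentzian lines at HMDB-style
#' reference positions (the fixture is configuration data, not measured
#' values), a relative area per line summing to 1, a baseline concentration,
#' and a species bias: `"A_lixula"` metabolites are elevated in the
#' *A. lixula* class (osmolytes and methylated amines such as betaine,
#' taurine, sarcosine, TMA/TMAO), `"P_lividus"` metabolites in the
#' *P. lividus* class (lysine, glycine, glutamine, C1 compounds and a broad
#' fatty-acid envelope), and `"shared"` metabolites (e.g. kynurenine) in
#' neither.
#'
#' @param path Path to a peak table (TSV with columns `name`, `kegg_id`,
#'   `species_bias`, `base_conc`, `center_ppm`, `relative_area`,
#'   `linewidth_ppm`). Defaults to the packaged fixture.
#' @return A list of `metabolite_template` objects with fields `name`,
#'   `kegg_id`, `species_bias`, `base_conc` and a `peaks` data frame
#'   (`center_ppm`, `relative_area`, `linewidth_ppm`).
#' @export
#' @examples
#' lib <- build_metabolite_library()
#' names(lib)[1:4]
build_metabolite_library <- function(path = system.file("extdata", "metabolite_peaks.tsv",
                                                        package = "metabodisc")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "kegg_id", "species_bias", "base_conc",
              "center_ppm", "relative_area", "linewidth_ppm")
  if (!all(needed %in% names(tab))) {
    stop("peak table must have columns: ", paste(needed, collapse = ", "))
  }
  lib <- lapply(split(tab, factor(tab$name, levels = unique(tab$name))), function(d) {
    peaks <- data.frame(center_ppm = d$center_ppm,
                        relative_area = d$relative_area / sum(d$relative_area),
                        linewidth_ppm = d$linewidth_ppm)
    stopifnot(nrow(peaks) >= 1,
              all(peaks$center_ppm >= 0, peaks$center_ppm <= 10),
              all(peaks$relative_area > 0), all(peaks$linewidth_ppm > 0))
    structure(list(name = d$name[1],
                   kegg_id = if (nzchar(d$kegg_id[1])) d$kegg_id[1] else "",
                   species_bias = match.arg(d$species_bias[1],
                                            c("A_lixula", "P_lividus", "shared")),
                   base_conc = d$base_conc[1],
                   peaks = peaks),
              class = "metabolite_template")
  })
  lib[unique(tab$name)]
}

#' Configuration for a synthetic two-class cohort
#'
#' Defaults define the reference study conditions used throughout the
#' package: 12 spectra per species, a mean log2 fold-difference of 2
#' (four-fold between class geometric means, applied symmetrically in log
#' space so each class moves by `2^(log2_effect/2)` around a shared
#' baseline), 20% biological coefficient of variation, low additive noise,
#' a weak smooth baseline, and a small per-spectrum chemical-shift jitter.
#' The default axis places 0.01-ppm bin centres on the conventional
#' shift-reporting grid.
#'
#' @param n_per_class Spectra per species (>= 3).
#' @param ppm_axis Numeric `c(min, max, n_points)`; ppm axis limits and
#'   number of points (>= 64).
#' @param log2_effect Mean log2 fold-difference injected into biased
#'   metabolites.
#' @param biological_cv Log-scale SD of per-sample metabolite concentration.
#' @param noise_sd SD of additive Gaussian point noise.
#' @param baseline_amplitude Scale of the smooth random polynomial baseline.
#' @param shift_jitter_sd_ppm SD of the per-spectrum global ppm shift.
#' @param seed Integer root seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_class = 12,
                          ppm_axis = c(-0.495, 10.005, 16384),
                          log2_effect = 2,
                          biological_cv = 0.2,
                          noise_sd = 0.5,
                          baseline_amplitude = 0.2,
                          shift_jitter_sd_ppm = 0.0015,
                          seed = 1) {
  stopifnot(n_per_class >= 3, length(ppm_axis) == 3, ppm_axis[2] > ppm_axis[1],
            noise_sd >= 0, shift_jitter_sd_ppm >= 0, biological_cv >= 0)
  if (ppm_axis[3] < 64) stop("degenerate ppm axis: n_points must be >= 64")
  structure(list(n_per_class = as.integer(n_per_class),
                 ppm_axis = ppm_axis,
                 log2_effect = log2_effect,
                 biological_cv = biological_cv,
                 noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 shift_jitter_sd_ppm = shift_jitter_sd_ppm,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Render one Lorentzian line and rescale so its trapezoidal integral on the
# discrete axis equals `area` exactly (absorbs quadrature error and the mass
# truncated at the axis ends).
render_lorentzian <- function(ppm, center, area, fwhm) {
  hwhm <- fwhm / 2
  y <- hwhm^2 / ((ppm - center)^2 + hwhm^2)
  got <- trapz_descending(ppm, y)
  if (got <= 0) return(rep(0, length(ppm)))
  y * (area / got)
}

# Trapezoidal integral over a strictly descending ppm axis.
trapz_descending <- function(ppm, y) {
  n <- length(ppm)
  sum((y[-n] + y[-1]) / 2 * (ppm[-n] - ppm[-1]))
}

#' Simulate a two-class cohort of 1D NMR-like spectra
#'
#' Renders each metabolite as Lorentzian lines on a shared descending ppm
#' axis. Metabolites biased towards a species are scaled by
#' `2^(+log2_effect/2)` in that class and `2^(-log2_effect/2)` in the other,
#' so class geometric means straddle the shared baseline concentration.
#' Per-sample concentrations vary log-normally (`biological_cv`), each
#' spectrum receives a global chemical-shift jitter, a smooth random
#' polynomial baseline and additive Gaussian noise. Fully reproducible from
#' `config$seed` via fixed-offset per-spectrum substreams.
#'
#' @param config A [cohort_config()].
#' @param library A metabolite library from [build_metabolite_library()].
#' @return A list with `spectra` (list of `spectrum` objects, class
#'   *A. lixula* first), and `truth` (`cohort_truth`): `labels` (+1 =
#'   *A. lixula*, -1 = *P. lividus*), `classes`, `enriched_in_A`,
#'   `enriched_in_B`, `marker_ppm` (dominant line per biased metabolite),
#'   `concentrations` (samples x metabolites) and `template_area` per
#'   metabolite.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_class = 3, ppm_axis = c(0, 10, 1024)),
#'                           build_metabolite_library())
#' length(cohort$spectra)
simulate_cohort <- function(config, library = build_metabolite_library()) {
  stopifnot(inherits(config, "cohort_config"), length(library) >= 1)
  n <- config$n_per_class
  axis <- config$ppm_axis
  ppm <- seq(axis[2], axis[1], length.out = axis[3])
  classes <- rep(c("A_lixula", "P_lividus"), each = n)
  labels <- ifelse(classes == "A_lixula", 1, -1)
  half <- config$log2_effect / 2

  bias <- vapply(library, `[[`, "", "species_bias")
  base <- vapply(library, `[[`, 1, "base_conc")
  mnames <- vapply(library, `[[`, "", "name")

  conc <- matrix(NA_real_, nrow = 2 * n, ncol = length(library),
                 dimnames = list(NULL, mnames))
  spectra <- vector("list", 2 * n)
  for (i in seq_len(2 * n)) {
    set.seed(derive_seed(config$seed, i))
    direction <- ifelse(bias == "shared", 0, ifelse(bias == classes[i], 1, -1))
    ci <- base * 2^(direction * half) * exp(rnorm(length(library), 0, config$biological_cv))
    conc[i, ] <- ci
    jitter <- rnorm(1, 0, config$shift_jitter_sd_ppm)
    y <- numeric(length(ppm))
    for (m in seq_along(library)) {
      pk <- library[[m]]$peaks
      for (k in seq_len(nrow(pk))) {
        y <- y + render_lorentzian(ppm, pk$center_ppm[k] + jitter,
                                   ci[m] * pk$relative_area[k], pk$linewidth_ppm[k])
      }
    }
    if (config$baseline_amplitude > 0) {
      u <- seq(-1, 1, length.out = length(ppm))
      coefs <- rnorm(5, 0, 1) / (1 + 0:4)
      y <- y + config$baseline_amplitude *
        (coefs[1] + coefs[2] * u + coefs[3] * (2 * u^2 - 1) +
           coefs[4] * (4 * u^3 - 3 * u) + coefs[5] * (8 * u^4 - 8 * u^2 + 1) + 1)
    }
    if (config$noise_sd > 0) y <- y + rnorm(length(ppm), 0, config$noise_sd)
    spectra[[i]] <- new_spectrum(ppm, y)
  }

  biased_A <- mnames[bias == "A_lixula"]
  biased_B <- mnames[bias == "P_lividus"]
  marker_ppm <- vapply(library[bias != "shared"], function(tmpl) {
    tmpl$peaks$center_ppm[which.max(tmpl$peaks$relative_area)]
  }, 1)
  names(marker_ppm) <- mnames[bias != "shared"]

  truth <- structure(list(labels = labels,
                          classes = classes,
                          enriched_in_A = biased_A,
                          enriched_in_B = biased_B,
                          marker_ppm = marker_ppm,
                          concentrations = conc,
                          template_area = setNames(rep(1, length(library)), mnames)),
                     class = "cohort_truth")
  list(spectra = spectra, truth = truth)
}

#' Construct a spectrum object
#'
#' @param ppm Strictly descending numeric vector of chemical shifts.
#' @param intensity Numeric vector of the same length; must be finite.
#' @return A `spectrum` object.
#' @export
new_spectrum <- function(ppm, intensity) {
  stopifnot(length(ppm) == length(intensity), all(diff(ppm) < 0),
            all(is.finite(intensity)))
  structure(list(ppm = ppm, intensity = intensity), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.3f to %.3f ppm\n",
              length(x$ppm), max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes a wide CSV (`sample_id`, `class`, then one intensity column per
#' ppm point), one two-column ppm/intensity CSV per sample, and the ground
#' truth as JSON.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ppm <- cohort$spectra[[1]]$ppm
  wide <- data.frame(sample_id = sprintf("S%02d", seq_along(cohort$spectra)),
                     class = cohort$truth$classes,
                     check.names = FALSE)
  mat <- t(vapply(cohort$spectra, function(s) s$intensity, numeric(length(ppm))))
  colnames(mat) <- sprintf("%.5f", ppm)
  wide <- cbind(wide, as.data.frame(mat, check.names = FALSE))
  wide_path <- file.path(dir, "spectra_wide.csv")
  write.csv(wide, wide_path, row.names = FALSE)
  per_sample <- vapply(seq_along(cohort$spectra), function(i) {
    p <- file.path(dir, sprintf("spectrum_%s.csv", wide$sample_id[i]))
    write.csv(data.frame(ppm = ppm, intensity = cohort$spectra[[i]]$intensity),
              p, row.names = FALSE)
    p
  }, "")
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth[c("labels", "classes", "enriched_in_A",
                                      "enriched_in_B", "marker_ppm")],
                       truth_path, auto_unbox = FALSE, digits = NA)
  invisible(c(wide_path, per_sample, truth_path))
}

#' Read a wide-format cohort CSV back into spectra
#'
#' @param path Path to a file written by [write_cohort()].
#' @return A list with `spectra`, `classes` and `labels`.
#' @export
read_cohort_wide <- function(path) {
  wide <- read.csv(path, check.names = FALSE)
  ppm <- as.numeric(names(wide)[-(1:2)])
  spectra <- lapply(seq_len(nrow(wide)), function(i) {
    new_spectrum(ppm, as.numeric(wide[i, -(1:2)]))
  })
  list(spectra = spectra, classes = wide$class,
       labels = ifelse(wide$class == "A_lixula", 1, -1))
}
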