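# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, expr, .fixture_env)
  get(key, .fixture_env)
}

metab_library <- function() memo("library", build_metabolite_library())

# The reference study conditions: 12 + 12 spectra, log2 effect 2, seed 1.
default_cohort <- function() {
  memo("cohort", simulate_cohort(cohort_config(), metab_library()))
}

default_fm <- function() {
  memo("fm", normalize_total_area(bin_spectra(default_cohort()$spectra,
                                              default_cohort()$truth$labels)))
}

# A lighter cohort for property loops (coarser axis, fewer samples).
small_cohort <- function(seed = 1, n_per_class = 6, log2_effect = 2, ...) {
  simulate_cohort(cohort_config(n_per_class = n_per_class,
                                ppm_axis = c(-0.495, 10.005, 4096),
                                log2_effect = log2_effect, seed = seed, ...),
                  metab_library())
}

small_fm <- function(cohort) {
  normalize_total_area(bin_spectra(cohort$spectra, cohort$truth$labels,
                                   bin_width_ppm = 0.02))
}

# Small two-pathway library with a universe of 10 compounds: pathway "pw1"
# has 4 members (a chain), "pw2" the remaining 6.
toy_pathway_library <- function() {
  ids1 <- sprintf("T%02d", 1:4)
  ids2 <- sprintf("T%02d", 5:10)
  structure(list(
    pathways = list(
      pw1 = list(id = "pw1", name = "toy pathway one", compounds = ids1,
                 edges = cbind(ids1[-4], ids1[-1])),
      pw2 = list(id = "pw2", name = "toy pathway two", compounds = ids2,
                 edges = cbind(ids2[-6], ids2[-1]))),
    universe = c(ids1, ids2)), class = "pathway_library")
}
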