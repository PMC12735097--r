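#' End-to-end run configuration
#'
#' Collects every stage parameter with the published analysis settings as
#' defaults: 3 latent variables with mean centering for the main model,
#' SPA at Q = 15, K = 3, ratio = 0.7, N = 1000 with Pareto scaling,
#' COSS > 2 selection, VIP > 1.0 profiling, and 0.01-ppm binning with
#' water/TSP exclusions. The configuration is validated up front and
#' persisted verbatim next to the outputs.
#'
#' @param outdir Output directory.
#' @param seed Root seed for all stages.
#' @param cohort A [cohort_config()] (its seed is overridden by `seed`).
#' @param bin_width_ppm Bucket width.
#' @param exclusions Excluded ppm intervals.
#' @param ncomp Latent variables for the main PLS-LDA model.
#' @param cv_folds,cv_repeats Cross-validation design.
#' @param n_perm Label permutations for the model permutation test
#'   (0 skips it).
#' @param spa An [spa_config()] (its seed is overridden by `seed`).
#' @param screen_factor Optional intensity-screen factor passed to
#'   [filter_bins()] before SPA; `NULL` (default) runs SPA on the full
#'   binned matrix as in the published workflow.
#' @param vip_threshold VIP cut-off reported in the diagnostics export.
#' @param window_half_width Half-width for targeted integration windows.
#' @param stages Named logical toggles: `simulate`, `preprocess`, `fit`,
#'   `spa`, `integrate`, `pathway`.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir = tempfile("metabodisc_run_"),
                       seed = 1,
                       cohort = cohort_config(),
                       bin_width_ppm = 0.01,
                       exclusions = default_exclusions(),
                       ncomp = 3,
                       cv_folds = 5,
                       cv_repeats = 20,
                       n_perm = 0,
                       spa = spa_config(),
                       screen_factor = NULL,
                       vip_threshold = 1.0,
                       window_half_width = 0.015,
                       stages = c(simulate = TRUE, preprocess = TRUE, fit = TRUE,
                                  spa = TRUE, integrate = TRUE, pathway = TRUE)) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(spa, "spa_config"),
            ncomp >= 1, cv_folds >= 2, cv_repeats >= 1,
            all(c("simulate", "preprocess", "fit", "spa", "integrate",
                  "pathway") %in% names(stages)))
  cohort$seed <- as.integer(seed)
  spa$seed <- derive_seed(seed, 7)
  structure(list(outdir = outdir, seed = as.integer(seed), cohort = cohort,
                 bin_width_ppm = bin_width_ppm, exclusions = exclusions,
                 ncomp = ncomp, cv_folds = cv_folds, cv_repeats = cv_repeats,
                 n_perm = n_perm, spa = spa, screen_factor = screen_factor,
                 vip_threshold = vip_threshold,
                 window_half_width = window_half_width,
                 stages = as.logical(stages[c("simulate", "preprocess", "fit",
                                              "spa", "integrate", "pathway")])),
            class = "run_config")
}

write_stage_csv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full discrimination pipeline
#'
#' Executes simulate -> preprocess -> fit/CV (-> permutation test) -> SPA
#' -> targeted integration -> pathway ORA, writing plain-text figure data
#' at every stage (see [export_figure_data()]) and a JSON manifest with
#' the seed, parameters, per-file MD5 checksums and package version. Any
#' stage failure aborts with a stage-tagged message. With a stage toggled
#' off, its outputs are re-read from `outdir` (a clear error is raised if
#' they are missing).
#'
#' @param config A [run_config()].
#' @return The manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass_config(config), file.path(config$outdir, "run_config.yaml"))
  stage_names <- c("simulate", "preprocess", "fit", "spa", "integrate", "pathway")
  on_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  library_ <- build_metabolite_library()
  files <- character()

  # -- simulate ---------------------------------------------------------
  cohort <- on_stage("simulate", {
    if (config$stages[1]) {
      ch <- simulate_cohort(config$cohort, library_)
      files <- c(files, write_cohort(ch, file.path(config$outdir, "cohort")))
      ch
    } else {
      wide <- file.path(config$outdir, "cohort", "spectra_wide.csv")
      if (!file.exists(wide)) stop("stage disabled and no cached cohort at ", wide)
      cw <- read_cohort_wide(wide)
      list(spectra = cw$spectra, truth = list(labels = cw$labels, classes = cw$classes))
    }
  })

  # -- preprocess -------------------------------------------------------
  fm <- on_stage("preprocess", {
    if (!config$stages[2]) stop("the preprocess stage cannot be disabled")
    fm <- bin_spectra(cohort$spectra, cohort$truth$labels,
                      bin_width_ppm = config$bin_width_ppm,
                      exclusions = config$exclusions)
    fm <- normalize_total_area(fm)
    files <- c(files, write_stage_csv(
      data.frame(sample_id = fm$sample_ids, class = ifelse(fm$labels > 0, "A_lixula", "P_lividus"),
                 fm$data, check.names = FALSE),
      config$outdir, "feature_matrix.csv"))
    fm
  })

  # -- fit --------------------------------------------------------------
  fitted <- on_stage("fit", {
    sc <- scale_features(fm, "centre")
    model <- fit_nipals_pls(sc, fm$labels, ncomp = config$ncomp)
    boundary <- fit_discriminant(model$scores, fm$labels)
    cv <- cross_validate(fm, ncomp = config$ncomp, folds = config$cv_folds,
                         repeats = config$cv_repeats, seed = derive_seed(config$seed, 3))
    perm <- if (config$n_perm >= 99) {
      permutation_test_plslda(fm, ncomp = config$ncomp, n_perm = config$n_perm,
                              folds = config$cv_folds, seed = derive_seed(config$seed, 4))
    } else NULL
    list(model = model, boundary = boundary, cv = cv, perm = perm)
  })

  # -- spa --------------------------------------------------------------
  spa_out <- on_stage("spa", {
    if (config$stages[4]) {
      if (!is.null(config$screen_factor)) {
        screened <- filter_bins(fm, config$screen_factor)
        res <- run_spa(screened, config$spa)
        res$table$bin <- attr(screened, "kept")[res$table$bin]
        res$table$ppm <- fm$ppm_mid[res$table$bin]
        res
      } else {
        run_spa(fm, config$spa)
      }
    } else NULL
  })

  # -- integrate --------------------------------------------------------
  integ <- on_stage("integrate", {
    if (config$stages[5]) {
      windows <- metabolite_windows(library_, config$window_half_width)
      if (!is.null(spa_out)) {
        sel_bins <- select_variables(spa_out)
        sel_ppm <- fm$ppm_mid[sel_bins]
        keep <- vapply(windows, function(w) any(sel_ppm >= w[1] & sel_ppm <= w[2]), TRUE)
        if (any(keep)) windows <- windows[keep]
      }
      build_metabolite_table(cohort$spectra, windows, cohort$truth$labels)
    } else NULL
  })

  # -- pathway ----------------------------------------------------------
  ora_out <- on_stage("pathway", {
    if (!config$stages[6]) return(NULL)
    lib <- load_pathway_library()
    tab <- if (!is.null(integ)) integ$table else NULL
    panels <- if (!is.null(tab)) {
      list(A_lixula = tab$metabolite[tab$direction == "A_lixula" & tab$raw_p < 0.01],
           P_lividus = tab$metabolite[tab$direction == "P_lividus" & tab$raw_p < 0.01])
    } else {
      list(A_lixula = cohort$truth$enriched_in_A,
           P_lividus = cohort$truth$enriched_in_B)
    }
    out <- lapply(panels, function(nm) {
      mp <- map_compound_names(nm)
      if (length(mp$unmapped)) {
        message("unmapped compound names: ", paste(mp$unmapped, collapse = ", "))
      }
      if (length(intersect(mp$ids, lib$universe)) == 0) {
        message("panel has no compounds in the pathway universe; skipped")
        return(NULL)
      }
      suppressMessages(run_ora(mp$ids, lib))
    })
    Filter(Negate(is.null), out)
  })

  files <- c(files, export_figure_data(config$outdir, fm = fm, fitted = fitted,
                                       spa = spa_out, integ = integ, ora = ora_out))
  manifest <- list(
    package = "metabodisc",
    version = as.character(utils::packageVersion("metabodisc")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages_run = setNames(as.list(config$stages), stage_names),
    cv = fitted$cv[c("error", "sensitivity", "specificity", "auc")],
    permutation_p = if (!is.null(fitted$perm)) fitted$perm$p_value else NULL,
    n_selected = if (!is.null(spa_out)) sum(spa_out$table$selected) else NULL,
    files = as.list(setNames(unname(tools::md5sum(sort(unique(files)))),
                             basename(sort(unique(files)))))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out$spa <- unclass(out$spa)
  out$stages <- as.list(setNames(out$stages, c("simulate", "preprocess", "fit",
                                               "spa", "integrate", "pathway")))
  out
}

#' Export plain-text figure data
#'
#' Writes the tables needed to regenerate every figure of the workflow
#' without rerunning computation: score plot with the LV1/LV2 discriminant
#' boundary and per-species 95% ellipses, VIP/tpLoadings profile, COSS and
#' DMEAN-DSD tables, per-metabolite boxplot statistics and integrals, and
#' per-species pathway bubble tables.
#'
#' @param outdir Output directory.
#' @param fm Feature matrix.
#' @param fitted List with `model`, `boundary`, `cv` (from the fit stage).
#' @param spa Optional `spa_result`.
#' @param integ Optional `metabolite_table`.
#' @param ora Optional named list of `ora_result`s.
#' @return Character vector of files written.
#' @export
export_figure_data <- function(outdir, fm, fitted, spa = NULL, integ = NULL,
                               ora = NULL) {
  files <- character()
  model <- fitted$model; boundary <- fitted$boundary
  scores <- as.data.frame(model$scores)
  names(scores) <- paste0("LV", seq_len(ncol(scores)))
  sc_df <- cbind(data.frame(sample_id = fm$sample_ids,
                            class = ifelse(fm$labels > 0, "A_lixula", "P_lividus")),
                 scores)
  b12 <- boundary$boundary_lv12
  if (!is.null(b12)) {
    sc_df$c1 <- b12[["c1"]]; sc_df$c2 <- b12[["c2"]]; sc_df$c0 <- b12[["c0"]]
  }
  files <- c(files, write_stage_csv(sc_df, outdir, "scores_lv.csv"))

  if (ncol(model$scores) >= 2) {
    ell <- lapply(c(1, -1), function(cl) {
      e <- confidence_ellipse(model$scores[fm$labels == cl, 1:2, drop = FALSE])
      data.frame(class = if (cl > 0) "A_lixula" else "P_lividus",
                 center_lv1 = e$center[1], center_lv2 = e$center[2],
                 radius_major = e$radii[1], radius_minor = e$radii[2],
                 angle = e$angle)
    })
    files <- c(files, write_stage_csv(do.call(rbind, ell), outdir, "score_ellipses.csv"))
  }

  prof <- data.frame(ppm = fm$ppm_mid, vip = vip(model), tploading = tp_loadings(model))
  prof$selected_vip <- prof$vip > 1.0
  files <- c(files, write_stage_csv(prof, outdir, "vip_tploadings.csv"))
  files <- c(files, write_stage_csv(
    data.frame(metric = c("error", "sensitivity", "specificity", "auc",
                          "r2x_cum", "r2y_cum"),
               value = c(fitted$cv$error, fitted$cv$sensitivity,
                         fitted$cv$specificity, fitted$cv$auc,
                         model$r2x_cum[model$ncomp], model$r2y_cum[model$ncomp])),
    outdir, "model_metrics.csv"))

  if (!is.null(spa)) {
    files <- c(files, write_stage_csv(spa$table, outdir, "spa_coss.csv"))
    sel <- spa$table[spa$table$selected, c("bin", "ppm", "coss", "dmean", "dsd")]
    files <- c(files, write_stage_csv(sel, outdir, "spa_selected.csv"))
  }
  if (!is.null(integ)) {
    files <- c(files, write_stage_csv(integ$table, outdir, "metabolite_boxplots.csv"))
    files <- c(files, write_stage_csv(
      cbind(data.frame(sample_id = rownames(integ$integrals) %||%
                         sprintf("S%02d", seq_len(nrow(integ$integrals)))),
            as.data.frame(integ$integrals)),
      outdir, "metabolite_integrals.csv"))
  }
  if (!is.null(ora)) {
    for (panel in names(ora)) {
      files <- c(files, write_stage_csv(as.data.frame(ora[[panel]]), outdir,
                                        sprintf("ora_%s.csv", panel)))
      files <- c(files, write_stage_csv(bubble_data(ora[[panel]]), outdir,
                                        sprintf("bubble_%s.csv", panel)))
    }
  }
  files
}
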