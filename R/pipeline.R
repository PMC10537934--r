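#' Validate and resolve a pipeline run configuration
#'
#' A run configuration is a YAML file (or an equivalent nested list)
#' with three optional sections: `generator` (fields of
#' [generator_config()]), `cv` (`repeats`, `folds`, `aggregation`) and
#' `models` — either a character vector of model ids or a named list of
#' per-model hyperparameter overrides (e.g.
#' `list(M7 = list(num_trees = 300), M0 = list())`) — plus a top-level
#' `seed`. Missing fields are filled with package defaults; every
#' invariant is checked before any work starts and violations are
#' reported with their field path.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return Object of class `run_config`: list with resolved `generator`
#'   (a `generator_config`), `cv`, `models` (always normalized to a
#'   named list of override lists) and `seed`.
#' @export
#' @examples
#' validate_run_config(list(generator = list(n_patients = 40),
#'                          cv = list(repeats = 2)))
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    abort_if(!file.exists(config), paste0("config file not found: ", config),
             "echodens_io_error")
    config <- yaml::read_yaml(config)
  }
  abort_if(!is.list(config), "`config` must be a list or a YAML file path",
           "echodens_config_error")
  known <- c("generator", "cv", "models", "seed")
  unknown <- setdiff(names(config), known)
  abort_if(length(unknown) > 0,
           paste0("unknown config sections: ", paste(unknown, collapse = ", ")),
           "echodens_config_error")

  gen_args <- config$generator %||% list()
  bad <- setdiff(names(gen_args), names(formals(generator_config)))
  abort_if(length(bad) > 0,
           paste0("generator: unknown fields: ", paste(bad, collapse = ", ")),
           "echodens_config_error")
  gen <- tryCatch(do.call(generator_config, gen_args),
                  error = function(e) rlang::abort(
                    paste0("generator: ", conditionMessage(e)),
                    class = "echodens_config_error"))

  cv <- utils::modifyList(list(repeats = 100L, folds = 3L,
                               aggregation = "fold"),
                          config$cv %||% list())
  abort_if(cv$repeats < 1, "cv.repeats: must be >= 1",
           "echodens_config_error")
  abort_if(cv$folds < 2 || cv$folds > max(gen$n_patients, 2L),
           "cv.folds: must lie in 2..n_patients", "echodens_config_error")
  abort_if(!cv$aggregation %in% c("fold", "pooled"),
           "cv.aggregation: must be 'fold' or 'pooled'",
           "echodens_config_error")

  # models: either a character vector of ids, or a named list of
  # per-model hyperparameter overrides, e.g. list(M7 = list(num_trees = 300))
  models <- config$models %||% paste0("M", 0:7)
  if (is.list(models)) {
    abort_if(is.null(names(models)) || any(names(models) == ""),
             "models: override lists must be named by model id",
             "echodens_config_error")
    overrides <- lapply(models, function(m) if (is.list(m)) m else list())
  } else {
    overrides <- setNames(rep(list(list()), length(models)), models)
  }
  bad <- setdiff(names(overrides), paste0("M", 0:7))
  abort_if(length(bad) > 0,
           paste0("models: unknown ids: ", paste(bad, collapse = ", ")),
           "echodens_config_error")
  models <- overrides

  structure(list(generator = gen, cv = cv, models = models,
                 seed = as.integer(config$seed %||% gen$seed)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 class = "echodens_stage_error", parent = e)
  })
}

#' Run the full density-prediction pipeline
#'
#' Orchestrates generate, extract, model, evaluate and report: writes the
#' synthetic images and manifest, the per-patient gray-level-bin feature
#' CSV, the cross-validation summary (the performance-table analogue) and
#' per-fold records, per-model fitted summaries (JSON), the per-bin
#' Spearman profile, the hold-out scatter of the final model, the
#' standard figures, and a run log with the resolved configuration and
#' all derived seeds. Re-running with the same configuration reproduces
#' every numeric output byte-for-byte. While a run is underway an
#' `INCOMPLETE` marker file sits in `out_dir`; it is removed on success,
#' so its presence flags the partial outputs of an aborted run.
#'
#' @param config Path to a YAML run configuration, a list, or a
#'   `run_config`.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of the configured global seed.
#' @param repeats,models Optional overrides of the configured
#'   cross-validation repeats and model suite (`models` as in
#'   [validate_run_config()]).
#' @param write_images Write the per-view PNGs and masks? Disabling keeps
#'   pixel data in memory and speeds up simulation studies; the manifest
#'   then records in-memory keys.
#' @return (Invisibly) a list with the `cohort`, `features`, `cv`,
#'   `spearman`, `holdout` results and the output `paths`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, repeats = NULL,
                         models = NULL, write_images = TRUE) {
  cfg <- pipeline_stage("validate", {
    if (inherits(config, "run_config")) config else validate_run_config(config)
  })
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(repeats)) cfg$cv$repeats <- as.integer(repeats)
  if (!is.null(models)) {
    cfg$models <- if (is.list(models)) models else
      setNames(rep(list(list()), length(models)), models)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(out_dir),
           paste0("cannot create output directory: ", out_dir),
           "echodens_io_error")
  # present while the run is underway; any stage failure leaves it
  # behind to flag the partial outputs
  incomplete <- file.path(out_dir, "INCOMPLETE")
  file.create(incomplete)

  seeds <- derive_seeds(cfg$seed, 3L)
  gen_cfg <- cfg$generator
  gen_cfg$seed <- seeds[1]

  cohort <- pipeline_stage("generate", {
    generate_cohort(gen_cfg,
                    out_dir = if (write_images)
                      file.path(out_dir, "images") else NULL)
  })
  if (!write_images) {
    readr::write_csv(cohort$manifest, file.path(out_dir, "manifest.csv"))
  }
  readr::write_csv(cohort$truth, file.path(out_dir, "truth.csv"))

  features <- pipeline_stage("features", cohort_features(cohort))
  write_features(features, file.path(out_dir, "features.csv"))

  specs <- lapply(names(cfg$models), function(id) {
    do.call(pmd_model_spec, c(list(id), cfg$models[[id]]))
  })
  names(specs) <- names(cfg$models)
  cv <- pipeline_stage("evaluate", {
    repeated_cv(features, specs, repeats = cfg$cv$repeats,
                folds = cfg$cv$folds, seed = seeds[2],
                aggregation = cfg$cv$aggregation)
  })
  readr::write_csv(cv$summary, file.path(out_dir, "cv_summary.csv"))
  readr::write_csv(cv$records, file.path(out_dir, "cv_records.csv"))
  jsonlite::write_json(cv$records, file.path(out_dir, "cv_records.json"),
                       digits = NA)

  fits <- pipeline_stage("refit", {
    lapply(specs, function(sp) fit_pmd(features, sp, seed = seeds[2]))
  })
  jsonlite::write_json(dplyr::bind_rows(lapply(fits, glance)),
                       file.path(out_dir, "model_summaries.json"),
                       digits = NA)

  sp <- pipeline_stage("correlations", spearman_profile(features))
  readr::write_csv(sp, file.path(out_dir, "spearman.csv"))

  ho <- pipeline_stage("holdout", {
    holdout_illustration(features, specs[[cv$final_model]], seed = seeds[3])
  })
  readr::write_csv(ho$table, file.path(out_dir, "holdout.csv"))

  pipeline_stage("figures", {
    ggplot2::ggsave(file.path(out_dir, "pmd_distribution.png"),
                    plot_pmd_distribution(features), width = 6, height = 4,
                    dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "spearman_profile.png"),
                    autoplot(sp), width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "holdout_scatter.png"),
                    autoplot(ho), width = 5, height = 5, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "model_performance.png"),
                    autoplot(cv), width = 6, height = 4, dpi = 150)
  })

  log <- list(
    package_version = as.character(utils::packageVersion("echodens")),
    seed = cfg$seed,
    derived_seeds = list(generator = seeds[1], cv = seeds[2],
                         holdout = seeds[3]),
    generator = unclass(gen_cfg),
    cv = cfg$cv,
    models = cfg$models,
    final_model = cv$final_model
  )
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  file.remove(incomplete)

  invisible(list(cohort = cohort, features = features, cv = cv,
                 spearman = sp, holdout = ho,
                 paths = list(out_dir = out_dir,
                              features = file.path(out_dir, "features.csv"),
                              cv_summary = file.path(out_dir, "cv_summary.csv"),
                              run_log = file.path(out_dir, "run_log.yaml"))))
}
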