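#' Mean squared error
#'
#' @param y_obs,y_pred Equal-length numeric vectors.
#' @return Mean of squared residuals.
#' @export
mse <- function(y_obs, y_pred) {
  abort_if(length(y_obs) != length(y_pred) || length(y_obs) == 0,
           "`y_obs` and `y_pred` must have equal non-zero length",
           "echodens_value_error")
  mean((y_obs - y_pred)^2)
}

#' R-squared against the observed mean
#'
#' `1 - MSE(y_obs, y_pred) / Var_n(y_obs)` with the population variance
#' (divisor `n`) of the observed values about their own mean. On training
#' data this lies in `[0, 1]` for least-squares fits and is exactly 0 for
#' the training-mean (null) prediction; on validation data it can be
#' negative, meaning the model predicts worse than the validation mean.
#'
#' @param y_obs Observed values; at least 2, non-constant.
#' @param y_pred Predictions.
#' @return R-squared, possibly negative.
#' @export
r_squared <- function(y_obs, y_pred) {
  abort_if(length(y_obs) < 2, "need at least 2 observations",
           "echodens_value_error")
  v <- var_n(y_obs)
  abort_if(v == 0, "R-squared undefined: `y_obs` has zero variance",
           "echodens_metric_error")
  1 - mse(y_obs, y_pred) / v
}

#' Repeated k-fold cross-validation of the model suite
#'
#' For each of `repeats` repetitions the cohort is partitioned afresh
#' into `folds` near-equal random folds; every model — including its
#' stepwise selection, penalty tuning and spline knot placement — is
#' rebuilt on the training folds and scored on the held-out fold. The
#' default 100 x 3-fold protocol yields 300 held-out records per model.
#' Apparent measures come from fitting and scoring on the complete data.
#' The model with the smallest cross-validated MSE is flagged as the
#' final model.
#'
#' Two aggregation rules for the cross-validated R-squared are available:
#' `"fold"` (default) computes R-squared within each held-out fold
#' (fold-local observed variance) and averages the fold values; `"pooled"`
#' pools squared errors over all records and relates them to the full
#' cohort variance. The fold partition RNG stream is independent of the
#' model RNG streams, so different suites are comparable on identical
#' partitions.
#'
#' @param data Feature tibble (`bin_01`..`bin_15`, `pmd_observed`).
#' @param specs List of [pmd_model_spec()]s (default the M0-M7 suite).
#' @param repeats Number of repetitions (default 100).
#' @param folds Number of folds (default 3).
#' @param seed Integer seed for partitions and model randomness.
#' @param aggregation `"fold"` or `"pooled"` (see above).
#' @return Object of class `pmd_cv`: list with `summary` (one row per
#'   model: `model_id`, `label`, `apparent_mse`, `apparent_r2`, `cv_mse`,
#'   `cv_r2`, `final`), `records` (one row per repeat x fold x model) and
#'   the run settings.
#' @export
#' @examples
#' feats <- simulate_linear_features(60, oracle_r2 = 0.4, seed = 7)
#' cv <- repeated_cv(feats, pmd_model_suite(c("M0", "M1")),
#'                   repeats = 2, seed = 7)
#' tidy(cv)
repeated_cv <- function(data, specs = pmd_model_suite(), repeats = 100L,
                        folds = 3L, seed = 1L,
                        aggregation = c("fold", "pooled")) {
  aggregation <- match.arg(aggregation)
  abort_if(length(specs) == 0, "`specs` must be non-empty",
           "echodens_value_error")
  if (inherits(specs, "pmd_model_spec")) specs <- list(specs)
  fx <- check_features(data, min_n = 2L)
  n <- nrow(data)
  abort_if(repeats < 1, "`repeats` must be >= 1", "echodens_config_error")
  abort_if(folds < 2 || folds > n, "`folds` must lie in 2..n",
           "echodens_config_error")
  abort_if(n %/% folds < 2,
           "fold size below 2 observations: reduce `folds` or enlarge the cohort",
           "echodens_config_error")
  ids <- vapply(specs, `[[`, character(1), "model_id")
  names(specs) <- ids

  seeds <- derive_seeds(seed, 2L)
  partition_seeds <- derive_seeds(seeds[1], repeats)
  n_model_seeds <- repeats * folds * length(specs)
  all_model_seeds <- derive_seeds(seeds[2], n_model_seeds + length(specs))
  model_seeds <- array(all_model_seeds[seq_len(n_model_seeds)],
                       dim = c(repeats, folds, length(specs)))
  apparent_seeds <- all_model_seeds[n_model_seeds + seq_along(specs)]

  y <- fx$y
  apparent <- purrr::imap(specs, function(sp, id) {
    f <- fit_pmd(data, sp, seed = apparent_seeds[match(id, ids)])
    pred <- predict(f, data)
    tibble::tibble(model_id = id, label = sp$label,
                   apparent_mse = mse(y, pred),
                   apparent_r2 = r_squared(y, pred))
  }) |> dplyr::bind_rows()

  records <- vector("list", repeats * folds * length(specs))
  k <- 0L
  for (r in seq_len(repeats)) {
    foldid <- withr::with_seed(partition_seeds[r],
                               sample(rep(seq_len(folds), length.out = n)))
    for (f in seq_len(folds)) {
      test <- foldid == f
      train_data <- data[!test, , drop = FALSE]
      test_data <- data[test, , drop = FALSE]
      y_test <- y[test]
      for (s in seq_along(specs)) {
        fitted <- fit_pmd(train_data, specs[[s]],
                          seed = model_seeds[r, f, s])
        pred <- predict(fitted, test_data)
        fold_r2 <- if (var_n(y_test) > 0) r_squared(y_test, pred) else NA_real_
        k <- k + 1L
        records[[k]] <- tibble::tibble(
          rep = r, fold = f, model_id = ids[s], n_test = sum(test),
          mse = mse(y_test, pred), r2 = fold_r2)
      }
    }
  }
  records <- dplyr::bind_rows(records)

  cv <- records |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(
      cv_mse = mean(.data$mse),
      cv_r2 = if (aggregation == "fold") mean(.data$r2) else
        1 - sum(.data$mse * .data$n_test) / sum(.data$n_test) / var_n(y),
      .groups = "drop")

  summary <- apparent |>
    dplyr::left_join(cv, by = "model_id") |>
    dplyr::arrange(match(.data$model_id, ids)) |>
    dplyr::mutate(final = .data$cv_mse == min(.data$cv_mse))

  structure(list(summary = summary, records = records,
                 final_model = summary$model_id[which.max(summary$final)],
                 settings = list(repeats = repeats, folds = folds,
                                 seed = seed, aggregation = aggregation,
                                 n = n)),
            class = "pmd_cv")
}

#' @exportS3Method base::print
print.pmd_cv <- function(x, ...) {
  cat(sprintf("<pmd_cv> %d x %d-fold cross-validation, n = %d\n",
              x$settings$repeats, x$settings$folds, x$settings$n))
  print(x$summary)
  invisible(x)
}

#' @describeIn repeated_cv Per-model summary table (the performance
#'   table analogue: apparent and cross-validated MSE and R-squared).
#' @param x A `pmd_cv`.
#' @param ... Unused.
#' @export
tidy.pmd_cv <- function(x, ...) x$summary

#' @describeIn repeated_cv One-row run summary with the final model.
#' @export
glance.pmd_cv <- function(x, ...) {
  tibble::tibble(final_model = x$final_model,
                 n = x$settings$n, repeats = x$settings$repeats,
                 folds = x$settings$folds,
                 aggregation = x$settings$aggregation)
}

#' Per-bin Spearman correlation with PMD
#'
#' Rank correlation (average ranks for ties) between each of the 15
#' retained gray-level bins and the PMD outcome. Because the bin-index
#' orientation (white-first vs black-first) is a labelling convention,
#' the profile reports both: `bin` counts from white (1) to black (16),
#' `bin_dark` the reverse.
#'
#' @param data Feature tibble with at least 3 rows.
#' @return Object of class `pmd_spearman`: tibble with `bin`, `bin_dark`,
#'   `glv_min`, `glv_max`, `rho`. A constant bin yields `NA` with a
#'   warning rather than a silent drop.
#' @export
spearman_profile <- function(data) {
  fx <- check_features(data, min_n = 3L)
  rho <- vapply(seq_len(15L), function(b) {
    xb <- fx$x[, b]
    if (var(xb) == 0) {
      warning(sprintf("bin %d is constant: Spearman correlation undefined", b),
              call. = FALSE)
      return(NA_real_)
    }
    cor(xb, fx$y, method = "spearman")
  }, numeric(1))
  out <- tibble::tibble(bin = 1:15, bin_dark = 17L - (1:15),
                        glv_min = 256L - 16L * (1:15),
                        glv_max = 271L - 16L * (1:15),
                        rho = rho)
  class(out) <- c("pmd_spearman", class(out))
  out
}

#' Single train/validation hold-out illustration
#'
#' Randomly assigns two thirds of the patients to a training set, fits
#' the chosen model there, and predicts the remaining third — the
#' predicted-versus-observed scatter conventionally shown for the final
#' model.
#'
#' @param data Feature tibble with at least 30 rows.
#' @param spec A [pmd_model_spec()]; typically the final model.
#' @param seed Integer seed for the split and the model fit.
#' @param train_frac Training fraction (default 2/3).
#' @return Object of class `pmd_holdout`: list with `table` (tibble of
#'   `patient_id`, `observed`, `predicted` on the validation set),
#'   `r_squared`, `model_id` and `seed`.
#' @export
holdout_illustration <- function(data, spec, seed = 1L, train_frac = 2 / 3) {
  fx <- check_features(data, min_n = 30L)
  n <- nrow(data)
  seeds <- derive_seeds(seed, 2L)
  train_idx <- withr::with_seed(seeds[1],
                                sample.int(n, size = round(train_frac * n)))
  train_data <- data[train_idx, , drop = FALSE]
  valid_data <- data[-train_idx, , drop = FALSE]
  fit <- fit_pmd(train_data, spec, seed = seeds[2])
  pred <- predict(fit, valid_data)
  obs <- fx$y[-train_idx]
  out <- list(table = tibble::tibble(
                patient_id = if ("patient_id" %in% names(valid_data))
                  valid_data$patient_id else as.character(seq_along(obs)),
                observed = obs, predicted = pred),
              r_squared = r_squared(obs, pred),
              model_id = spec$model_id, seed = seed)
  class(out) <- "pmd_holdout"
  out
}

#' @exportS3Method base::print
print.pmd_holdout <- function(x, ...) {
  cat(sprintf("<pmd_holdout> %s on %d validation patients: R^2 = %.3f\n",
              x$model_id, nrow(x$table), x$r_squared))
  invisible(x)
}
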