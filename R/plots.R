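#' Histogram of the cohort PMD distribution
#'
#' @param data Tibble with a `pmd_observed` column (feature table or
#'   truth table), fraction scale.
#' @param binwidth Histogram bin width on the percent scale.
#' @return A ggplot.
#' @export
plot_pmd_distribution <- function(data, binwidth = 5) {
  abort_if(!"pmd_observed" %in% names(data),
           "data must contain `pmd_observed`", "echodens_value_error")
  ggplot2::ggplot(data, ggplot2::aes(x = 100 * .data$pmd_observed)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(x = "Percent mammographic density (PMD, %)",
                  y = "Patients") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pmd_spearman <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$bin), y = .data$rho)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Gray level bin (1 = white ... 16 = black)",
                  y = "Spearman's rho with PMD") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pmd_holdout <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = 100 * .data$observed,
                               y = 100 * .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Observed PMD (%)", y = "Predicted PMD (%)",
                  title = sprintf("%s hold-out validation (R² = %.2f)",
                                  object$model_id, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pmd_cv <- function(object, ...) {
  long <- object$summary |>
    dplyr::select("model_id", "apparent_r2", "cv_r2") |>
    tidyr::pivot_longer(c("apparent_r2", "cv_r2"),
                        names_to = "measure", values_to = "r2") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
                                          apparent_r2 = "apparent",
                                          cv_r2 = "cross-validated"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model_id, y = .data$r2,
                                     colour = .data$measure,
                                     group = .data$measure)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = NULL, y = expression(R^2), colour = NULL) +
    ggplot2::theme_minimal()
}
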