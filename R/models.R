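#' Specification of one density-prediction model
#'
#' The suite benchmarks eight model classes of increasing flexibility on
#' the 15 gray-level-bin predictors:
#'
#' * `M0` intercept-only null model (training-mean prediction),
#' * `M1` ordinary least squares on all 15 bins,
#' * `M2` = M1 with stepwise backward elimination by AIC,
#' * `M3` OLS with each bin expanded as a natural cubic spline with 2
#'   degrees of freedom (interior knot at the training median, boundary
#'   knots at the training range),
#' * `M4` = M3 with backward elimination of whole spline term groups by
#'   AIC,
#' * `M5` lasso, penalty chosen by inner 10-fold cross-validation
#'   (minimum-MSE rule) on standardized predictors,
#' * `M6` ridge regression, tuned like M5,
#' * `M7` random forest (500 trees, 5 candidate predictors per split,
#'   minimum node size 5).
#'
#' A prediction-free `constant` spec (always predicts `value`) is
#' available as a diagnostic reference for the evaluation harness; it is
#' not part of the benchmark suite.
#'
#' @param model_id One of `"M0"`..`"M7"` or `"constant"`.
#' @param ... Hyperparameter overrides: `spline_df` (M3/M4), `nlambda`,
#'   `lambda_min_ratio`, `nfolds`, `lambda` (explicit penalty grid;
#'   a single value skips the inner CV) for M5/M6, `num_trees`, `mtry`,
#'   `min_node` for M7, `value` for the constant spec.
#' @return Object of class `pmd_model_spec`.
#' @export
#' @examples
#' pmd_model_spec("M5", nlambda = 50)
pmd_model_spec <- function(model_id, ...) {
  ids <- c(paste0("M", 0:7), "constant")
  abort_if(!model_id %in% ids,
           paste0("`model_id` must be one of ", paste(ids, collapse = ", ")),
           "echodens_value_error")
  labels <- c(M0 = "Null model", M1 = "Linear regression",
              M2 = "Linear regression with variable selection",
              M3 = "Cubic splines",
              M4 = "Cubic splines with variable selection",
              M5 = "Lasso", M6 = "Ridge regression", M7 = "Random forest",
              constant = "Constant (diagnostic)")
  defaults <- switch(model_id,
    M2 = , M4 = list(k_aic = 2),
    M3 = list(spline_df = 2L),
    M5 = list(alpha = 1, nlambda = 100L, lambda_min_ratio = 1e-6,
              nfolds = 10L, lambda = NULL),
    M6 = list(alpha = 0, nlambda = 100L, lambda_min_ratio = 1e-6,
              nfolds = 10L, lambda = NULL),
    M7 = list(num_trees = 500L, mtry = 5L, min_node = 5L),
    constant = list(value = 0.5),
    list()
  )
  if (model_id == "M4") defaults$spline_df <- 2L
  params <- utils::modifyList(defaults, list(...))
  structure(list(model_id = model_id, label = unname(labels[model_id]),
                 params = params),
            class = "pmd_model_spec")
}

#' The M0-M7 benchmark suite
#'
#' @param ids Character vector of model ids.
#' @return Named list of [pmd_model_spec()] objects.
#' @export
pmd_model_suite <- function(ids = paste0("M", 0:7)) {
  setNames(lapply(ids, pmd_model_spec), ids)
}

#' @exportS3Method base::print
print.pmd_model_spec <- function(x, ...) {
  cat(sprintf("<pmd_model_spec> %s: %s\n", x$model_id, x$label))
  invisible(x)
}

# validate a feature data frame and return list(x = matrix, y or NULL)
check_features <- function(data, require_outcome = TRUE, min_n = 1L) {
  cols <- bin_cols(15L)
  abort_if(!all(cols %in% names(data)),
           "data must contain predictor columns bin_01..bin_15",
           "echodens_value_error")
  x <- as.matrix(data[cols])
  abort_if(anyNA(x), "predictors contain missing values",
           "echodens_value_error")
  abort_if(nrow(x) < min_n,
           sprintf("at least %d observations required, got %d", min_n, nrow(x)),
           "echodens_value_error")
  y <- NULL
  if (require_outcome) {
    abort_if(!"pmd_observed" %in% names(data),
             "data must contain the outcome column `pmd_observed`",
             "echodens_value_error")
    y <- data$pmd_observed
    abort_if(anyNA(y) || any(y < 0 | y > 1),
             "`pmd_observed` must lie in [0, 1] with no missing values",
             "echodens_value_error")
  }
  list(x = x, y = y)
}

# Backward elimination by AIC, dropping whole terms (for spline fits a
# term is the complete 2-column basis of one bin). A saturated or
# degenerate design can make AIC -Inf, in which case selection is
# impossible and the full (pivoted) fit is kept with a warning.
backward_step <- function(full, k = 2, data) {
  # step() re-evaluates each candidate fit in its caller's frame, so the
  # training data must be bound there under the name the lm call used
  env <- list2env(list(df = data), parent = parent.frame())
  step_call <- as.call(list(stats::step, full, direction = "backward",
                            trace = 0, k = k))
  tryCatch(eval(step_call, env),
           error = function(e) {
             warning(paste0("stepwise selection failed (",
                            conditionMessage(e), "); keeping the full model"),
                     call. = FALSE)
             full
           })
}

# predict.lm warns on every call for pivoted (rank-deficient) fits; the
# fallback is deliberate, so that specific warning is muffled.
predict_lm_quiet <- function(fit, nd) {
  withCallingHandlers(
    as.numeric(predict(fit, newdata = nd)),
    warning = function(w) {
      if (grepl("rank-deficient", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
}

# Closed-form ridge on glmnet-standardized predictors (population-sd
# scaling), solved by pseudo-inverse so rank deficiency cannot break it.
ridge_exact <- function(x, y, lambda) {
  n <- nrow(x)
  mu <- colMeans(x)
  s <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
  s[s == 0] <- 1
  z <- scale(x, center = mu, scale = s)
  m <- crossprod(z) / n + diag(lambda, ncol(x))
  rhs <- crossprod(z, y - mean(y)) / n
  sv <- svd(m)
  pos <- sv$d > max(sv$d) * 1e-12
  a <- sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], rhs) / sv$d[pos])
  beta <- drop(a) / s
  c("(Intercept)" = mean(y) - sum(beta * mu), beta)
}

# spline terms: ns() with df = 2 puts the interior knot at the training
# median and boundary knots at the training range; R's safe-prediction
# machinery carries these training knots to new data. Constant training
# columns cannot support a spline basis and fall back to a linear term.
spline_formula <- function(df, data) {
  terms <- vapply(bin_cols(15L), function(cl) {
    if (diff(range(data[[cl]])) == 0) {
      warning(sprintf("predictor %s is constant on training data; %s",
                      cl, "using a linear term instead of a spline basis"),
              call. = FALSE)
      cl
    } else {
      sprintf("splines::ns(%s, df = %d)", cl, df)
    }
  }, character(1))
  stats::reformulate(terms, response = "pmd_observed")
}

#' Fit one density-prediction model
#'
#' Fits the model described by `spec` on a training feature table. Every
#' data-dependent choice — stepwise selection, penalty tuning, spline
#' knot placement, forest growth — uses the training rows only, so the
#' fitted object can be evaluated on held-out data without leakage.
#'
#' @param data Feature tibble with `bin_01`..`bin_15` and `pmd_observed`
#'   in `[0, 1]`; at least 20 rows.
#' @param spec A [pmd_model_spec()].
#' @param seed Integer seed driving the model's own randomness (inner CV
#'   folds for M5/M6, forest bootstrap for M7). Deterministic refits
#'   require the same seed.
#' @return Object of class `pmd_fit` supporting [predict()], [tidy()]
#'   and [glance()].
#' @export
#' @examples
#' feats <- simulate_linear_features(80, oracle_r2 = 0.5, seed = 1)
#' fit <- fit_pmd(feats, pmd_model_spec("M1"))
#' glance(fit)
fit_pmd <- function(data, spec, seed = 1L) {
  stopifnot(inherits(spec, "pmd_model_spec"))
  fx <- check_features(data, min_n = if (spec$model_id == "constant") 1L else 20L)
  x <- fx$x
  y <- fx$y
  df <- tibble::as_tibble(as.data.frame(x))
  df$pmd_observed <- y
  p <- spec$params
  n <- nrow(x)

  fit <- switch(spec$model_id,
    M0 = list(mean = mean(y)),
    constant = list(value = p$value),
    M1 = stats::lm(stats::reformulate(bin_cols(15L), "pmd_observed"),
                   data = df),
    M2 = {
      full <- stats::lm(stats::reformulate(bin_cols(15L), "pmd_observed"),
                        data = df)
      backward_step(full, k = p$k_aic, data = df)
    },
    M3 = stats::lm(spline_formula(p$spline_df, df), data = df),
    M4 = {
      full <- stats::lm(spline_formula(p$spline_df, df), data = df)
      backward_step(full, k = p$k_aic, data = df)
    },
    M5 = ,
    M6 = {
      if (!is.null(p$lambda) && length(p$lambda) == 1L && p$alpha == 0) {
        # explicit single-penalty ridge has a closed form; solving it
        # directly is exact where coordinate descent only approximates
        # (in particular ridge(0) = OLS to machine precision)
        list(ridge_coef = ridge_exact(x, y, p$lambda), lambda = p$lambda)
      } else if (!is.null(p$lambda) && length(p$lambda) == 1L) {
        g <- glmnet::glmnet(x, y, alpha = p$alpha, lambda = p$lambda,
                            standardize = TRUE, thresh = 1e-14)
        list(glmnet = g, lambda = p$lambda)
      } else {
        foldid <- withr::with_seed(seed,
          sample(rep(seq_len(p$nfolds), length.out = n)))
        cvfit <- glmnet::cv.glmnet(
          x, y, alpha = p$alpha, foldid = foldid,
          nlambda = p$nlambda, lambda.min.ratio = p$lambda_min_ratio,
          lambda = p$lambda, type.measure = "mse", standardize = TRUE)
        list(glmnet = cvfit$glmnet.fit, lambda = cvfit$lambda.min)
      }
    },
    M7 = withr::with_seed(seed,
      randomForest::randomForest(x, y, ntree = p$num_trees, mtry = p$mtry,
                                 nodesize = p$min_node))
  )

  if (inherits(fit, "lm") && fit$rank < length(coef(fit))) {
    warning(sprintf(paste0("%s: rank-deficient design (%d aliased terms); ",
                           "using the pivoted least-squares fallback"),
                    spec$model_id, sum(is.na(coef(fit)))),
            call. = FALSE)
  }

  out <- structure(list(model_id = spec$model_id, label = spec$label,
                        spec = spec, fit = fit, n_train = n,
                        train_mean = mean(y)),
                   class = "pmd_fit")
  out$train_mse <- mse(y, predict(out, data))
  out$train_r2 <- r_squared(y, predict(out, data))
  out
}

#' Predict percent mammographic density from a fitted model
#'
#' @param object A `pmd_fit`.
#' @param new_data Feature table with `bin_01`..`bin_15`. Spline bases
#'   and penalty standardization reuse training-derived parameters.
#' @param clip Clip predictions to `[0, 1]`? Off by default; apparent
#'   and cross-validated errors are conventionally computed on raw model
#'   output.
#' @param ... Unused.
#' @return Numeric vector, one prediction per row.
#' @export
predict.pmd_fit <- function(object, new_data, clip = FALSE, ...) {
  fx <- check_features(new_data, require_outcome = FALSE)
  x <- fx$x
  pred <- switch(object$model_id,
    M0 = rep(object$fit$mean, nrow(x)),
    constant = rep(object$fit$value, nrow(x)),
    M1 = , M2 = , M3 = , M4 = predict_lm_quiet(object$fit, as.data.frame(x)),
    M5 = , M6 = if (!is.null(object$fit$ridge_coef)) {
      drop(cbind(1, x) %*% object$fit$ridge_coef)
    } else {
      as.numeric(predict(object$fit$glmnet, newx = x,
                         s = object$fit$lambda))
    },
    M7 = as.numeric(predict(object$fit, x))
  )
  if (clip) pred <- clamp01(pred)
  pred
}

#' @exportS3Method base::print
print.pmd_fit <- function(x, ...) {
  cat(sprintf("<pmd_fit> %s: %s (n = %d, training R^2 = %.3f)\n",
              x$model_id, x$label, x$n_train, x$train_r2))
  invisible(x)
}

#' Tidy a fitted density model
#'
#' Returns the per-term view appropriate to the family: coefficients for
#' the linear, spline and penalized models, the stored mean for the null
#' model, and variable importance (increase in node purity) for the
#' random forest.
#'
#' @param x A `pmd_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` (plus `std.error`,
#'   `statistic`, `p.value` for OLS-type fits, `importance` for M7).
#' @export
tidy.pmd_fit <- function(x, ...) {
  switch(x$model_id,
    M0 = tibble::tibble(term = "(Intercept)", estimate = x$fit$mean),
    constant = tibble::tibble(term = "(Constant)", estimate = x$fit$value),
    M1 = , M2 = , M3 = , M4 = {
      cs <- coef(summary(x$fit))
      tibble::tibble(term = rownames(cs), estimate = cs[, 1],
                     std.error = cs[, 2], statistic = cs[, 3],
                     p.value = cs[, 4])
    },
    M5 = , M6 = {
      if (!is.null(x$fit$ridge_coef)) {
        tibble::tibble(term = names(x$fit$ridge_coef),
                       estimate = unname(x$fit$ridge_coef))
      } else {
        b <- as.matrix(coef(x$fit$glmnet, s = x$fit$lambda))
        tibble::tibble(term = rownames(b), estimate = b[, 1])
      }
    },
    M7 = {
      imp <- randomForest::importance(x$fit)
      tibble::tibble(term = rownames(imp), importance = imp[, 1])
    }
  )
}

#' One-row summary of a fitted density model
#'
#' @param x A `pmd_fit`.
#' @param ... Unused.
#' @return Tibble with model id, label, training size, number of retained
#'   terms, chosen penalty (penalized fits) and apparent (training) MSE
#'   and R-squared.
#' @export
glance.pmd_fit <- function(x, ...) {
  n_terms <- switch(x$model_id,
    M0 = , constant = 0L,
    M1 = , M2 = , M3 = , M4 = length(attr(stats::terms(x$fit), "term.labels")),
    M5 = , M6 = if (!is.null(x$fit$ridge_coef))
      sum(x$fit$ridge_coef[-1] != 0)
    else sum(as.matrix(coef(x$fit$glmnet, s = x$fit$lambda))[-1, 1] != 0),
    M7 = 15L
  )
  tibble::tibble(model_id = x$model_id, label = x$label, n_train = x$n_train,
                 n_terms = n_terms,
                 lambda = if (x$model_id %in% c("M5", "M6"))
                   x$fit$lambda else NA_real_,
                 train_mse = x$train_mse, train_r2 = x$train_r2)
}

#' Natural cubic spline basis with training-derived knots
#'
#' Expands one predictor column into a 2-degree-of-freedom natural
#' (restricted) cubic spline basis: one interior knot at the median of
#' the reference (training) values, boundary knots at their range. When
#' applied to validation data, pass the training column as `ref` so the
#' basis is evaluated with training knots. A constant reference column
#' cannot support a spline; the column itself plus a zero column is
#' returned with a warning.
#'
#' @param x Numeric vector to expand.
#' @param df Degrees of freedom (only 2 supported).
#' @param ref Reference values supplying the knots; defaults to `x`.
#' @return Numeric matrix with `df` columns.
#' @export
spline_basis <- function(x, df = 2L, ref = x) {
  abort_if(df != 2L, "only df = 2 is supported", "echodens_value_error")
  rng <- range(ref)
  if (diff(rng) == 0) {
    warning("constant reference column: returning the column plus a zero column",
            call. = FALSE)
    return(cbind(x, 0))
  }
  unclass(splines::ns(x, knots = median(ref), Boundary.knots = rng))
}
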