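test_that("the null model predicts the training mean everywhere", {
  fe <- random_features(40, seed = 2)
  f0 <- fit_pmd(fe, pmd_model_spec("M0"))
  expect_equal(predict(f0, fe), rep(mean(fe$pmd_observed), 40))
  new <- random_features(25, seed = 3)
  expect_equal(predict(f0, new), rep(mean(fe$pmd_observed), 25))
  expect_equal(f0$train_r2, 0)
})

test_that("ridge at zero penalty reproduces ordinary least squares", {
  fe <- random_features(120, seed = 4)
  ols <- fit_pmd(fe, pmd_model_spec("M1"))
  ridge0 <- fit_pmd(fe, pmd_model_spec("M6", lambda = 0))
  expect_equal(predict(ridge0, fe), predict(ols, fe), tolerance = 1e-8)
})

test_that("lasso at an extreme penalty collapses to the null model", {
  fe <- random_features(80, seed = 5)
  l <- fit_pmd(fe, pmd_model_spec("M5", lambda = 1e9))
  f0 <- fit_pmd(fe, pmd_model_spec("M0"))
  expect_equal(predict(l, fe), predict(f0, fe), tolerance = 1e-10)
  expect_true(all(tidy(l)$estimate[-1] == 0))
})

test_that("nested least-squares families order their training errors", {
  for (s in 1:5) {
    fe <- simulate_linear_features(90, oracle_r2 = 0.4, seed = s)
    m0 <- fit_pmd(fe, pmd_model_spec("M0"))$train_mse
    m1 <- fit_pmd(fe, pmd_model_spec("M1"))$train_mse
    m3 <- fit_pmd(fe, pmd_model_spec("M3"))$train_mse
    expect_lte(m1, m0)
    expect_lte(m3, m1 + 1e-12)
  }
})

test_that("backward selection retains a strongly informative bin", {
  beta <- c(0, 0, 1, rep(0, 12))  # all signal in bin_03
  kept <- vapply(1:50, function(s) {
    fe <- simulate_linear_features(500, oracle_r2 = 0.6, seed = 1000 + s,
                                   beta = beta)
    f2 <- fit_pmd(fe, pmd_model_spec("M2"))
    "bin_03" %in% attr(stats::terms(f2$fit), "term.labels")
  }, logical(1))
  expect_gte(mean(kept), 0.95)
})

test_that("OLS residuals are orthogonal to every predictor on training data", {
  fe <- random_features(100, seed = 6)
  f1 <- fit_pmd(fe, pmd_model_spec("M1"))
  res <- fe$pmd_observed - predict(f1, fe)
  x <- as.matrix(fe[sprintf("bin_%02d", 1:15)])
  expect_true(all(abs(crossprod(x, res)) < 1e-6))
})

test_that("model fits depend only on training rows and refit deterministically", {
  fe <- random_features(90, seed = 7)
  train <- fe[1:60, ]
  probe <- random_features(10, seed = 8)
  for (id in c("M2", "M5", "M7")) {
    a <- fit_pmd(train, pmd_model_spec(id), seed = 123)
    b <- fit_pmd(train, pmd_model_spec(id), seed = 123)
    expect_identical(predict(a, probe), predict(b, probe))
    # a second predict from the same fitted state is identical too
    expect_identical(predict(a, probe), predict(a, probe))
  }
})

test_that("the spline basis nests linear functions and is continuous at its knot", {
  withr::with_seed(11, {
    x <- runif(200, 0, 40)
    y <- 2 * x
    b <- spline_basis(x)
    fitted <- lm.fit(cbind(1, b), y)$fitted.values
    expect_equal(fitted, y, tolerance = 1e-8)

    # centered basis columns are orthogonal to the intercept
    expect_equal(colSums(scale(b, scale = FALSE)), c(0, 0), tolerance = 1e-9,
                 ignore_attr = TRUE)

    # continuity at the interior (median) knot
    k <- median(x)
    eps <- 1e-9
    lo <- spline_basis(c(k - eps, k, k + eps), ref = x)
    expect_lt(max(abs(lo[1, ] - lo[2, ])), 1e-7)
    expect_lt(max(abs(lo[3, ] - lo[2, ])), 1e-7)
  })
  expect_warning(spline_basis(rep(2, 30)), "constant")
})

test_that("spline models reuse training knots on validation data", {
  fe <- simulate_linear_features(120, oracle_r2 = 0.7, seed = 12)
  f3 <- fit_pmd(fe[1:80, ], pmd_model_spec("M3"))
  # prediction must work on data outside the training range without error
  shifted <- fe[81:120, ]
  shifted[sprintf("bin_%02d", 1:15)] <- shifted[sprintf("bin_%02d", 1:15)] * 1.2
  expect_length(predict(f3, shifted), 40)
  # in-sample prediction equals lm's fitted values (knots consistent)
  expect_equal(predict(f3, fe[1:80, ]), unname(fitted(f3$fit)),
               tolerance = 1e-10)
})

test_that("tidy and glance expose the fitted state of every family", {
  fe <- simulate_linear_features(60, oracle_r2 = 0.4, seed = 13)
  for (id in paste0("M", 0:7)) {
    f <- fit_pmd(fe, pmd_model_spec(id), seed = 99)
    td <- tidy(f)
    expect_s3_class(td, "tbl_df")
    expect_gt(nrow(td), 0)
    gl <- glance(f)
    expect_equal(nrow(gl), 1)
    expect_equal(gl$model_id, id)
    expect_true(is.finite(gl$train_mse))
  }
  g5 <- glance(fit_pmd(fe, pmd_model_spec("M5"), seed = 1))
  expect_true(is.finite(g5$lambda))
})

test_that("prediction clipping restricts raw model output to the unit interval", {
  fe <- random_features(50, seed = 14)
  fe$pmd_observed <- pmin(pmax(fe$pmd_observed * 0.02, 0), 1)  # outcomes near zero
  f1 <- fit_pmd(fe, pmd_model_spec("M1"))
  raw <- predict(f1, fe)
  clipped <- predict(f1, fe, clip = TRUE)
  expect_true(all(clipped >= 0 & clipped <= 1))
  expect_equal(clipped, pmin(pmax(raw, 0), 1))
})

test_that("fit preconditions are enforced", {
  fe <- random_features(10, seed = 15)
  expect_error(fit_pmd(fe, pmd_model_spec("M1")),
               class = "echodens_value_error")
  fe2 <- random_features(30, seed = 16)
  fe2$pmd_observed[3] <- 1.7
  expect_error(fit_pmd(fe2, pmd_model_spec("M1")),
               class = "echodens_value_error")
  f <- fit_pmd(random_features(30, seed = 17), pmd_model_spec("M1"))
  expect_error(predict(f, random_features(5, seed = 1)[, -3]),
               class = "echodens_value_error")
})
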