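test_that("mse and r_squared match their definitions", {
  expect_equal(mse(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(mse(c(0, 1), c(1, 0)), 1)
  withr::with_seed(1, {
    a <- runif(1000); b <- runif(1000)
    naive <- sum((a - b)^2) / 1000
    expect_equal(mse(a, b), naive, tolerance = 1e-12)
  })
  expect_error(mse(1:3, 1:4), class = "echodens_value_error")

  y <- c(0.1, 0.5, 0.9)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  # anti-correlated prediction: 1 - 1.0 / 0.25 = -3
  expect_equal(r_squared(c(0, 0, 1, 1), c(1, 1, 0, 0)), -3)
  expect_error(r_squared(c(0.3, 0.3), c(0.1, 0.2)),
               class = "echodens_metric_error")
})

test_that("cross-validation partitions are valid and reproducible", {
  fe <- random_features(50, seed = 20)
  cv <- repeated_cv(fe, pmd_model_suite("M0"), repeats = 4, seed = 31)
  rec <- cv$records
  # every observation held out exactly once per repeat; fold sizes within 1
  sizes <- tapply(rec$n_test, rec$rep, function(s) s)
  for (r in 1:4) {
    ns <- rec$n_test[rec$rep == r]
    expect_equal(sum(ns), 50)
    expect_lte(diff(range(ns)), 1)
  }
  expect_equal(nrow(rec), 4 * 3)
  cv2 <- repeated_cv(fe, pmd_model_suite("M0"), repeats = 4, seed = 31)
  expect_identical(cv$summary, cv2$summary)
  expect_error(repeated_cv(fe, pmd_model_suite("M0"), folds = 40),
               class = "echodens_config_error")
})

test_that("the null model's apparent R-squared is exactly zero but degrades under CV", {
  for (s in 1:50) {
    fe <- random_features(33, seed = 300 + s)
    cv <- repeated_cv(fe, pmd_model_suite("M0"), repeats = 1, seed = s)
    expect_identical(cv$summary$apparent_r2, 0)
    expect_lte(cv$summary$cv_r2, 0)
  }
})

test_that("a prediction-free constant model shows no apparent-vs-CV gap", {
  fe <- random_features(60, seed = 21)  # 60 divisible by 3: equal folds
  cv <- repeated_cv(fe, list(pmd_model_spec("constant", value = 0.5)),
                    repeats = 5, seed = 9)
  expect_equal(cv$summary$cv_mse, cv$summary$apparent_mse, tolerance = 1e-12)
})

test_that("cross-validated R-squared recovers a known generative signal", {
  vals <- vapply(1:10, function(s) {
    fe <- simulate_linear_features(500, oracle_r2 = 0.5, seed = 2000 + s)
    cv <- repeated_cv(fe, pmd_model_suite("M1"), repeats = 20, seed = s)
    cv$summary$cv_r2
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.5), 0.1)
})

test_that("lower cv MSE implies higher cv R-squared across models", {
  fe <- simulate_linear_features(90, oracle_r2 = 0.4, seed = 22)
  cv_pooled <- repeated_cv(fe, pmd_model_suite(c("M0", "M1", "M5", "M6")),
                           repeats = 3, seed = 4, aggregation = "pooled")
  s <- cv_pooled$summary
  expect_equal(order(s$cv_mse), order(-s$cv_r2))
  # equal folds (90 divisible by 3) make the pooled relation exact
  v <- mean((fe$pmd_observed - mean(fe$pmd_observed))^2)
  expect_equal(s$cv_r2, 1 - s$cv_mse / v, tolerance = 1e-12)

  cv_fold <- repeated_cv(fe, pmd_model_suite(c("M0", "M1", "M5", "M6")),
                         repeats = 3, seed = 4, aggregation = "fold")
  sf <- cv_fold$summary
  expect_equal(order(sf$cv_mse), order(-sf$cv_r2))
})

test_that("permuting outcome labels destroys every model's cross-validated signal", {
  fe <- simulate_linear_features(60, oracle_r2 = 0.5, seed = 23)
  specs <- pmd_model_suite()
  means <- matrix(NA_real_, 50, length(specs))
  withr::with_seed(77, {
    for (p in 1:50) {
      perm <- fe
      perm$pmd_observed <- sample(fe$pmd_observed)
      cv <- suppressWarnings(
        repeated_cv(perm, specs, repeats = 1, seed = 5000 + p))
      means[p, ] <- cv$summary$cv_r2
    }
  })
  expect_true(all(colMeans(means) <= 0.05))
})

test_that("the Spearman profile matches a rank-transform oracle and flags constant bins", {
  fe <- random_features(50, seed = 24)
  sp <- spearman_profile(fe)
  expect_equal(nrow(sp), 15)
  expect_true(all(abs(sp$rho) <= 1))
  expect_equal(sp$bin_dark, 16:2)
  x <- as.matrix(fe[sprintf("bin_%02d", 1:15)])
  oracle <- apply(x, 2, function(col)
    cor(rank(col), rank(fe$pmd_observed), method = "pearson"))
  expect_equal(sp$rho, unname(oracle), tolerance = 1e-10)

  # monotone bins give perfect rank correlation
  mono <- fe
  mono$bin_01 <- sort(runif(50))
  mono$bin_02 <- -sort(runif(50))
  mono$pmd_observed <- sort(runif(50))
  sp <- spearman_profile(mono)
  expect_equal(sp$rho[1], 1)
  expect_equal(sp$rho[2], -1)

  const <- fe
  const$bin_05 <- 3
  expect_warning(spc <- spearman_profile(const), "constant")
  expect_true(is.na(spc$rho[5]))
})

test_that("the hold-out illustration is seed-deterministic and recovers noiseless truth", {
  fe <- simulate_linear_features(60, oracle_r2 = 1, seed = 25,
                                 outcome_mean = 0.5, outcome_var = 0.008)
  h1 <- holdout_illustration(fe, pmd_model_spec("M1"), seed = 3)
  h2 <- holdout_illustration(fe, pmd_model_spec("M1"), seed = 3)
  expect_identical(h1$table, h2$table)
  expect_equal(h1$r_squared, 1, tolerance = 1e-6)
  expect_equal(nrow(h1$table), 20)
})

test_that("hold-out R-squared tracks a moderate generative signal on average", {
  vals <- vapply(1:20, function(s) {
    fe <- simulate_linear_features(504, oracle_r2 = 0.3, seed = 4000 + s)
    holdout_illustration(fe, pmd_model_spec("M1"), seed = s)$r_squared
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.3), 0.15)
})

test_that("result objects plot without error", {
  fe <- simulate_linear_features(60, oracle_r2 = 0.4, seed = 26)
  cv <- repeated_cv(fe, pmd_model_suite(c("M0", "M1")), repeats = 2, seed = 1)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(spearman_profile(fe)), "ggplot")
  expect_s3_class(autoplot(holdout_illustration(fe, pmd_model_spec("M1"))),
                  "ggplot")
  expect_s3_class(plot_pmd_distribution(fe), "ggplot")
})
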