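test_that("Beta prior is moment-matched to the configured PMD moments", {
  # frozen from the moment-matching formulas nu = mu(1-mu)/var - 1,
  # a = mu*nu, b = (1-mu)*nu
  sh <- beta_shapes(0.422, 0.0396)
  expect_equal(unname(sh), c(2.177307, 2.982188), tolerance = 1e-6)

  withr::with_seed(42, {
    d <- sample_pmd(1e5)
    expect_lt(abs(mean(d) - 0.422), 0.01)
    expect_lt(abs(mean((d - mean(d))^2) - 0.0396), 0.004)
  })

  expect_identical(sample_pmd(0), numeric(0))
  expect_error(generator_config(pmd_mean = 0.5, pmd_var = 0.3),
               class = "echodens_config_error")
  expect_error(beta_shapes(0.422, 0.25), class = "echodens_config_error")
})

test_that("reader simulation is unbiased away from the boundaries and truncated at them", {
  withr::with_seed(1, {
    r <- simulate_readers(rep(0.5, 1e5), reader_sd = 0.03)
    expect_lt(abs(mean(r$pmd_observed) - 0.5), 0.002)
    expect_equal(r$pmd_observed, (r$reader_1 + r$reader_2) / 2)

    r0 <- simulate_readers(rep(0, 1e4), reader_sd = 0.03)
    expect_true(all(r0$pmd_observed >= 0))
  })
  rz <- simulate_readers(c(0.1, 0.9), reader_sd = 0)
  expect_equal(rz$pmd_observed, c(0.1, 0.9))
})

test_that("image generation is deterministic and density-monotone in mean gray", {
  cfg <- small_cohort_config(signal_strength = 1, view_jitter_sd = 0)
  im1 <- withr::with_seed(7, generate_image(0.4, cfg, 10, 100))
  im2 <- withr::with_seed(7, generate_image(0.4, cfg, 10, 100))
  expect_identical(im1$image, im2$image)
  expect_identical(im1$mask, im2$mask)

  hits <- vapply(1:20, function(s) {
    hi <- withr::with_seed(s, generate_image(0.9, cfg, 10, 100))
    lo <- withr::with_seed(s, generate_image(0.1, cfg, 10, 100))
    mean(hi$image[hi$mask]) > mean(lo$image[lo$mask])
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("image layout: skin band, ROI band, muscle band, exact mask rows", {
  cfg <- small_cohort_config(speckle_shape = 1e6)
  im <- withr::with_seed(3, generate_image(0.5, cfg, skin_row = 15,
                                           muscle_row = 100))
  # negligible speckle: bands sit at their tissue means
  expect_lt(abs(mean(im$image[1:15, ]) - cfg$skin_gray), 2)
  expect_lt(abs(mean(im$image[100:120, ]) - cfg$muscle_gray), 2)
  roi_rows <- which(apply(im$mask, 1, any))
  expect_identical(roi_rows, 16:99)
  expect_true(all(im$mask[roi_rows, ]))

  expect_error(generate_image(0.5, cfg, 60, 61),
               class = "echodens_config_error")
})

test_that("vanishing speckle concentrates pixels at their tissue means", {
  cfg <- small_cohort_config(speckle_shape = 1e6, signal_strength = 1,
                             view_jitter_sd = 0)
  all_fibro <- withr::with_seed(5, generate_image(1, cfg, 10, 100))
  all_fat <- withr::with_seed(5, generate_image(0, cfg, 10, 100))
  expect_lt(sd(all_fibro$image[all_fibro$mask]), 2)
  expect_lt(sd(all_fat$image[all_fat$mask]), 2)
  expect_lt(abs(mean(all_fibro$image[all_fibro$mask]) - cfg$fibro_gray), 2)
  expect_lt(abs(mean(all_fat$image[all_fat$mask]) - cfg$fat_gray), 2)
})

test_that("signal knob: bright fraction tracks density at 1 and decouples at 0", {
  n <- 1000
  for (s in c(0, 1)) {
    cfg <- generator_config(n_patients = n, image_height = 80,
                            image_width = 80, signal_strength = s,
                            blob_scale = 4, seed = 100 + s)
    ch <- generate_cohort(cfg)
    per_view <- merge(ch$views, ch$truth[c("patient_id", "latent_density")])
    r <- cor(per_view$bright_fraction, per_view$latent_density)
    if (s == 0) expect_lt(abs(r), 0.05) else expect_gt(r, 0.9)
  }
})

test_that("cohort generation is reproducible and correctly sized", {
  cfg <- small_cohort_config(n_patients = 6, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth$pmd_observed, b$truth$pmd_observed)
  expect_identical(a$images[[1]]$image, b$images[[1]]$image)

  expect_equal(nrow(a$manifest), 30)
  expect_equal(nrow(a$truth), 6)
  expect_true(all(a$views$skin_row < a$views$muscle_row))
  expect_equal(a$truth$pmd_observed,
               (a$truth$reader_1 + a$truth$reader_2) / 2)

  empty <- generate_cohort(small_cohort_config(n_patients = 0))
  expect_equal(nrow(empty$manifest), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("every generated ROI mask is a contiguous full-width band excluding the boundary rows", {
  cfg <- small_cohort_config(n_patients = 3, seed = 21)
  ch <- generate_cohort(cfg)
  for (k in seq_along(ch$images)) {
    mask <- ch$images[[k]]$mask
    rows <- which(apply(mask, 1, any))
    expect_identical(rows, min(rows):max(rows))
    expect_true(all(mask[rows, ]))
    v <- ch$views[k, ]
    expect_identical(rows, (v$skin_row + 1L):(v$muscle_row - 1L))
  }
})

test_that("on-disk cohorts round-trip through PNG and the manifest CSV", {
  out <- withr::local_tempdir()
  cfg <- small_cohort_config(n_patients = 4, seed = 13)
  ch_mem <- generate_cohort(cfg)
  ch_disk <- generate_cohort(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_equal(nrow(ch_disk$manifest), 20)
  expect_true(all(file.exists(ch_disk$manifest$image)))

  img <- read_gray_image(ch_disk$manifest$image[1])
  expect_identical(img, ch_mem$images[[1]]$image)

  fe_disk <- cohort_features(file.path(out, "manifest.csv"))
  fe_mem <- cohort_features(ch_mem)
  expect_equal(fe_disk, fe_mem)
})

test_that("linear feature cohorts hit their oracle R-squared by construction", {
  fe <- simulate_linear_features(5000, oracle_r2 = 0.5, seed = 3)
  x <- as.matrix(fe[sprintf("bin_%02d", 1:15)])
  f <- lm.fit(cbind(1, x), fe$pmd_observed)
  r2 <- 1 - mean(f$residuals^2) / mean((fe$pmd_observed - mean(fe$pmd_observed))^2)
  expect_lt(abs(r2 - 0.5), 0.05)
  expect_equal(attr(fe, "oracle_r2"), 0.5)
  expect_true(all(rowSums(fe[sprintf("bin_%02d", 1:16)]) - 100 < 1e-9))
})
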