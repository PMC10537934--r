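#' Configuration for the synthetic ultrasound cohort generator
#'
#' Bundles and validates every knob of the synthetic-cohort generator:
#' cohort size, image geometry, the latent-density prior, reader noise,
#' the strength of the texture--density association, speckle, and the mean
#' gray levels of the four simulated tissue classes.
#'
#' The latent percent mammographic density (PMD) of each patient is drawn
#' from a Beta distribution moment-matched to `pmd_mean` and `pmd_var`
#' (fraction scale). The defaults reproduce a screening-age PMD
#' distribution with mean 42.2% and variance 0.0396, which is also the
#' training mean squared error of the intercept-only null model on such a
#' cohort.
#'
#' @param n_patients Number of patients (five images each). Default 168.
#' @param image_height,image_width Image size in pixels. Default 400x400.
#' @param pmd_mean,pmd_var Mean and variance of the latent density on the
#'   fraction scale. Must satisfy `pmd_var < pmd_mean * (1 - pmd_mean)`.
#' @param reader_sd Standard deviation of each simulated reader's additive
#'   Gaussian error (fraction scale, truncated to `[0, 1]`).
#' @param signal_strength Real in `[0, 1]`. 1 means the bright-tissue
#'   fraction of each view is fully determined by the latent density, 0
#'   means no association (fraction centred at 0.5 regardless of density).
#'   The default 0.12, together with `view_jitter_sd`, emulates the weak
#'   coupling between echotexture and mammographic density seen in vivo,
#'   where even the best prediction model explains only a modest share of
#'   the PMD variance out of sample.
#' @param speckle_shape Gamma shape of the multiplicative unit-mean
#'   speckle; larger values mean less speckle (variance `1/shape`).
#' @param fibro_gray,fat_gray,skin_gray,muscle_gray Mean gray levels
#'   (0-255) of fibroglandular tissue, fat, the skin band and the muscle
#'   band. Fibroglandular tissue is echogenic (bright), fat hypoechoic.
#' @param blob_scale Spatial correlation length, in pixels, of the
#'   two-tissue texture field.
#' @param view_jitter_sd Standard deviation of the small per-view
#'   perturbation of the bright-tissue probability (recorded in the truth
#'   table), representing genuine compositional heterogeneity between the
#'   five views of one breast.
#' @param seed Integer seed; all generator output is a pure function of
#'   the configuration including this seed.
#'
#' @return A validated list of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_patients = 4, image_height = 120, image_width = 120)
#' cohort <- generate_cohort(cfg)
#' cohort$truth
generator_config <- function(n_patients = 168L,
                             image_height = 400L,
                             image_width = 400L,
                             pmd_mean = 0.422,
                             pmd_var = 0.0396,
                             reader_sd = 0.03,
                             signal_strength = 0.12,
                             speckle_shape = 4,
                             fibro_gray = 170,
                             fat_gray = 70,
                             skin_gray = 220,
                             muscle_gray = 40,
                             blob_scale = 8,
                             view_jitter_sd = 0.08,
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    pmd_mean = pmd_mean, pmd_var = pmd_var,
    reader_sd = reader_sd, signal_strength = signal_strength,
    speckle_shape = speckle_shape,
    fibro_gray = fibro_gray, fat_gray = fat_gray,
    skin_gray = skin_gray, muscle_gray = muscle_gray,
    blob_scale = blob_scale, view_jitter_sd = view_jitter_sd,
    seed = as.integer(seed)
  )
  abort_if(cfg$n_patients < 0, "`n_patients` must be >= 0",
           "echodens_config_error")
  abort_if(!(pmd_mean > 0 && pmd_mean < 1),
           "`pmd_mean` must lie strictly in (0, 1)", "echodens_config_error")
  abort_if(pmd_var <= 0 || pmd_var >= pmd_mean * (1 - pmd_mean),
           paste0("invalid Beta moments: `pmd_var` must satisfy ",
                  "0 < pmd_var < pmd_mean * (1 - pmd_mean) = ",
                  signif(pmd_mean * (1 - pmd_mean), 4)),
           "echodens_config_error")
  abort_if(reader_sd < 0, "`reader_sd` must be >= 0", "echodens_config_error")
  abort_if(signal_strength < 0 || signal_strength > 1,
           "`signal_strength` must lie in [0, 1]", "echodens_config_error")
  abort_if(speckle_shape <= 0, "`speckle_shape` must be > 0",
           "echodens_config_error")
  grays <- c(fibro_gray, fat_gray, skin_gray, muscle_gray)
  abort_if(any(grays < 0 | grays > 255),
           "tissue gray means must lie in [0, 255]", "echodens_config_error")
  abort_if(blob_scale <= 0, "`blob_scale` must be > 0", "echodens_config_error")
  abort_if(view_jitter_sd < 0, "`view_jitter_sd` must be >= 0",
           "echodens_config_error")
  structure(cfg, class = "generator_config")
}

#' Moment-matched Beta shape parameters
#'
#' Converts a (mean, variance) pair on `(0, 1)` into the shape parameters
#' of the Beta distribution with those moments:
#' `nu = mean * (1 - mean) / var - 1`, `shape1 = mean * nu`,
#' `shape2 = (1 - mean) * nu`.
#'
#' @param mean,var Target mean and variance; `var` must be positive and
#'   smaller than `mean * (1 - mean)`.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @export
#' @examples
#' beta_shapes(0.422, 0.0396)
beta_shapes <- function(mean, var) {
  abort_if(!(mean > 0 && mean < 1), "`mean` must lie in (0, 1)",
           "echodens_config_error")
  abort_if(var <= 0 || var >= mean * (1 - mean),
           "`var` must satisfy 0 < var < mean * (1 - mean)",
           "echodens_config_error")
  nu <- mean * (1 - mean) / var - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Draw latent percent mammographic densities
#'
#' Samples latent densities from the Beta prior moment-matched to
#' `(pmd_mean, pmd_var)`. Uses the current RNG state, so wrap in
#' [withr::with_seed()] (or call `set.seed()`) for reproducibility.
#'
#' @param n Number of draws (>= 0).
#' @param pmd_mean,pmd_var Prior moments on the fraction scale.
#' @return Numeric vector of length `n` in `(0, 1)`.
#' @export
sample_pmd <- function(n, pmd_mean = 0.422, pmd_var = 0.0396) {
  abort_if(n < 0, "`n` must be >= 0", "echodens_config_error")
  if (n == 0) return(numeric(0))
  sh <- beta_shapes(pmd_mean, pmd_var)
  rbeta(n, sh[["shape1"]], sh[["shape2"]])
}

#' Simulate two readers scoring percent mammographic density
#'
#' Each reader observes the latent density plus independent Gaussian error
#' truncated to `[0, 1]`; the recorded PMD outcome is the mean of the two
#' reader values, mirroring the two-observer averaging used in
#' computer-assisted threshold density assessment.
#'
#' @param density Vector of latent densities in `[0, 1]`.
#' @param reader_sd Reader error standard deviation (>= 0).
#' @return Tibble with columns `reader_1`, `reader_2`, `pmd_observed`.
#' @export
simulate_readers <- function(density, reader_sd = 0.03) {
  abort_if(any(density < 0 | density > 1),
           "`density` values must lie in [0, 1]", "echodens_config_error")
  abort_if(reader_sd < 0, "`reader_sd` must be >= 0", "echodens_config_error")
  n <- length(density)
  r1 <- clamp01(density + rnorm(n, 0, reader_sd))
  r2 <- clamp01(density + rnorm(n, 0, reader_sd))
  tibble::tibble(reader_1 = r1, reader_2 = r2, pmd_observed = (r1 + r2) / 2)
}

# Spatially correlated Gaussian field: coarse white noise on a grid with
# spacing `blob_scale`, bilinearly interpolated up to h x w.
correlated_field <- function(h, w, blob_scale) {
  gh <- as.integer(ceiling((h - 1) / blob_scale)) + 2L
  gw <- as.integer(ceiling((w - 1) / blob_scale)) + 2L
  g <- matrix(rnorm(gh * gw), gh, gw)
  ty <- (seq_len(h) - 1) / blob_scale + 1
  tx <- (seq_len(w) - 1) / blob_scale + 1
  i0 <- pmin(floor(ty), gh - 1L)
  j0 <- pmin(floor(tx), gw - 1L)
  fy <- matrix(ty - i0, h, w)
  fx <- matrix(tx - j0, h, w, byrow = TRUE)
  (1 - fy) * ((1 - fx) * g[i0, j0] + fx * g[i0, j0 + 1]) +
    fy * ((1 - fx) * g[i0 + 1, j0] + fx * g[i0 + 1, j0 + 1])
}

#' Generate one synthetic B-mode ultrasound view
#'
#' Renders an 8-bit grayscale image with a bright skin band (rows
#' `1..skin_row`), a dark muscle band (rows `muscle_row..height`), and a
#' two-tissue breast field in between: a spatially correlated binary
#' texture assigns each region-of-interest pixel the fibroglandular mean
#' gray with fraction `p` or the fat mean gray otherwise, where
#' `p = signal_strength * density + (1 - signal_strength) * 0.5 +
#' view_jitter`. Every pixel is multiplied by gamma speckle with unit
#' mean, rounded and clipped to `[0, 255]`. The ROI mask marks exactly
#' the rows strictly between the skin and muscle bands. The bright
#' fraction is realized by thresholding the correlated field at its
#' `1 - p` quantile, so the recorded fraction matches `p` exactly up to
#' pixel granularity.
#'
#' Uses the current RNG state; identical state yields a byte-identical
#' image.
#'
#' @param density Latent density in `[0, 1]` for this view.
#' @param config A [generator_config()].
#' @param skin_row Last row (1-based) of the skin band.
#' @param muscle_row First row (1-based) of the muscle band; must leave at
#'   least one row strictly between the bands.
#' @param view_jitter Additive perturbation of the bright-tissue
#'   probability for this view.
#' @return List with `image` (integer matrix, 0-255), `mask` (logical
#'   matrix, the ROI band), `bright_fraction` (realized fraction of
#'   fibroglandular pixels in the ROI) and `p` (the target probability).
#' @export
generate_image <- function(density, config, skin_row, muscle_row,
                           view_jitter = 0) {
  h <- config$image_height
  w <- config$image_width
  abort_if(!(skin_row >= 1 && muscle_row <= h && skin_row + 1 < muscle_row),
           paste0("image too small to hold skin, tissue and muscle bands: ",
                  "need 1 <= skin_row, skin_row + 1 < muscle_row <= height"),
           "echodens_config_error")
  abort_if(density < 0 || density > 1, "`density` must lie in [0, 1]",
           "echodens_config_error")
  p <- clamp01(config$signal_strength * density +
                 (1 - config$signal_strength) * 0.5 + view_jitter)
  roi_rows <- (skin_row + 1L):(muscle_row - 1L)
  field <- correlated_field(h, w, config$blob_scale)[roi_rows, , drop = FALSE]
  thr <- quantile(field, probs = 1 - p, names = FALSE)
  bright <- field >= thr
  if (p == 0) bright[] <- FALSE
  mean_gray <- matrix(config$muscle_gray, h, w)
  mean_gray[seq_len(skin_row), ] <- config$skin_gray
  mean_gray[roi_rows, ] <- ifelse(bright, config$fibro_gray, config$fat_gray)
  s <- config$speckle_shape
  speckle <- matrix(rgamma(h * w, shape = s, rate = s), h, w)
  img <- matrix(as.integer(pmin(pmax(round(mean_gray * speckle), 0), 255)),
                h, w)
  mask <- matrix(FALSE, h, w)
  mask[roi_rows, ] <- TRUE
  list(image = img, mask = mask,
       bright_fraction = mean(bright), p = p)
}

#' Generate a full synthetic cohort
#'
#' Draws latent densities from the Beta prior, simulates the two-reader
#' PMD outcome, and renders five speckled ultrasound-like views per
#' patient with known skin/muscle band positions. Fully reproducible from
#' `config$seed`.
#'
#' With `out_dir` set, images and ROI masks are written as 8-bit
#' grayscale PNGs together with `manifest.csv` (columns
#' `patient_id,view,image,mask,pmd_observed`, one row per image); without
#' it the pixel data stay in memory, which is considerably faster for
#' simulation studies.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory for images, masks and the manifest.
#' @return Object of class `us_cohort`: a list with `manifest` (tibble,
#'   one row per image), `truth` (tibble, one row per patient: latent
#'   density, both reader values, observed PMD), `views` (tibble, one row
#'   per image: band rows, target probability, realized bright fraction),
#'   `images` (named list of `list(image, mask)` when in memory, else
#'   `NULL`) and the `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  to_disk <- !is.null(out_dir)
  if (to_disk) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    abort_if(!dir.exists(out_dir),
             paste0("cannot create output directory: ", out_dir),
             "echodens_io_error")
  }

  h <- config$image_height
  empty <- tibble::tibble(patient_id = character(), view = integer(),
                          image = character(), mask = character(),
                          pmd_observed = numeric())
  if (n == 0) {
    res <- list(manifest = empty,
                truth = tibble::tibble(patient_id = character(),
                                       latent_density = numeric(),
                                       reader_1 = numeric(),
                                       reader_2 = numeric(),
                                       pmd_observed = numeric()),
                views = tibble::tibble(patient_id = character(),
                                       view = integer(), skin_row = integer(),
                                       muscle_row = integer(), p = numeric(),
                                       bright_fraction = numeric()),
                images = if (to_disk) NULL else list(),
                config = config)
    class(res) <- "us_cohort"
    if (to_disk) readr::write_csv(empty, file.path(out_dir, "manifest.csv"))
    return(res)
  }

  withr::with_seed(config$seed, {
    d <- sample_pmd(n, config$pmd_mean, config$pmd_var)
    readers <- simulate_readers(d, config$reader_sd)
    truth <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      latent_density = d
    ) |> dplyr::bind_cols(readers)

    # band geometry: skin occupies roughly the top 5-10%, muscle the
    # bottom 10-18% of each view
    skin_rows <- matrix(sample(max(1L, round(0.05 * h)):round(0.10 * h),
                               n * 5L, replace = TRUE), n, 5)
    muscle_rows <- matrix(sample(round(0.82 * h):round(0.90 * h),
                                 n * 5L, replace = TRUE), n, 5)
    jitter <- matrix(rnorm(n * 5L, 0, config$view_jitter_sd), n, 5)

    images <- if (to_disk) NULL else vector("list", n * 5L)
    views <- vector("list", n * 5L)
    manifest <- vector("list", n * 5L)
    k <- 0L
    for (i in seq_len(n)) {
      for (v in 1:5) {
        k <- k + 1L
        im <- generate_image(d[i], config, skin_rows[i, v], muscle_rows[i, v],
                             jitter[i, v])
        key <- sprintf("%s_view%d", truth$patient_id[i], v)
        if (to_disk) {
          img_path <- file.path(out_dir, paste0(key, ".png"))
          mask_path <- file.path(out_dir, paste0(key, "_mask.png"))
          write_gray_png(im$image, img_path)
          write_gray_png(ifelse(im$mask, 255L, 0L), mask_path)
        } else {
          img_path <- key
          mask_path <- key
          images[[k]] <- im[c("image", "mask")]
        }
        views[[k]] <- tibble::tibble(
          patient_id = truth$patient_id[i], view = v,
          skin_row = skin_rows[i, v], muscle_row = muscle_rows[i, v],
          p = im$p, bright_fraction = im$bright_fraction)
        manifest[[k]] <- tibble::tibble(
          patient_id = truth$patient_id[i], view = v,
          image = img_path, mask = mask_path,
          pmd_observed = truth$pmd_observed[i])
      }
    }
    views <- dplyr::bind_rows(views)
    manifest <- dplyr::bind_rows(manifest)
    if (!to_disk) names(images) <- sprintf("%s_view%d",
                                           rep(truth$patient_id, each = 5),
                                           rep(1:5, n))
    if (to_disk) readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    res <- list(manifest = manifest, truth = truth, views = views,
                images = images, config = config)
    class(res) <- "us_cohort"
    res
  })
}

#' @exportS3Method base::print
print.us_cohort <- function(x, ...) {
  cat(sprintf("<us_cohort> %d patients, %d images (%s)\n",
              nrow(x$truth), nrow(x$manifest),
              if (is.null(x$images)) "on disk" else "in memory"))
  invisible(x)
}

# 8-bit grayscale PNG writer: integer matrix 0..255 in, single channel out.
write_gray_png <- function(img, path) {
  png::writePNG(img / 255, path)
}

#' Read an 8-bit grayscale image (PNG or TIFF)
#'
#' @param path File path; `.png` read via the png package, `.tif`/`.tiff`
#'   via the tiff package. Multi-channel images are reduced to their
#'   first channel.
#' @return Integer matrix with values 0-255.
#' @export
read_gray_image <- function(path) {
  abort_if(!file.exists(path), paste0("image not found: ", path),
           "echodens_io_error")
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        rlang::abort("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    rlang::abort(paste0("unsupported image format: .", ext),
                 class = "echodens_io_error")
  )
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Simulate a feature-level cohort with a known linear signal
#'
#' Bypasses image rendering and generates the 16 gray-level-bin
#' percentages directly from a Dirichlet composition, then constructs the
#' PMD outcome as a linear function of the 15 predictor bins plus
#' Gaussian noise scaled so that the population proportion of outcome
#' variance explained by the signal equals `oracle_r2`. Because the
#' generative R-squared is known by construction, the cohort serves as an
#' oracle for recovery tests of the cross-validation harness.
#'
#' @param n_patients Number of patients.
#' @param oracle_r2 Target proportion of variance explained, in `(0, 1)`,
#'   or 0 for pure noise. 1 gives a noiseless linear outcome.
#' @param seed Integer seed.
#' @param beta Length-15 coefficient pattern applied to the standardized
#'   signal; the default loads mid-gray bins, peaking at bin 8.
#' @param outcome_mean,outcome_var Mean and variance of the generated
#'   outcome (fraction scale; values are truncated to `[0, 1]`).
#' @return Tibble with `patient_id`, `bin_01`..`bin_16`, `pmd_observed`,
#'   carrying attributes `oracle_r2` and `beta`.
#' @export
simulate_linear_features <- function(n_patients, oracle_r2, seed = 1L,
                                     beta = NULL,
                                     outcome_mean = 0.422,
                                     outcome_var = 0.0396) {
  abort_if(oracle_r2 < 0 || oracle_r2 > 1,
           "`oracle_r2` must lie in [0, 1]", "echodens_config_error")
  if (is.null(beta)) {
    beta <- c(0, 0, 0, 0.5, 1, 2, 3, 4, 3, 2, 1, 0.5, 0, 0, 0)
  }
  stopifnot(length(beta) == 15L)
  withr::with_seed(seed, {
    # Dirichlet bins via normalized gammas; alpha profile puts most mass
    # in the mid-gray bins, as speckled two-tissue texture does
    alpha <- c(1, 1.5, 2, 3, 4, 5, 6, 6, 6, 5, 4, 3, 2, 1.5, 1, 1)
    g <- matrix(rgamma(n_patients * 16L, shape = rep(alpha, each = n_patients)),
                n_patients, 16L)
    bins <- 100 * g / rowSums(g)
    colnames(bins) <- bin_cols(16L)
    signal <- as.numeric(bins[, bin_cols(15L)] %*% beta)
    signal <- (signal - mean(signal)) / sd(signal)
    y <- outcome_mean +
      sqrt(oracle_r2 * outcome_var) * signal +
      if (oracle_r2 < 1) rnorm(n_patients, 0, sqrt((1 - oracle_r2) * outcome_var))
      else 0
    out <- tibble::as_tibble(bins) |>
      dplyr::mutate(patient_id = sprintf("P%03d", seq_len(n_patients)),
                    pmd_observed = clamp01(y)) |>
      dplyr::select("patient_id", dplyr::all_of(bin_cols(16L)), "pmd_observed")
    attr(out, "oracle_r2") <- oracle_r2
    attr(out, "beta") <- beta
    out
  })
}
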