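#' Exact 256-level gray histogram of an image region
#'
#' Counts pixels at each gray level value (GLV) 0-255 inside a rectangle
#' (or the whole image). Histograms are poolable across views by
#' summation via [pool_histograms()].
#'
#' @param image Integer matrix with values 0-255.
#' @param rect Optional `roi_rect`; when supplied the image is cropped to
#'   it first.
#' @return Object of class `gray_histogram`: list with `counts` (integer
#'   vector of length 256, index `g + 1` holds the count of GLV `g`) and
#'   `total_pixels`.
#' @export
gray_histogram <- function(image, rect = NULL) {
  if (!is.null(rect)) image <- crop(image, rect)
  abort_if(length(image) == 0, "zero-area region: no pixels to count",
           "echodens_value_error")
  v <- as.integer(image)
  abort_if(anyNA(v) || any(v < 0L | v > 255L),
           "`image` must contain integer gray levels in 0..255",
           "echodens_value_error")
  counts <- tabulate(v + 1L, nbins = 256L)
  structure(list(counts = counts, total_pixels = length(v)),
            class = "gray_histogram")
}

#' @exportS3Method base::print
print.gray_histogram <- function(x, ...) {
  cat(sprintf("<gray_histogram> %d pixels, %d distinct gray levels\n",
              x$total_pixels, sum(x$counts > 0)))
  invisible(x)
}

#' Pool gray histograms by summation
#'
#' Combines the per-view measurements of one breast into a single
#' combined region of interest by element-wise summation of pixel
#' counts. Order-invariant.
#'
#' @param histograms Non-empty list of `gray_histogram` objects
#'   (typically the five views of one breast).
#' @return A single pooled `gray_histogram`.
#' @export
pool_histograms <- function(histograms) {
  abort_if(!is.list(histograms) || length(histograms) == 0,
           "`histograms` must be a non-empty list", "echodens_value_error")
  abort_if(!all(vapply(histograms, inherits, logical(1), "gray_histogram")),
           "all elements must be gray_histogram objects",
           "echodens_value_error")
  counts <- Reduce(`+`, lapply(histograms, `[[`, "counts"))
  structure(list(counts = counts, total_pixels = sum(counts)),
            class = "gray_histogram")
}

# glv -> bin lookup (white-ordered): bin b covers GLVs [256-16b, 271-16b],
# so bin 1 = 240..255 (whitest), bin 16 = 0..15 (darkest)
glv_bin_index <- function(n_bins = 16L) {
  width <- 256L %/% n_bins
  n_bins - (0:255) %/% width
}

#' Reduce a gray histogram to 16 equal gray-level bins
#'
#' Divides the full 0-255 gray spectrum into 16 equal-width categories
#' ("bins") ordered from white (bin 1, GLVs 240-255) to black (bin 16,
#' GLVs 0-15) and reports the percentage of region pixels in each. The
#' 16 percentages sum to 100 by construction, so bin 16 is redundant and
#' bins 1-15 are the model predictors.
#'
#' @param hist A `gray_histogram` with at least one pixel.
#' @return Object of class `bin_features`: tibble with `bin` (1-16,
#'   white to black), `glv_min`, `glv_max` and `pct`.
#' @export
#' @examples
#' img <- matrix(rep(0:255, each = 1), 16, 16)
#' bin_features(gray_histogram(img))  # every bin 6.25
bin_features <- function(hist) {
  abort_if(!inherits(hist, "gray_histogram"),
           "`hist` must be a gray_histogram", "echodens_value_error")
  abort_if(hist$total_pixels <= 0, "empty histogram: no pixels",
           "echodens_value_error")
  idx <- glv_bin_index()
  pct <- 100 * as.numeric(rowsum(hist$counts, idx)) / hist$total_pixels
  out <- tibble::tibble(
    bin = 1:16,
    glv_min = 256L - 16L * (1:16),
    glv_max = 271L - 16L * (1:16),
    pct = pct
  )
  class(out) <- c("bin_features", class(out))
  out
}

# wide named vector bin_01..bin_16 for feature-matrix assembly
bin_pct_row <- function(hist) {
  bf <- bin_features(hist)
  setNames(bf$pct, bin_cols(16L))
}

#' Gray-level-bin feature matrix for a cohort
#'
#' Runs the full texture-extraction protocol for every patient: for each
#' of the five views, the largest rectangle inside the ROI mask is
#' selected, its 256-level gray histogram computed, the five histograms
#' pooled by summation, and the pooled histogram reduced to the 16
#' gray-level bin percentages.
#'
#' @param x A `us_cohort` from [generate_cohort()] (in-memory or
#'   on-disk), a manifest tibble with columns
#'   `patient_id, view, image, mask, pmd_observed` holding file paths, or
#'   the path of a manifest CSV.
#' @param n_views Required number of views per patient (default 5).
#' @return Tibble with `patient_id`, `bin_01`..`bin_16`, `pmd_observed` —
#'   one row per patient; models consume `bin_01`..`bin_15`.
#' @export
cohort_features <- function(x, n_views = 5L) {
  if (inherits(x, "us_cohort")) {
    manifest <- x$manifest
    images <- x$images
  } else if (is.character(x) && length(x) == 1L) {
    manifest <- readr::read_csv(x, show_col_types = FALSE)
    # relative paths resolve against the manifest's directory
    base <- dirname(x)
    manifest$image <- ifelse(file.exists(manifest$image), manifest$image,
                             file.path(base, manifest$image))
    manifest$mask <- ifelse(file.exists(manifest$mask), manifest$mask,
                            file.path(base, manifest$mask))
    images <- NULL
  } else {
    manifest <- tibble::as_tibble(x)
    images <- NULL
  }
  need <- c("patient_id", "view", "image", "mask", "pmd_observed")
  abort_if(!all(need %in% names(manifest)),
           paste0("manifest must have columns ", paste(need, collapse = ", ")),
           "echodens_value_error")
  if (nrow(manifest) == 0) {
    return(tibble::tibble(patient_id = character()) |>
             dplyr::bind_cols(tibble::as_tibble(
               matrix(numeric(0), 0, 16, dimnames = list(NULL, bin_cols(16L))))) |>
             dplyr::mutate(pmd_observed = numeric(0)))
  }
  counts <- dplyr::count(manifest, .data$patient_id)
  abort_if(any(counts$n != n_views),
           sprintf("every patient must contribute exactly %d views", n_views),
           "echodens_value_error")

  one_view <- function(row) {
    if (!is.null(images)) {
      key <- sprintf("%s_view%d", row$patient_id, row$view)
      img <- images[[key]]$image
      mask <- images[[key]]$mask
    } else {
      img <- read_gray_image(row$image)
      mask <- read_gray_image(row$mask) > 0
    }
    gray_histogram(img, largest_rectangle(mask))
  }

  manifest |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_map(function(g, key) {
      hists <- lapply(seq_len(nrow(g)), function(i) {
        one_view(list(patient_id = key$patient_id, view = g$view[i],
                      image = g$image[i], mask = g$mask[i]))
      })
      pooled <- pool_histograms(hists)
      tibble::tibble(patient_id = key$patient_id,
                     !!!bin_pct_row(pooled),
                     pmd_observed = g$pmd_observed[1])
    }) |>
    dplyr::bind_rows()
}

#' Write / read a cohort feature table as CSV
#'
#' The on-disk analogue of the device's histogram export: one row per
#' patient with `patient_id`, `bin_01`..`bin_16`, `pmd_observed`.
#'
#' @param features Feature tibble from [cohort_features()].
#' @param path CSV path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   the tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(patient_id = readr::col_character()))
}
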