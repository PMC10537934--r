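#' Build the between-skin-and-muscle ROI band mask
#'
#' The region of interest of a breast ultrasound view is the tissue
#' strictly between the skin line and the pectoral muscle. Rows are
#' 1-based: `skin_row` is the last skin row (0 for no skin band) and
#' `muscle_row` the first muscle row (`nrow + 1` for no muscle band);
#' the mask is true exactly for the rows strictly between them, across
#' all columns.
#'
#' @param nrow,ncol Image dimensions in pixels.
#' @param skin_row Last skin row, in `0..nrow - 1`.
#' @param muscle_row First muscle row, in `skin_row + 1 .. nrow + 1`.
#' @return Logical matrix of dimension `nrow x ncol`.
#' @export
#' @examples
#' band_mask(10, 10, skin_row = 3, muscle_row = 8)  # rows 4..7 true
band_mask <- function(nrow, ncol, skin_row, muscle_row) {
  abort_if(!(skin_row >= 0 && skin_row < muscle_row && muscle_row <= nrow + 1),
           "need 0 <= skin_row < muscle_row <= nrow + 1",
           "echodens_value_error")
  mask <- matrix(FALSE, nrow, ncol)
  if (muscle_row - skin_row > 1) {
    mask[(skin_row + 1):(muscle_row - 1), ] <- TRUE
  }
  mask
}

#' Largest axis-aligned rectangle of true pixels in a binary mask
#'
#' Finds the biggest rectangular space that fits entirely inside the true
#' region of a mask, using the row-stacked histogram method in
#' `O(rows * cols)`. Area ties are broken deterministically: smallest top
#' row, then smallest left column, then largest height. Arbitrary masks
#' are supported, not only horizontal bands.
#'
#' Coordinates are 1-based and inclusive: the rectangle covers rows
#' `top_row .. top_row + height - 1` and columns
#' `left_col .. left_col + width - 1`.
#'
#' @param mask Logical (or 0/1 numeric) matrix; must contain at least one
#'   true pixel.
#' @return Object of class `roi_rect`: a one-row tibble with `top_row`,
#'   `left_col`, `height`, `width`, `area`.
#' @export
#' @examples
#' m <- band_mask(10, 12, 2, 9)
#' largest_rectangle(m)  # the full 6 x 12 band
largest_rectangle <- function(mask) {
  abort_if(!is.matrix(mask), "`mask` must be a matrix", "echodens_value_error")
  m <- mask != 0
  abort_if(!any(m),
           "empty ROI: mask contains no true pixel (image unusable)",
           "echodens_empty_roi")
  r <- .largest_rect_cpp(m)
  out <- tibble::tibble(top_row = r[["top_row"]], left_col = r[["left_col"]],
                        height = r[["height"]], width = r[["width"]],
                        area = r[["height"]] * r[["width"]])
  class(out) <- c("roi_rect", class(out))
  out
}

#' Crop an image to a rectangle
#'
#' @param image Matrix (any numeric/integer mode).
#' @param rect An `roi_rect` (or any list/one-row data frame with
#'   `top_row`, `left_col`, `height`, `width`).
#' @return The sub-matrix; pixel values unchanged.
#' @export
crop <- function(image, rect) {
  abort_if(!is.matrix(image), "`image` must be a matrix",
           "echodens_value_error")
  top <- rect$top_row; left <- rect$left_col
  h <- rect$height; w <- rect$width
  abort_if(any(c(top, left, h, w) < 1) ||
             top + h - 1 > nrow(image) || left + w - 1 > ncol(image),
           "rectangle lies outside the image bounds", "echodens_value_error")
  image[top:(top + h - 1), left:(left + w - 1), drop = FALSE]
}

#' Serialize / deserialize a rectangle as JSON
#'
#' @param rect An `roi_rect`.
#' @param path File path.
#' @return `write_rect_json` returns `path` invisibly; `read_rect_json`
#'   returns an `roi_rect`.
#' @export
write_rect_json <- function(rect, path) {
  jsonlite::write_json(list(top = rect$top_row, left = rect$left_col,
                            height = rect$height, width = rect$width),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rect_json
#' @export
read_rect_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::tibble(top_row = as.integer(x$top),
                        left_col = as.integer(x$left),
                        height = as.integer(x$height),
                        width = as.integer(x$width),
                        area = as.integer(x$height) * as.integer(x$width))
  class(out) <- c("roi_rect", class(out))
  out
}
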