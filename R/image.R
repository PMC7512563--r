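#' Read a grayscale image
#'
#' Reads an 8-bit grayscale PNG (values rescaled to \[0, 1\] by the decoder)
#' or a headerless numeric CSV matrix. Multi-channel PNGs are converted to
#' luminance by averaging the colour channels.
#'
#' @param path file path ending in \code{.png} or \code{.csv}.
#' @return numeric matrix of intensities.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(1, 2), mean)
    a
  } else if (ext == "csv") {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img numeric matrix; values are clamped to \[0, 1\].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_gray_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Preprocess an image for the classification pipeline
#'
#' Normalizes intensities to \[0, 1\] (integer-valued 8-bit matrices are
#' divided by 255, anything else by its maximum when it exceeds 1; negatives
#' are clamped to 0) and resizes to \code{size} x \code{size} by bilinear
#' interpolation, so that a 3-level decomposition yields a 16x16
#' approximation at the default \code{size = 128}.
#'
#' @param img numeric matrix.
#' @param size target side length in pixels (default 128).
#' @return numeric matrix of dimension \code{size} x \code{size} in \[0, 1\].
#' @export
preprocess_image <- function(img, size = 128L) {
  .check_image_matrix(img, min_dim = 2L)
  img <- pmax(img, 0)
  mx <- max(img)
  if (mx > 1) img <- img / if (mx <= 255 && all(img == round(img))) 255 else mx
  if (nrow(img) != size || ncol(img) != size) {
    img <- as.matrix(EBImage::resize(img, w = size, h = size))
  }
  img
}
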