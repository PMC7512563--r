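# Orthonormal Haar analysis of the columns of a matrix.
# Symmetric (half-point) extension: an odd-length signal is padded by
# repeating its last sample, so output length is ceiling(n / 2).
# Downsampling keeps the even-indexed filter outputs, i.e. coefficients are
# computed over the non-overlapping pairs (x[2k-1], x[2k]).
.haar_analysis_cols <- function(x) {
  n <- nrow(x)
  if (n %% 2L == 1L) x <- rbind(x, x[n, , drop = FALSE])
  ev <- x[seq(1L, nrow(x), by = 2L), , drop = FALSE]
  od <- x[seq(2L, nrow(x), by = 2L), , drop = FALSE]
  s <- 1 / sqrt(2)
  list(low = (ev + od) * s, high = (ev - od) * s)
}

# Inverse of .haar_analysis_cols; `n` is the original column length.
.haar_synthesis_cols <- function(low, high, n) {
  s <- 1 / sqrt(2)
  ev <- (low + high) * s
  od <- (low - high) * s
  out <- matrix(0, nrow = 2L * nrow(low), ncol = ncol(low))
  out[seq(1L, nrow(out), by = 2L), ] <- ev
  out[seq(2L, nrow(out), by = 2L), ] <- od
  out[seq_len(n), , drop = FALSE]
}

.check_image_matrix <- function(img, min_dim = 2L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`img` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(img))) stop("image contains non-finite values", call. = FALSE)
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop(sprintf("image must be at least %dx%d", min_dim, min_dim), call. = FALSE)
  }
  invisible(img)
}

#' One-level 2D Haar wavelet decomposition
#'
#' Separable decimated analysis with the orthonormal Haar filter pair
#' (low-pass \eqn{(1/\sqrt2, 1/\sqrt2)}, high-pass \eqn{(1/\sqrt2, -1/\sqrt2)}),
#' applied to rows then columns. Boundary handling is symmetric half-point
#' extension; downsampling keeps the even-indexed outputs, so each sub-band
#' has dimensions \code{ceiling(dim(img) / 2)}.
#'
#' @param img numeric matrix (a grayscale image or a coefficient block).
#' @return A list with matrices \code{LL} (approximation), \code{HL}
#'   (horizontal detail), \code{LH} (vertical detail) and \code{HH}
#'   (diagonal detail).
#' @examples
#' b <- dwt2d_single(matrix(1:16, 4, 4))
#' dim(b$LL)
#' @export
dwt2d_single <- function(img) {
  .check_image_matrix(img, min_dim = 2L)
  # rows first: filter along each row = filter the columns of t(img)
  rowpass <- .haar_analysis_cols(t(img))
  L <- t(rowpass$low)   # row-lowpass, shape h x ceil(w/2)
  H <- t(rowpass$high)
  colL <- .haar_analysis_cols(L)
  colH <- .haar_analysis_cols(H)
  list(LL = colL$low, HL = colH$low, LH = colL$high, HH = colH$high)
}

#' Multilevel 2D Haar wavelet decomposition
#'
#' Recursively re-decomposes the LL band. The result is the sub-band pyramid
#' used for feature extraction: the deepest approximation plus three detail
#' matrices (HL, LH, HH) per level.
#'
#' @param img numeric matrix.
#' @param levels number of decomposition levels \code{J >= 1}.
#' @return An object of class \code{wavelet_pyramid}: a list with
#'   \code{levels}, \code{approximation} (the level-\code{J} LL matrix) and
#'   \code{details}, a list of length \code{J} whose j-th entry holds the
#'   level-j \code{HL}, \code{LH}, \code{HH} matrices.
#' @examples
#' p <- dwt2d_multilevel(matrix(rnorm(128^2), 128, 128), 3)
#' dim(p$approximation)  # 16 x 16
#' @export
dwt2d_multilevel <- function(img, levels) {
  .check_image_matrix(img)
  levels <- as.integer(levels)
  stopifnot(levels >= 1L)
  if (ceiling(min(dim(img)) / 2^levels) < 1L) {
    stop("too many decomposition levels for this image size", call. = FALSE)
  }
  details <- vector("list", levels)
  cur <- img
  for (j in seq_len(levels)) {
    if (min(dim(cur)) < 2L) {
      stop("too many decomposition levels for this image size", call. = FALSE)
    }
    b <- dwt2d_single(cur)
    details[[j]] <- list(HL = b$HL, LH = b$LH, HH = b$HH)
    cur <- b$LL
  }
  structure(
    list(levels = levels, approximation = cur, details = details),
    class = "wavelet_pyramid"
  )
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat(sprintf(
    "<wavelet_pyramid> %d level(s); approximation %dx%d\n",
    x$levels, nrow(x$approximation), ncol(x$approximation)
  ))
  for (j in seq_len(x$levels)) {
    d <- x$details[[j]]$HL
    cat(sprintf("  level %d details: %dx%d (HL, LH, HH)\n", j, nrow(d), ncol(d)))
  }
  invisible(x)
}

# per-level shapes implied by a target shape under ceil-halving
.pyramid_shapes <- function(target_shape, levels) {
  shapes <- vector("list", levels)
  h <- target_shape[1]; w <- target_shape[2]
  for (j in seq_len(levels)) {
    h <- ceiling(h / 2); w <- ceiling(w / 2)
    shapes[[j]] <- c(h, w)
  }
  shapes
}

.idwt2d_single <- function(LL, HL, LH, HH, target_shape) {
  h <- target_shape[1]; w <- target_shape[2]
  if (!all(dim(LL) == dim(HL)) || !all(dim(LL) == dim(LH)) ||
      !all(dim(LL) == dim(HH))) {
    stop("sub-band shapes are inconsistent", call. = FALSE)
  }
  L <- .haar_synthesis_cols(LL, LH, h)
  H <- .haar_synthesis_cols(HL, HH, h)
  t(.haar_synthesis_cols(t(L), t(H), w))
}

#' Multilevel inverse 2D Haar wavelet transform
#'
#' Reconstructs an image from a \code{wavelet_pyramid}. For dyadic input
#' sizes the orthonormal Haar bank achieves perfect reconstruction (round-trip
#' error at machine precision).
#'
#' @param pyramid a \code{wavelet_pyramid}.
#' @param target_shape integer vector \code{c(height, width)} of the original
#'   image.
#' @return numeric matrix of dimension \code{target_shape}.
#' @export
idwt2d_multilevel <- function(pyramid, target_shape) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"), length(target_shape) == 2)
  shapes <- .pyramid_shapes(target_shape, pyramid$levels)
  cur <- pyramid$approximation
  for (j in rev(seq_len(pyramid$levels))) {
    up_shape <- if (j == 1L) target_shape else shapes[[j - 1L]]
    d <- pyramid$details[[j]]
    if (!all(dim(cur) == dim(d$HH))) {
      stop("sub-band shapes are inconsistent", call. = FALSE)
    }
    cur <- .idwt2d_single(cur, d$HL, d$LH, d$HH, up_shape)
  }
  cur
}

#' Flatten a pyramid into named sub-band matrices
#'
#' Sub-bands are ordered deepest approximation first, then details level
#' 1..J as (HL, LH, HH); names are \code{LL<J>}, \code{HL<j>}, \code{LH<j>},
#' \code{HH<j>}.
#'
#' @param pyramid a \code{wavelet_pyramid}.
#' @return named list of matrices, length \code{3 * levels + 1}.
#' @export
pyramid_subbands <- function(pyramid) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  out <- list()
  out[[sprintf("LL%d", pyramid$levels)]] <- pyramid$approximation
  for (j in seq_len(pyramid$levels)) {
    d <- pyramid$details[[j]]
    out[[sprintf("HL%d", j)]] <- d$HL
    out[[sprintf("LH%d", j)]] <- d$LH
    out[[sprintf("HH%d", j)]] <- d$HH
  }
  out
}

#' Write a pyramid's sub-bands as CSV files
#'
#' Debug/inspection output: one headerless CSV per sub-band, named after
#' \code{pyramid_subbands()} naming.
#'
#' @param pyramid a \code{wavelet_pyramid}.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_pyramid_csv <- function(pyramid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sb <- pyramid_subbands(pyramid)
  paths <- character(0)
  for (nm in names(sb)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.table(sb[[nm]], p, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
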