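#' Gray-level histogram of a coefficient matrix
#'
#' Coefficients are min-max scaled onto \code{n_bins} gray levels:
#' \code{floor((v - min) / (max - min) * n_bins)}, clamped to the top bin.
#' A constant matrix puts all mass in the first bin. Probabilities are bin
#' counts over the total pixel count.
#'
#' @param x numeric matrix (or vector) of coefficients.
#' @param n_bins number of gray levels (default 256, mirroring 8-bit images).
#' @return an object of class \code{gray_histogram}: list with
#'   \code{probabilities} (length \code{n_bins}, summing to 1) and
#'   \code{n_bins}.
#' @export
coeff_histogram <- function(x, n_bins = 256L) {
  if (length(x) == 0L) stop("empty coefficient matrix", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite coefficients", call. = FALSE)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    idx <- rep.int(0L, length(v))
  } else {
    idx <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1L)
  }
  counts <- tabulate(idx + 1L, nbins = n_bins)
  new_gray_histogram(counts / length(v))
}

#' Construct a gray-level histogram from probabilities
#'
#' @param probabilities non-negative numeric vector summing to 1.
#' @return a \code{gray_histogram}.
#' @export
new_gray_histogram <- function(probabilities) {
  p <- as.numeric(probabilities)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stop("probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(probabilities = p, n_bins = length(p)),
            class = "gray_histogram")
}

.hist_probs <- function(hist) {
  if (inherits(hist, "gray_histogram")) hist$probabilities else as.numeric(hist)
}

#' Shannon entropy of a gray-level histogram
#'
#' \eqn{S = -\sum_i p_i \log(p_i)}, with empty bins contributing zero.
#'
#' @param hist a \code{gray_histogram} (or bare probability vector).
#' @param base logarithm base: 2 for bits (the display convention) or
#'   \code{exp(1)} for nats (the scale on which the Tsallis entropy reduces
#'   to Shannon as \eqn{q \to 1}).
#' @return non-negative entropy value.
#' @export
shannon_entropy <- function(hist, base = 2) {
  p <- .hist_probs(hist)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Tsallis entropy of a gray-level histogram
#'
#' The non-extensive generalization \eqn{S_q = (1 - \sum_i p_i^q)/(q - 1)},
#' in nats. Within 1e-9 of \eqn{q = 1} the natural-log Shannon entropy (its
#' algebraic limit) is returned.
#'
#' @param hist a \code{gray_histogram} (or bare probability vector).
#' @param q non-extensive parameter, \code{q > 0}.
#' @return entropy value.
#' @export
tsallis_entropy <- function(hist, q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0) {
    stop("`q` must be a positive number", call. = FALSE)
  }
  p <- .hist_probs(hist)
  if (abs(q - 1) < 1e-9) return(shannon_entropy(p, base = exp(1)))
  p <- p[p > 0]
  (1 - sum(p^q)) / (q - 1)
}

#' Pseudo-additivity residual of the Tsallis entropy
#'
#' For independent systems A and B (joint distribution the outer product of
#' the marginals) the Tsallis entropy composes as
#' \eqn{S_q(A+B) = S_q(A) + S_q(B) + (1-q) S_q(A) S_q(B)}. This function
#' returns the residual of that identity evaluated numerically; it should be
#' zero to machine precision.
#'
#' @param hist_a,hist_b \code{gray_histogram}s (or probability vectors).
#' @param q non-extensive parameter.
#' @return the (near-zero) residual.
#' @export
pseudo_additivity_gap <- function(hist_a, hist_b, q) {
  pa <- .hist_probs(hist_a)
  pb <- .hist_probs(hist_b)
  joint <- as.numeric(outer(pa, pb))
  sq_joint <- tsallis_entropy(joint, q)
  sa <- tsallis_entropy(pa, q)
  sb <- tsallis_entropy(pb, q)
  sq_joint - (sa + sb + (1 - q) * sa * sb)
}

#' Tsallis feature vector of a wavelet pyramid
#'
#' One Tsallis entropy per sub-band, computed from the sub-band's gray-level
#' histogram, in the order \code{LL_J, HL_1, LH_1, HH_1, ..., HL_J, LH_J,
#' HH_J} — a length \code{3J + 1} vector (10 features for the default
#' 3-level decomposition).
#'
#' @param pyramid a \code{wavelet_pyramid}.
#' @param q non-extensive parameter.
#' @param n_bins gray levels per sub-band histogram (default 256).
#' @return named numeric vector with attribute \code{q_used}.
#' @export
extract_features <- function(pyramid, q, n_bins = 256L) {
  sb <- pyramid_subbands(pyramid)
  v <- vapply(sb, function(m) tsallis_entropy(coeff_histogram(m, n_bins), q),
              numeric(1))
  attr(v, "q_used") <- q
  v
}
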