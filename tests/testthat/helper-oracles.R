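# Independent oracles used to cross-check the implementation.
# These deliberately use a different construction than the package code.

# Orthonormal Haar analysis matrices for even n: rows of `low` average
# adjacent pairs, rows of `high` difference them, both scaled by 1/sqrt(2).
haar_matrices <- function(n) {
  stopifnot(n %% 2 == 0)
  low <- matrix(0, n / 2, n)
  high <- matrix(0, n / 2, n)
  for (k in seq_len(n / 2)) {
    low[k, c(2 * k - 1, 2 * k)] <- 1 / sqrt(2)
    high[k, 2 * k - 1] <- 1 / sqrt(2)
    high[k, 2 * k] <- -1 / sqrt(2)
  }
  list(low = low, high = high)
}

# One 2D Haar level by explicit matrix products (rows then columns).
oracle_dwt2d <- function(x) {
  hr <- haar_matrices(ncol(x))  # row direction
  hc <- haar_matrices(nrow(x))  # column direction
  L <- x %*% t(hr$low); H <- x %*% t(hr$high)
  list(LL = hc$low %*% L, HL = hc$low %*% H,
       LH = hc$high %*% L, HH = hc$high %*% H)
}

# Brute-force counting histogram matching the documented binning rule.
oracle_histogram <- function(v, n_bins) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  counts <- rep(0, n_bins)
  for (x in v) {
    i <- if (hi == lo) 0 else min(floor((x - lo) / (hi - lo) * n_bins),
                                  n_bins - 1)
    counts[i + 1] <- counts[i + 1] + 1
  }
  counts / length(v)
}

# random probability vector
random_probs <- function(n) {
  p <- stats::runif(n)
  p / sum(p)
}

# small labeled 2-class feature dataset with controllable separation
toy_features <- function(n_per_class, p = 3, shift = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
             matrix(stats::rnorm(n_per_class * p, mean = shift), ncol = p))
  y <- rep(c(-1, 1), each = n_per_class)
  list(x = x, y = y)
}
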