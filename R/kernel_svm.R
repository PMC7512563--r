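# Soft-margin RBF-kernel SVM. The dual quadratic program is solved by
# libsvm (via e1071); the returned duals are re-expressed in this package's
# own model structure and all prediction flows through the explicit kernel
# expansion below, so the decision function, KKT diagnostics and
# serialization are fully inspectable.

#' Gaussian radial basis kernel
#'
#' \eqn{K(x, y) = \exp(-\sigma \|x - y\|^2)}. Note the convention: the width
#' parameter \eqn{\sigma} multiplies the squared Euclidean distance
#' (gamma-style), it is not a denominator.
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma kernel width multiplier, \code{sigma >= 0}.
#' @return kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, y, sigma) {
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  exp(-sigma * sum((x - y)^2))
}

# K(A, B) for row-matrices A (n x p), B (m x p)
.rbf_kernel_matrix <- function(a, b, sigma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-sigma * pmax(d2, 0))
}

.standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

.standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/")
}

#' Train a soft-margin RBF-kernel SVM
#'
#' Solves the soft-margin dual (box constraints \code{0 <= alpha_i <= C},
#' equality constraint \code{sum(alpha_i y_i) = 0}) under the
#' \code{rbf_kernel()} Gaussian kernel. Features are standardized to zero
#' mean and unit variance per column (statistics from the training data
#' only) before training, since the kernel's Euclidean distances are
#' scale-sensitive.
#'
#' @param x numeric feature matrix (rows = observations).
#' @param y labels in \{-1, +1\}; both classes must be present.
#' @param C penalty coefficient, \code{C > 0}.
#' @param sigma kernel width multiplier, \code{sigma > 0}.
#' @param standardize standardize columns first (default TRUE).
#' @return an object of class \code{ksvm_model} with fields
#'   \code{support_vectors} (standardized), \code{dual_coefs}
#'   (\eqn{\alpha_i y_i}), \code{bias}, \code{sigma}, \code{C},
#'   \code{center}, \code{scale}.
#' @export
ksvm_train <- function(x, y, C, sigma, standardize = TRUE) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite features", call. = FALSE)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)), C > 0, sigma > 0)
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  st <- if (standardize) .standardize_fit(x) else
    list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  xs <- .standardize_apply(x, st)

  fit <- e1071::svm(xs, factor(y, levels = c(-1, 1)),
                    type = "C-classification", kernel = "radial",
                    gamma = sigma, cost = C, scale = FALSE,
                    tolerance = 1e-5)
  # libsvm orients its decision values by the first training label it sees;
  # the decision-value column name "<pos>/<neg>" records that orientation.
  dv <- attr(stats::predict(fit, xs[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  pos_label <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  orient <- if (pos_label == "1") 1 else -1

  model <- structure(list(
    support_vectors = fit$SV,
    dual_coefs = orient * as.numeric(fit$coefs),
    sv_index = fit$index,
    bias = -orient * fit$rho,
    sigma = sigma, C = C,
    center = st$center, scale = st$scale,
    n_features = ncol(x)
  ), class = "ksvm_model")
  model
}

#' @export
print.ksvm_model <- function(x, ...) {
  cat(sprintf("<ksvm_model> RBF kernel (sigma = %.4g), C = %.4g, %d support vectors\n",
              x$sigma, x$C, nrow(x$support_vectors)))
  invisible(x)
}

#' Decision values and labels from a trained SVM
#'
#' Computes \eqn{g(x) = \sum_i \alpha_i y_i K(s_i, x) + b} through the
#' explicit kernel expansion over the stored support vectors. The label is
#' the sign of the decision value, with ties broken towards +1.
#'
#' @param model a \code{ksvm_model}.
#' @param x numeric matrix (or single vector) of new observations.
#' @return tibble with columns \code{.decision} and \code{.pred} (-1/+1).
#' @export
ksvm_predict <- function(model, x) {
  stopifnot(inherits(model, "ksvm_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) stop("dimension mismatch", call. = FALSE)
  xs <- .standardize_apply(x, list(center = model$center, scale = model$scale))
  K <- .rbf_kernel_matrix(xs, model$support_vectors, model$sigma)
  dec <- as.numeric(K %*% model$dual_coefs) + model$bias
  tibble::tibble(.decision = dec, .pred = ifelse(dec >= 0, 1, -1))
}

#' KKT diagnostics of a trained SVM
#'
#' Checks the optimality conditions of the soft-margin dual on its training
#' set: box constraints, the equality constraint
#' \eqn{\sum_i \alpha_i y_i = 0}, and the margin conditions
#' (\eqn{y_i g(x_i) \ge 1} for \eqn{\alpha_i = 0},
#' \eqn{y_i g(x_i) = 1} for \eqn{0 < \alpha_i < C},
#' \eqn{y_i g(x_i) \le 1} for \eqn{\alpha_i = C}).
#'
#' @param model a \code{ksvm_model}.
#' @param x,y the training features and labels.
#' @return one-row tibble with \code{max_kkt_residual},
#'   \code{equality_residual}, \code{box_violation}.
#' @export
ksvm_kkt <- function(model, x, y) {
  stopifnot(inherits(model, "ksvm_model"))
  y <- as.numeric(y)
  dec <- ksvm_predict(model, x)$.decision
  m <- y * dec
  # per-observation alpha: nonzero only on support vectors
  alpha <- numeric(length(y))
  sv_y <- sign(model$dual_coefs)
  alpha[model$sv_index] <- abs(model$dual_coefs)
  eps <- 1e-8 * model$C
  at_zero <- alpha <= eps
  at_C <- alpha >= model$C - 1e-6 * model$C
  interior <- !at_zero & !at_C
  res <- max(c(0,
               pmax(1 - m[at_zero], 0),
               abs(m[interior] - 1),
               pmax(m[at_C] - 1, 0)))
  tibble::tibble(
    max_kkt_residual = res,
    equality_residual = abs(sum(model$dual_coefs)),
    box_violation = max(c(0, -model$dual_coefs * sv_y,
                          abs(model$dual_coefs) - model$C))
  )
}

#' Confusion matrix and classification metrics
#'
#' Counts TP/FP/FN/TN with the malignant class (+1) as positive, and derives
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP) and accuracy
#' (TP+TN)/total, reported as percentages. A rate whose denominator is zero
#' is \code{NA}.
#'
#' @param y_true,y_pred label vectors over \{-1, +1\}, equal length.
#' @return one-row tibble with columns \code{TP, FP, FN, TN, sensitivity,
#'   specificity, accuracy} (rates in percent).
#' @export
confusion_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop("label vectors must be non-empty and of equal length", call. = FALSE)
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == -1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  tn <- sum(y_true == -1 & y_pred == -1)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    TP = tp, FP = fp, FN = fn, TN = tn,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    accuracy = rate(tp + tn, length(y_true))
  )
}

#' Round half-up to a fixed number of decimals
#'
#' Display rounding used in reports (97.77(7)% prints as 97.78).
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
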