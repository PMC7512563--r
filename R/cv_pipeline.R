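# End-to-end orchestration: per-image sub-band histograms are computed once
# (the wavelet transform is the expensive stage and is independent of q), so
# the GA's repeated fitness evaluations only re-evaluate the cheap Tsallis
# sum over the cached histograms.

#' Precompute per-image sub-band histograms
#'
#' Preprocesses every image (normalize + bilinear resize), runs the
#' multilevel Haar decomposition once per image, and stores each sub-band's
#' gray-level histogram. Changing the entropy parameter q afterwards never
#' re-runs the transform; the object keeps an instrumentation counter of
#' transform invocations.
#'
#' @param images list of numeric matrices, or a dataset tibble with an
#'   \code{image} list-column.
#' @param levels decomposition levels (default 3).
#' @param n_bins gray levels per histogram (default 256).
#' @param size preprocessing side length (default 128).
#' @return an object of class \code{subband_histograms}.
#' @export
prepare_images <- function(images, levels = 3L, n_bins = 256L, size = 128L) {
  if (is.data.frame(images)) images <- images$image
  stopifnot(is.list(images), length(images) >= 1L)
  counter <- new.env(parent = emptyenv())
  counter$dwt_calls <- 0L
  hists <- lapply(images, function(img) {
    img <- preprocess_image(img, size = size)
    counter$dwt_calls <- counter$dwt_calls + 1L
    pyr <- dwt2d_multilevel(img, levels)
    lapply(pyramid_subbands(pyr), function(m) {
      coeff_histogram(m, n_bins)$probabilities
    })
  })
  structure(list(histograms = hists, levels = as.integer(levels),
                 n_bins = as.integer(n_bins), size = as.integer(size),
                 counter = counter),
            class = "subband_histograms")
}

#' @export
print.subband_histograms <- function(x, ...) {
  cat(sprintf("<subband_histograms> %d images, %d levels, %d bins (%d transforms run)\n",
              length(x$histograms), x$levels, x$n_bins, x$counter$dwt_calls))
  invisible(x)
}

#' Tsallis feature matrix from cached histograms
#'
#' @param prep a \code{subband_histograms}.
#' @param q non-extensive parameter.
#' @return numeric matrix, one row per image, \code{3 * levels + 1} columns
#'   named as in \code{extract_features()}.
#' @export
feature_matrix <- function(prep, q) {
  stopifnot(inherits(prep, "subband_histograms"))
  out <- t(vapply(prep$histograms, function(h) {
    vapply(h, function(p) tsallis_entropy(p, q), numeric(1))
  }, numeric(3L * prep$levels + 1L)))
  rownames(out) <- NULL
  out
}

#' Tidy feature table for a dataset
#'
#' @param data dataset tibble with an \code{image} list-column and a
#'   \code{label} column.
#' @param q non-extensive parameter.
#' @param levels,n_bins,size forwarded to \code{prepare_images()}.
#' @return tibble with \code{label} and feature columns \code{f1..f(3J+1)}.
#' @export
extract_feature_table <- function(data, q, levels = 3L, n_bins = 256L,
                                  size = 128L) {
  fm <- feature_matrix(prepare_images(data, levels, n_bins, size), q)
  colnames(fm) <- paste0("f", seq_len(ncol(fm)))
  dplyr::bind_cols(tibble::tibble(label = data$label),
                   tibble::as_tibble(fm))
}

#' Stratified K-fold assignment
#'
#' Shuffles within each class and deals observations round-robin, so
#' per-class counts across folds differ by at most one.
#'
#' @param labels class labels.
#' @param K number of folds (default 5).
#' @param rng an \code{rng_stream}.
#' @return integer vector of fold ids in 1..K, one per observation.
#' @export
stratified_kfold <- function(labels, K = 5L, rng) {
  K <- as.integer(K)
  stopifnot(K >= 2L)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < K) {
      stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                   cl, length(idx), K), call. = FALSE)
    }
    idx <- with_rng(rng, sample(idx))
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  fold
}

#' Cross-validated classification-rate fitness
#'
#' The GA's objective: at parameters (q, C, sigma), extract Tsallis features
#' from the cached sub-band histograms, then for each fold train an RBF SVM
#' on the other K-1 folds (standardization statistics from the training
#' folds only) and score accuracy on the held-out fold. Returns the mean of
#' the K fold accuracies, a value in \[0, 1\].
#'
#' @param prep a \code{subband_histograms}.
#' @param labels labels in \{-1, +1\}.
#' @param q,C,sigma pipeline parameters.
#' @param folds fold assignment from \code{stratified_kfold()}.
#' @return mean held-out accuracy in \[0, 1\].
#' @export
cv_fitness <- function(prep, labels, q, C, sigma, folds) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(prep$histograms),
            length(folds) == length(labels))
  X <- feature_matrix(prep, q)
  accs <- vapply(sort(unique(folds)), function(k) {
    tr <- folds != k
    if (length(unique(labels[tr])) < 2L) {
      stop("a training fold contains a single class", call. = FALSE)
    }
    model <- ksvm_train(X[tr, , drop = FALSE], labels[tr], C = C, sigma = sigma)
    pred <- ksvm_predict(model, X[!tr, , drop = FALSE])$.pred
    mean(pred == labels[!tr])
  }, numeric(1))
  mean(accs)
}

#' Fit the full DNA-GA-tuned Tsallis/SVM pipeline
#'
#' Runs the DNA genetic algorithm with the stratified five-fold
#' cross-validation classification rate as fitness, jointly tuning the
#' Tsallis parameter q and the SVM hyperparameters (C, sigma), then refits a
#' final SVM on all data at the best parameters. Fold, GA and data
#' randomness flow from independent sub-streams of \code{config$seed}.
#'
#' @param data dataset tibble (\code{image} list-column + \code{label}
#'   column), e.g. from \code{make_dataset()}.
#' @param specs list of three \code{param_spec}s for (q, C, sigma); default
#'   \code{default_param_specs()}.
#' @param config a \code{ga_config}.
#' @param K folds (default 5).
#' @param levels,n_bins,size feature-extraction settings.
#' @return an object of class \code{dnaga_ksvm}: \code{best_params} (named
#'   vector q, C, sigma), \code{cv_fitness}, \code{history} tibble,
#'   \code{model} (final \code{ksvm_model} refit on all data),
#'   \code{folds}, and the feature settings.
#' @export
fit_dnaga_ksvm <- function(data, specs = default_param_specs(),
                           config = ga_config(), K = 5L,
                           levels = 3L, n_bins = 256L, size = 128L) {
  stopifnot(is.data.frame(data), all(c("image", "label") %in% names(data)))
  labels <- as.numeric(data$label)
  fold_rng <- rng_substream(config$seed, 1L)
  ga_rng <- rng_substream(config$seed, 2L)
  folds <- stratified_kfold(labels, K = K, rng = fold_rng)
  prep <- prepare_images(data, levels = levels, n_bins = n_bins, size = size)

  fitness_fn <- function(chrom) {
    p <- decode_chromosome(chrom, specs)
    cv_fitness(prep, labels, q = p[["q"]], C = p[["C"]],
               sigma = p[["sigma"]], folds = folds)
  }
  ga <- dnaga_evolve(fitness_fn, specs, config, rng = ga_rng)
  p <- ga$best_values
  X <- feature_matrix(prep, p[["q"]])
  final <- ksvm_train(X, labels, C = p[["C"]], sigma = p[["sigma"]])

  structure(list(
    best_params = p,
    cv_fitness = ga$best_fitness,
    best_chromosome = ga$best_chromosome,
    history = ga$history,
    model = final,
    folds = folds,
    levels = as.integer(levels), n_bins = as.integer(n_bins),
    size = as.integer(size),
    n_obs = length(labels),
    config = config
  ), class = "dnaga_ksvm")
}

#' @export
print.dnaga_ksvm <- function(x, ...) {
  cat("<dnaga_ksvm> DNA-GA tuned Tsallis-entropy RBF-SVM classifier\n")
  cat(sprintf("  best parameters: q = %.4f, C = %.2f, sigma = %.4f\n",
              x$best_params[["q"]], x$best_params[["C"]],
              x$best_params[["sigma"]]))
  cat(sprintf("  five-fold CV classification rate: %.4f (%d observations, %d generations)\n",
              x$cv_fitness, x$n_obs, max(x$history$generation)))
  invisible(x)
}

#' Classify new images with a fitted pipeline
#'
#' Images are preprocessed, decomposed, reduced to Tsallis features at the
#' tuned q, standardized with the stored training statistics and classified
#' by the stored SVM.
#'
#' @param result a \code{dnaga_ksvm}.
#' @param data dataset tibble with an \code{image} list-column, or a list of
#'   matrices, or a single matrix.
#' @return tibble with \code{.decision}, \code{.pred} (-1/+1) and
#'   \code{.class} ("benign"/"malignant").
#' @export
classify_images <- function(result, data) {
  stopifnot(inherits(result, "dnaga_ksvm"))
  if (is.matrix(data)) data <- list(data)
  prep <- prepare_images(data, levels = result$levels,
                         n_bins = result$n_bins, size = result$size)
  X <- feature_matrix(prep, result$best_params[["q"]])
  out <- ksvm_predict(result$model, X)
  out$.class <- ifelse(out$.pred > 0, "malignant", "benign")
  out
}

# ---- broom-style methods ----

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy the tuned parameters of a fitted pipeline
#'
#' @param x a \code{dnaga_ksvm}.
#' @param ... unused.
#' @return tibble with one row per tuned parameter (term, estimate).
#' @method tidy dnaga_ksvm
#' @export
tidy.dnaga_ksvm <- function(x, ...) {
  tibble::tibble(
    term = names(x$best_params),
    estimate = as.numeric(x$best_params)
  )
}

#' One-row summary of a fitted pipeline
#'
#' @param x a \code{dnaga_ksvm}.
#' @param ... unused.
#' @return one-row tibble: cv_fitness, q, C, sigma, n_obs, generations,
#'   n_support_vectors.
#' @method glance dnaga_ksvm
#' @export
glance.dnaga_ksvm <- function(x, ...) {
  tibble::tibble(
    cv_fitness = x$cv_fitness,
    q = x$best_params[["q"]],
    C = x$best_params[["C"]],
    sigma = x$best_params[["sigma"]],
    n_obs = x$n_obs,
    generations = max(x$history$generation),
    n_support_vectors = nrow(x$model$support_vectors)
  )
}

#' Augment a dataset with pipeline predictions
#'
#' @param x a \code{dnaga_ksvm}.
#' @param data dataset tibble with an \code{image} list-column.
#' @param ... unused.
#' @return \code{data} with \code{.decision}, \code{.pred}, \code{.class}
#'   columns appended.
#' @method augment dnaga_ksvm
#' @export
augment.dnaga_ksvm <- function(x, data, ...) {
  dplyr::bind_cols(data, classify_images(x, data))
}

#' Plot the GA fitness trajectory of a fitted pipeline
#'
#' @param object a \code{dnaga_ksvm}.
#' @param ... unused.
#' @return a ggplot: best-so-far and population-mean CV classification rate
#'   per generation.
#' @method autoplot dnaga_ksvm
#' @export
autoplot.dnaga_ksvm <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("best", "mean"),
                           names_to = "series", values_to = "fitness")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation", y = "five-fold CV classification rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a grayscale image
#'
#' @param img numeric matrix.
#' @param title optional plot title.
#' @return a ggplot raster of the image.
#' @export
plot_gray_image <- function(img, title = NULL) {
  df <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.numeric(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, NA)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
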