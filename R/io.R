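# JSON serialization of fitted pipelines, so a model trained by the CLI's
# `train` command can be reloaded by `classify` in a later session.

#' Save a fitted pipeline as JSON
#'
#' Stores the tuned parameters, the final SVM (support vectors, dual
#' coefficients, bias, kernel width, penalty, standardization statistics)
#' and the feature-extraction settings.
#'
#' @param result a \code{dnaga_ksvm}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
save_model_json <- function(result, path) {
  stopifnot(inherits(result, "dnaga_ksvm"))
  m <- result$model
  obj <- list(
    format = "dnagaksvm-model",
    best_params = as.list(result$best_params),
    cv_fitness = result$cv_fitness,
    best_chromosome = result$best_chromosome,
    levels = result$levels, n_bins = result$n_bins, size = result$size,
    n_obs = result$n_obs,
    model = list(
      support_vectors = unclass(as.matrix(m$support_vectors)),
      dual_coefs = m$dual_coefs,
      sv_index = m$sv_index,
      bias = m$bias, sigma = m$sigma, C = m$C,
      center = m$center, scale = m$scale,
      n_features = m$n_features
    ),
    history = as.data.frame(result$history)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a fitted pipeline from JSON
#'
#' @param path a file written by \code{save_model_json()}.
#' @return a \code{dnaga_ksvm} (without fold assignment or GA config).
#' @export
load_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dnagaksvm-model")) {
    stop("not a dnagaksvm model file: ", path, call. = FALSE)
  }
  m <- obj$model
  model <- structure(list(
    support_vectors = as.matrix(m$support_vectors),
    dual_coefs = as.numeric(m$dual_coefs),
    sv_index = as.integer(m$sv_index),
    bias = as.numeric(m$bias), sigma = as.numeric(m$sigma),
    C = as.numeric(m$C),
    center = as.numeric(m$center), scale = as.numeric(m$scale),
    n_features = as.integer(m$n_features)
  ), class = "ksvm_model")
  structure(list(
    best_params = unlist(obj$best_params),
    cv_fitness = as.numeric(obj$cv_fitness),
    best_chromosome = obj$best_chromosome,
    history = tibble::as_tibble(obj$history),
    model = model,
    folds = NULL,
    levels = as.integer(obj$levels), n_bins = as.integer(obj$n_bins),
    size = as.integer(obj$size),
    n_obs = as.integer(obj$n_obs),
    config = NULL
  ), class = "dnaga_ksvm")
}
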