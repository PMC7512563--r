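test_that("stratified folds balance classes to within one observation", {
  rng <- rng_stream(1)
  lab <- c(rep(1, 85), rep(-1, 5))
  f <- stratified_kfold(lab, 5, rng)
  expect_length(f, 90)
  # 85 malignant + 5 benign over 5 folds: exactly 17 + 1 per fold
  for (k in 1:5) {
    expect_equal(sum(f == k & lab == 1), 17)
    expect_equal(sum(f == k & lab == -1), 1)
  }
  # balanced 10 over 5 folds: one of each class per fold
  lab2 <- rep(c(-1, 1), 5)
  f2 <- stratified_kfold(lab2, 5, rng_stream(2))
  for (k in 1:5) expect_equal(sort(lab2[f2 == k]), c(-1, 1))
  # every observation assigned exactly once
  expect_setequal(unique(f), 1:5)
  expect_identical(stratified_kfold(lab, 5, rng_stream(9)),
                   stratified_kfold(lab, 5, rng_stream(9)))
  expect_error(stratified_kfold(c(1, 1, 1, -1), 5, rng_stream(1)), "fewer")
})

test_that("pyramids are computed once per image and never re-run when q changes", {
  ds <- make_dataset(n_benign = 3, n_malignant = 3, snr_db = 20, seed = 4,
                     size = 64)
  prep <- prepare_images(ds, size = 64)
  expect_equal(prep$counter$dwt_calls, 6)
  X1 <- feature_matrix(prep, 0.5)
  X2 <- feature_matrix(prep, 1.5)
  expect_equal(prep$counter$dwt_calls, 6)  # unchanged by feature extraction
  expect_equal(dim(X1), c(6, 10))
  expect_false(isTRUE(all.equal(X1, X2)))
})

test_that("cv_fitness is the mean of per-fold held-out accuracies", {
  ds <- make_dataset(n_benign = 10, n_malignant = 10, snr_db = 20, seed = 6,
                     size = 64)
  prep <- prepare_images(ds, size = 64)
  lab <- ds$label
  folds <- stratified_kfold(lab, 5, rng_stream(3))
  f <- cv_fitness(prep, lab, q = 0.8, C = 100, sigma = 1, folds = folds)
  expect_gte(f, 0); expect_lte(f, 1)
  # composition oracle: recompute fold-by-fold by hand
  X <- feature_matrix(prep, 0.8)
  accs <- vapply(1:5, function(k) {
    tr <- folds != k
    m <- ksvm_train(X[tr, ], lab[tr], C = 100, sigma = 1)
    mean(ksvm_predict(m, X[!tr, , drop = FALSE])$.pred == lab[!tr])
  }, numeric(1))
  expect_equal(f, mean(accs))

  # uninformative features: fitness falls to the majority-class rate
  prep0 <- prep
  prep0$histograms <- rep(prep$histograms[1], 20)
  lab0 <- c(rep(1, 15), rep(-1, 5))
  f0 <- cv_fitness(prep0, lab0, 0.8, 100, 1,
                   stratified_kfold(lab0, 5, rng_stream(1)))
  expect_equal(f0, 0.75)
})

test_that("the fitted pipeline is reproducible and classifies its own regime", {
  ds <- make_dataset(n_benign = 10, n_malignant = 10, snr_db = 20, seed = 8,
                     size = 64)
  cfg <- ga_config(pop_size = 8, max_generations = 3, seed = 5)
  fit1 <- fit_dnaga_ksvm(ds, config = cfg, size = 64)
  fit2 <- fit_dnaga_ksvm(ds, config = cfg, size = 64)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$best_params, fit2$best_params)

  # tuned parameters stay inside their intervals
  sp <- default_param_specs()
  for (i in 1:3) {
    expect_gte(fit1$best_params[[i]], sp[[i]]$lower)
    expect_lte(fit1$best_params[[i]], sp[[i]]$upper)
  }

  # clean, well-separated phantoms: the pipeline fits its training set
  pred <- classify_images(fit1, ds)
  expect_gte(mean(pred$.pred == ds$label), 0.9)
  expect_identical(pred$.class, ifelse(pred$.pred > 0, "malignant", "benign"))

  # a large high-contrast lesion phantom is called malignant
  # a fresh high-contrast lesion phantom from the generator's malignant
  # regime is called malignant
  big <- make_dataset(n_benign = 1, n_malignant = 1, snr_db = 20, seed = 99,
                      size = 64)$image[[2]]
  expect_identical(classify_images(fit1, big)$.class, "malignant")

  # degenerate input: all-zero image classifies without error
  expect_no_error(p0 <- classify_images(fit1, matrix(0, 64, 64)))
  expect_true(p0$.class %in% c("benign", "malignant"))

  # broom-style accessors
  td <- tidy(fit1)
  expect_equal(td$term, c("q", "C", "sigma"))
  gl <- glance(fit1)
  expect_equal(gl$n_obs, 20)
  expect_equal(gl$cv_fitness, fit1$cv_fitness)
  ag <- augment(fit1, ds)
  expect_true(all(c(".pred", ".decision", ".class") %in% names(ag)))
  expect_equal(nrow(ag), 20)
  plt <- autoplot(fit1)
  expect_s3_class(plt, "ggplot")

  # degenerate config: one individual, one generation
  f1 <- fit_dnaga_ksvm(ds, config = ga_config(pop_size = 1, max_generations = 1,
                                              seed = 2), size = 64)
  expect_equal(nrow(f1$history), 1)
})

test_that("models survive a JSON round trip", {
  ds <- make_dataset(n_benign = 6, n_malignant = 6, snr_db = 20, seed = 9,
                     size = 64)
  fit <- fit_dnaga_ksvm(ds, config = ga_config(pop_size = 6, max_generations = 2,
                                               seed = 3), size = 64)
  path <- withr::local_tempfile(fileext = ".json")
  save_model_json(fit, path)
  back <- load_model_json(path)
  expect_equal(back$best_params, fit$best_params)
  expect_equal(back$cv_fitness, fit$cv_fitness)
  p1 <- classify_images(fit, ds)
  p2 <- classify_images(back, ds)
  expect_equal(p1$.decision, p2$.decision, tolerance = 1e-12)
  expect_error(load_model_json(withr::local_tempfile(lines = "{}",
                                                     fileext = ".json")),
               "not a dnagaksvm")
})
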