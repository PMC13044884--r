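# Metrics, cross-validation harnesses, concentration inversion and report
# assembly.

test_that("thresholded accuracy counts strict within-t predictions", {
  expect_equal(accuracy_score(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(accuracy_score(c(0, 0, 0, 0), c(0, 0.5, 0.8, 2)), 0.5)
  # boundary: deviation exactly t is incorrect
  t <- log(2)
  expect_equal(accuracy_score(c(0, 0), c(t, -t)), 0)
  # shift invariance
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(accuracy_score(a + 3, b + 3), accuracy_score(a, b))
  expect_error(accuracy_score(1:3, 1:2))
})

test_that("mae and mse match brute force, with exclusion support", {
  got <- mae_mse(c(1, 2), c(0, 0))
  expect_equal(got$mae, 1.5)
  expect_equal(got$mse, 2.5)

  # excluding the single gross outlier gives the starred score
  got <- mae_mse(c(0.1, -0.1, 10), c(0, 0, 0), exclude = 3L)
  expect_equal(got$mae, 0.1)
  expect_equal(got$n_excluded, 1L)
  expect_error(mae_mse(1, 1, exclude = 1L), "excluded")

  set.seed(2)
  for (i in 1:5) {
    a <- rnorm(40); b <- rnorm(40)
    got <- mae_mse(a, b)
    expect_equal(got$mae, sum(abs(a - b)) / 40)
    expect_equal(got$mse, sum((a - b)^2) / 40)
    expect_lte(got$mae, sqrt(got$mse))
    expect_lte(got$mae, max(abs(a - b)))
  }
})

test_that("five-fold assignment on ten molecules is perfectly balanced", {
  folds <- graphquant:::.make_folds(1:10, cv_plan("kfold", k = 5,
                                                  split_seed = 42), 1)
  expect_equal(sort(lengths(folds)), rep(2L, 5))
  expect_setequal(unlist(folds), 1:10)
  # fixed split seed: same folds on every repeat
  expect_identical(folds, graphquant:::.make_folds(
    1:10, cv_plan("kfold", k = 5, split_seed = 42), 2))
})

test_that("LOOCV with the mean model matches the closed form", {
  set.seed(3)
  n <- 12
  y <- rnorm(n)
  data <- tibble::tibble(molecule_id = sprintf("m%02d", 1:n), target = y)
  desc <- tibble::tibble(molecule_id = data$molecule_id, f1 = rnorm(n))
  rep <- run_cv(data, baseline_config("mean"), cv_plan("loocv", n_repeats = 1),
                descriptors = desc)
  preds <- rep$predictions
  expect_equal(nrow(preds), n)
  expect_setequal(preds$molecule_id, data$molecule_id)
  loo_oracle <- (sum(y) - y) / (n - 1)
  expect_equal(preds$target_pred[match(data$molecule_id, preds$molecule_id)],
               loo_oracle)
})

test_that("held-out molecules never enter fold training inputs", {
  set.seed(4)
  n <- 10
  data <- tibble::tibble(molecule_id = sprintf("m%02d", 1:n),
                         target = rnorm(n))
  desc <- dplyr::bind_cols(data["molecule_id"],
                           tibble::as_tibble(matrix(rnorm(n * 3), n, 3,
                             dimnames = list(NULL, c("a", "b", "c")))))
  rep <- run_cv(data, baseline_config("random_forest", seed = 1),
                cv_plan("loocv", n_repeats = 1), descriptors = desc)
  folds <- rep$folds
  for (i in seq_len(nrow(folds))) {
    expect_false(any(folds$test_ids[[i]] %in% folds$train_ids[[i]]))
    # fingerprint is reproducible from the training rows alone and ignores
    # anything about the held-out molecule
    train_ids <- folds$train_ids[[i]]
    keep <- match(train_ids, data$molecule_id)
    fp <- data_fingerprint(list(
      ids = train_ids,
      X = as.matrix(desc[keep, c("a", "b", "c")]),
      targets = data$target[keep]))
    expect_identical(folds$train_fingerprint[[i]], fp)
  }
})

test_that("subset LOOCV draws the stated fraction afresh per repeat", {
  set.seed(5)
  n <- 16
  data <- tibble::tibble(molecule_id = sprintf("m%02d", 1:n),
                         target = rnorm(n))
  desc <- tibble::tibble(molecule_id = data$molecule_id, f1 = rnorm(n))
  rep <- run_cv(data, baseline_config("mean"),
                cv_plan("subset_loocv", subset_fraction = 0.5,
                        n_repeats = 3), descriptors = desc)
  per_rep <- split(rep$predictions$molecule_id, rep$predictions$run)
  expect_true(all(lengths(per_rep) == 8))
  expect_gt(length(unique(lapply(per_rep, sort))), 1)
})

test_that("concentration inversion is exact and bounded by the beta error", {
  expect_equal(estimate_concentration(log(2), 10), 5)
  expect_equal(estimate_concentration(0, 0.07), 0.07)
  expect_error(estimate_concentration(0, -1), "negative")

  # whenever |beta_hat - beta_true| <= ln 2 the estimate is within 2x
  set.seed(6)
  beta_true <- runif(200, 0, 6)
  err <- runif(200, -log(2), log(2))
  c_true <- runif(200, 0.001, 0.1)
  s_bar <- exp(beta_true) * c_true
  c_hat <- estimate_concentration(beta_true + err, s_bar)
  ratio <- c_hat / c_true
  expect_true(all(ratio >= 0.5 - 1e-12 & ratio <= 2 + 1e-12))
  # boundary cases map to exactly half / double
  expect_equal(estimate_concentration(log(2), exp(0) * 1) / 1, 0.5)
  expect_equal(estimate_concentration(-log(2), exp(0) * 1) / 1, 2)

  # zero-noise synthetic round trip recovers the spiked concentration
  spec <- synthetic_spec(n_molecules = 4, signal_noise_cv = 0,
                         beta_noise_sd = 0, outlier_fraction = 0, seed = 8)
  study <- simulate_study(spec)
  m <- study$measurements
  bt <- study$ground_truth$beta_true[match(m$molecule_id,
                                           study$ground_truth$molecule_id)]
  c_hat <- estimate_concentration(bt, m$area / m$istd_area)
  expect_equal(c_hat, m$concentration_mg_per_kg, tolerance = 1e-12)
})

test_that("report aggregation reports mean and sample deviation over runs", {
  runs <- tibble::tibble(run = 1:3, seed = 1:3,
                         mae = c(0.4, 0.5, 0.6), mse = c(0.2, 0.3, 0.4),
                         accuracy = c(0.7, 0.8, 0.9), threshold = log(2),
                         n = 10L, n_excluded = 0L)
  preds <- tibble::tibble(molecule_id = "m", run = 1L,
                          target_true = 1, target_pred = 1.1)
  rep <- build_report(runs, preds)
  s <- rep$summary
  expect_equal(s$mean[s$metric == "mae"], 0.5)
  expect_equal(s$sd[s$metric == "mae"], stats::sd(c(0.4, 0.5, 0.6)))
  # single run: deviation zero
  rep1 <- build_report(runs[1, ], preds)
  expect_equal(rep1$summary$sd, rep(0, 3))

  gl <- glance(rep)
  expect_equal(gl$mae_mean, 0.5)
  td <- tidy(rep)
  expect_true(all(c("abs_error", "within_threshold") %in% names(td)))
})

test_that("report writing produces the three artifacts", {
  runs <- tibble::tibble(run = 1L, seed = 1L, mae = 0.1, mse = 0.02,
                         accuracy = 1, threshold = log(2), n = 2L,
                         n_excluded = 0L)
  preds <- tibble::tibble(molecule_id = c("a", "b"), run = 1L,
                          target_true = c(1, 2), target_pred = c(1.1, 2))
  rep <- build_report(runs, preds)
  stem <- file.path(withr::local_tempdir(), "cv")
  paths <- write_report(rep, stem)
  expect_true(all(file.exists(paths)))
  s <- jsonlite::fromJSON(paths[["summary"]])
  expect_equal(s$mae$mean, 0.1)
  back <- readr::read_csv(paths[["predictions"]], comment = "#",
                          show_col_types = FALSE)
  expect_equal(nrow(back), 2)
})

test_that("autoplot returns ggplot objects", {
  runs <- tibble::tibble(run = 1L, seed = 1L, mae = 0.1, mse = 0.02,
                         accuracy = 1, threshold = log(2), n = 2L,
                         n_excluded = 0L)
  preds <- tibble::tibble(molecule_id = c("a", "b"), run = 1L,
                          target_true = c(1, 2), target_pred = c(1.1, 2))
  expect_s3_class(ggplot2::autoplot(build_report(runs, preds)), "ggplot")
})
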