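# Evaluation: thresholded accuracy, MAE/MSE (with the outlier-excluding
# MAE* variant), cross-validation harnesses (LOOCV, k-fold, subset LOOCV)
# with repeated-training spread, and conversion of predicted beta into a
# concentration estimate.

#' Thresholded prediction accuracy
#'
#' The fraction of molecules whose predicted value lies strictly within
#' `t` of the truth: `A = #\{m : |pred_m - true_m| < t\} / N`. With the
#' default `t = ln 2`, a correct prediction corresponds to a concentration
#' estimate between 50% and 200% of the true value. A deviation exactly
#' equal to `t` counts as incorrect.
#'
#' @param beta_hat Numeric predictions.
#' @param beta Numeric ground truth, same length.
#' @param t Positive threshold (default `log(2)`).
#' @return A number in `[0, 1]`.
#' @examples
#' accuracy_score(c(0, 0, 0, 0), c(0, 0.5, 0.8, 2))  # 0.5
#' @export
accuracy_score <- function(beta_hat, beta, t = log(2)) {
  stopifnot(length(beta_hat) == length(beta), length(beta) >= 1L, t > 0)
  mean(abs(beta_hat - beta) < t)
}

#' Mean absolute and mean squared error, with optional exclusions
#'
#' The starred variant of the MAE (reported alongside the plain score when
#' a few gross outliers dominate) is obtained by listing the indices to
#' exclude.
#'
#' @param beta_hat Numeric predictions.
#' @param beta Numeric ground truth, same length.
#' @param exclude Integer indices excluded from the averages (recorded in
#'   the output).
#' @return A one-row tibble: `mae`, `mse`, `n`, `n_excluded`.
#' @examples
#' mae_mse(c(1, 2), c(0, 0))  # mae 1.5, mse 2.5
#' @export
mae_mse <- function(beta_hat, beta, exclude = integer(0)) {
  stopifnot(length(beta_hat) == length(beta))
  keep <- setdiff(seq_along(beta), exclude)
  if (!length(keep)) stop("all entries excluded", call. = FALSE)
  err <- beta_hat[keep] - beta[keep]
  tibble::tibble(mae = mean(abs(err)), mse = mean(err^2),
                 n = length(keep), n_excluded = length(exclude))
}

#' Combined metric set
#'
#' @inheritParams accuracy_score
#' @inheritParams mae_mse
#' @return One-row tibble: `mae`, `mse`, `accuracy`, `threshold`, `n`,
#'   `n_excluded`.
#' @export
metric_set <- function(beta_hat, beta, t = log(2), exclude = integer(0)) {
  mm <- mae_mse(beta_hat, beta, exclude)
  keep <- setdiff(seq_along(beta), exclude)
  tibble::tibble(mae = mm$mae, mse = mm$mse,
                 accuracy = accuracy_score(beta_hat[keep], beta[keep], t),
                 threshold = t, n = mm$n, n_excluded = mm$n_excluded)
}

#' Cross-validation plan
#'
#' @param scheme `"loocv"`, `"kfold"` or `"subset_loocv"` (LOOCV within a
#'   random subset of the data, drawn fresh per repeat).
#' @param k Number of folds for `"kfold"` (default 5; non-stratified random
#'   splits).
#' @param subset_fraction Fraction of molecules drawn for `"subset_loocv"`.
#' @param split_seed Seed of the fold assignment (default 42).
#' @param n_repeats Number of repeated model trainings (fresh model seed per
#'   repeat; the report carries mean and standard deviation over them).
#' @return A `cv_plan` list.
#' @export
cv_plan <- function(scheme = c("kfold", "loocv", "subset_loocv"), k = 5L,
                    subset_fraction = 1.0, split_seed = 42L, n_repeats = 5L) {
  scheme <- match.arg(scheme)
  stopifnot(k >= 2L, subset_fraction > 0, subset_fraction <= 1,
            n_repeats >= 1L)
  structure(list(scheme = scheme, k = as.integer(k),
                 subset_fraction = subset_fraction,
                 split_seed = as.integer(split_seed),
                 n_repeats = as.integer(n_repeats)),
            class = "cv_plan")
}

# Fold assignment: list of test-index vectors covering a set of indices.
.make_folds <- function(idx, plan, repeat_i) {
  n <- length(idx)
  switch(plan$scheme,
    loocv = as.list(idx),
    subset_loocv = {
      m <- max(2L, round(plan$subset_fraction * n))
      sub <- withr::with_seed(plan$split_seed + repeat_i - 1L,
                              sample(idx, m))
      as.list(sub)
    },
    kfold = {
      if (n < plan$k) stop("fewer molecules than folds", call. = FALSE)
      assign <- withr::with_seed(plan$split_seed,
                                 sample(rep(seq_len(plan$k), length.out = n)))
      lapply(seq_len(plan$k), function(f) idx[assign == f])
    })
}

#' Run a cross-validated evaluation of a model specification
#'
#' Every molecule receives exactly one out-of-fold prediction per repeat,
#' made by a model that never saw it: feature standardization and (for
#' `feature_set = "main"`) descriptor selection are re-fit inside each
#' training fold. Metrics are computed on the pooled out-of-fold
#' predictions of each repeat; the report carries their mean and standard
#' deviation over `n_repeats` retrainings (model seed = config seed +
#' repeat - 1; the fold split stays fixed for k-fold).
#'
#' @param data A tibble with `molecule_id`, a `target` column, and — for a
#'   GNN spec — a `graph` list-column from [featurize_molecules()].
#' @param model_spec A [gnn_config()] or [baseline_config()].
#' @param plan A [cv_plan()].
#' @param descriptors For baseline specs: descriptor tibble (`molecule_id` +
#'   numeric columns) aligned by `molecule_id`.
#' @param target Name of the target column in `data` (default
#'   `"target"`, falling back to `"beta_true"`/`"beta"` when present).
#' @param t Accuracy threshold (default `log(2)`).
#' @param selected_features Optional global feature list for baselines
#'   (bypasses fold-wise selection; logged in the report).
#' @return An `eval_report`; see [build_report()].
#' @export
run_cv <- function(data, model_spec, plan = cv_plan(), descriptors = NULL,
                   target = NULL, t = log(2), selected_features = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(target)) {
    target <- intersect(c("target", "beta_true", "beta"), names(data))[1]
    if (is.na(target)) stop("no target column found", call. = FALSE)
  }
  y <- as.numeric(data[[target]])
  n <- nrow(data)
  is_gnn <- inherits(model_spec, "gnn_config")
  if (is_gnn && !"graph" %in% names(data)) {
    stop("GNN evaluation needs a `graph` list-column; run featurize_molecules()",
         call. = FALSE)
  }
  if (!is_gnn && !inherits(model_spec, "baseline_config")) {
    stop("model_spec must be a gnn_config or baseline_config", call. = FALSE)
  }
  if (!is_gnn) {
    if (is.null(descriptors)) stop("baseline evaluation needs `descriptors`",
                                   call. = FALSE)
    descriptors <- tibble::as_tibble(descriptors)
    descriptors <- descriptors[match(data$molecule_id,
                                     descriptors$molecule_id), , drop = FALSE]
    if (anyNA(descriptors$molecule_id)) {
      stop("descriptors missing for some molecules", call. = FALSE)
    }
  }
  min_n <- if (identical(plan$scheme, "kfold")) plan$k else 2L
  if (n < min_n) stop("too few molecules for the requested scheme", call. = FALSE)

  runs <- vector("list", plan$n_repeats)
  predictions <- list()
  fold_log <- list()
  for (r in seq_len(plan$n_repeats)) {
    folds <- .make_folds(seq_len(n), plan, r)
    covered <- sort(unique(unlist(folds)))
    pred <- rep(NA_real_, n)
    spec_r <- model_spec
    spec_r$seed <- model_spec$seed + r - 1L
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      train <- setdiff(covered, test)
      if (length(train) < 1L) stop("fold with no training molecules",
                                   call. = FALSE)
      if (is_gnn) {
        fit <- train_gnn(data$graph[train], y[train], spec_r)
        pred[test] <- predict(fit, data$graph[test])
        fp <- fit$data_fingerprint
      } else {
        fit <- fit_baseline(descriptors[train, , drop = FALSE], y[train],
                            spec_r, selected_features = selected_features)
        pred[test] <- predict(fit, descriptors[test, , drop = FALSE])
        fp <- fit$data_fingerprint
      }
      fold_log[[length(fold_log) + 1L]] <- tibble::tibble(
        run = r, fold = f,
        train_ids = list(data$molecule_id[train]),
        test_ids = list(data$molecule_id[test]),
        train_fingerprint = fp)
    }
    runs[[r]] <- dplyr::bind_cols(
      tibble::tibble(run = r, seed = spec_r$seed),
      metric_set(pred[covered], y[covered], t))
    predictions[[r]] <- tibble::tibble(
      molecule_id = data$molecule_id[covered], run = r,
      target_true = y[covered], target_pred = pred[covered])
  }
  build_report(dplyr::bind_rows(runs), dplyr::bind_rows(predictions),
               plan = plan, model_spec = model_spec,
               folds = dplyr::bind_rows(fold_log))
}

#' Invert a predicted response factor into a concentration estimate
#'
#' `c_hat = s_bar / exp(beta_hat)` (mg/kg): the ISTD-corrected signal of an
#' unknown divided by the predicted response factor. When the beta
#' prediction errs by at most `ln 2`, the estimate lies between 50% and
#' 200% of the true concentration.
#'
#' @param beta_hat Predicted beta value(s).
#' @param s_bar Non-negative ISTD-corrected signal area(s).
#' @return Concentration estimate(s), mg/kg.
#' @examples
#' estimate_concentration(log(2), 10)  # 5
#' @export
estimate_concentration <- function(beta_hat, s_bar) {
  if (any(s_bar < 0)) stop("negative ISTD-corrected signal", call. = FALSE)
  s_bar / exp(beta_hat)
}

#' Assemble an evaluation report
#'
#' @param per_run Tibble of per-repeat metric rows (`run`, `seed`, `mae`,
#'   `mse`, `accuracy`, ...).
#' @param predictions Tibble of per-molecule out-of-fold predictions.
#' @param plan,model_spec,folds Provenance carried into the report.
#' @return An `eval_report`: `summary` (metric, mean, sd over repeats),
#'   `per_run`, `predictions`, `folds`, `plan`, `model_spec`.
#' @export
build_report <- function(per_run, predictions, plan = NULL,
                         model_spec = NULL, folds = NULL) {
  per_run <- tibble::as_tibble(per_run)
  stopifnot(nrow(per_run) >= 1L)
  metrics <- intersect(c("mae", "mse", "accuracy"), names(per_run))
  summary <- dplyr::bind_rows(lapply(metrics, function(m) {
    v <- per_run[[m]]
    tibble::tibble(metric = m, mean = mean(v),
                   sd = if (length(v) > 1L) stats::sd(v) else 0)
  }))
  structure(list(summary = summary, per_run = per_run,
                 predictions = tibble::as_tibble(predictions),
                 folds = folds, plan = plan, model_spec = model_spec),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  lab <- if (inherits(x$model_spec, "gnn_config")) "GNN"
         else x$model_spec$model %||% "model"
  cat("<eval_report> ", lab,
      if (!is.null(x$plan)) paste0(", ", x$plan$scheme), ", ",
      max(x$per_run$run), " repeat(s)\n", sep = "")
  df <- as.data.frame(x$summary)
  df$mean <- signif(df$mean, 4); df$sd <- signif(df$sd, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Three artifacts next to each other: `<stem>_metrics.csv` (per-run
#' metrics), `<stem>_predictions.csv` (per-molecule predicted vs true) and
#' `<stem>_summary.json` (mean and sd per metric).
#'
#' @param report An `eval_report`.
#' @param stem Path stem for the three files.
#' @return Character vector of the paths written, invisibly.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "eval_report"))
  paths <- c(metrics = paste0(stem, "_metrics.csv"),
             predictions = paste0(stem, "_predictions.csv"),
             summary = paste0(stem, "_summary.json"))
  .write_schema_csv(report$per_run, paths[["metrics"]], "cv_metrics")
  .write_schema_csv(report$predictions, paths[["predictions"]], "predictions")
  s <- stats::setNames(
    lapply(seq_len(nrow(report$summary)), function(i)
      list(mean = report$summary$mean[i], sd = report$summary$sd[i])),
    report$summary$metric)
  jsonlite::write_json(s, paths[["summary"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
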