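# Non-graph baseline regressors on descriptor tables: multi-layer
# perceptron (in-package trainer: BLAS matrix ops, ReLU, Adam, MSE),
# decision tree (rpart) and random forest (ranger), with the fixed
# hyperparameters the package standardizes on. A "mean" dummy model is
# included as a harness diagnostic.

#' Baseline model configuration
#'
#' Defaults: MLP with hidden sizes (500, 400, 300, 200, 100), ReLU
#' activations, MSE loss, Adam, standardized inputs; decision tree with
#' maximum depth 4, minimum split 2, squared-error criterion; random forest
#' with 500 trees of maximum depth 4. Targets are never standardized
#' (beta is already log scale).
#'
#' @param model One of `"mlp"`, `"decision_tree"`, `"random_forest"`,
#'   `"mean"` (intercept-only diagnostic).
#' @param feature_set `"all"` or `"main"`; `"main"` reduces to the `k` most
#'   important descriptors by random-forest impurity
#'   ([select_main_features()]).
#' @param k Number of main features when `feature_set = "main"`.
#' @param hidden MLP hidden layer sizes.
#' @param max_iter MLP Adam iterations (full batch).
#' @param learning_rate MLP Adam learning rate.
#' @param max_depth Tree depth for decision tree / forest.
#' @param min_split Minimum node size to attempt a split (decision tree).
#' @param n_estimators Number of forest trees.
#' @param seed Integer seed.
#' @return A `baseline_config` list.
#' @export
baseline_config <- function(model = c("random_forest", "decision_tree",
                                      "mlp", "mean"),
                            feature_set = c("all", "main"), k = 11L,
                            hidden = c(500L, 400L, 300L, 200L, 100L),
                            max_iter = 2000L, learning_rate = 1e-3,
                            max_depth = 4L, min_split = 2L,
                            n_estimators = 500L, seed = 1L) {
  model <- match.arg(model)
  feature_set <- match.arg(feature_set)
  structure(list(model = model, feature_set = feature_set, k = as.integer(k),
                 hidden = as.integer(hidden), max_iter = as.integer(max_iter),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_split = as.integer(min_split),
                 n_estimators = as.integer(n_estimators),
                 seed = as.integer(seed)),
            class = "baseline_config")
}

# In-package MLP trainer: full-batch Adam on MSE with ReLU hidden layers.
.mlp_fit <- function(X, y, hidden, max_iter, lr, seed) {
  dims <- c(ncol(X), hidden, 1L)
  withr::with_seed(seed, {
    W <- lapply(seq_len(length(dims) - 1L), function(l) {
      lim <- sqrt(6 / (dims[l] + dims[l + 1]))
      matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim),
             dims[l], dims[l + 1])
    })
  })
  b <- lapply(dims[-1], function(d) numeric(d))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(X); L <- length(W)
  losses <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    A <- vector("list", L + 1L); A[[1]] <- X
    for (l in seq_len(L)) {
      Z <- A[[l]] %*% W[[l]]
      Z <- sweep(Z, 2L, b[[l]], "+")
      A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
    }
    r <- A[[L + 1]][, 1] - y
    losses[it] <- mean(r^2)
    if (!is.finite(losses[it])) {
      stop("MLP training diverged at iteration ", it, call. = FALSE)
    }
    dZ <- matrix(2 * r / n, n, 1)
    for (l in rev(seq_len(L))) {
      dW <- crossprod(A[[l]], dZ)
      db <- colSums(dZ)
      if (l > 1L) dZ <- (dZ %*% t(W[[l]])) * (A[[l]] > 0)
      t_ <- it
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * dW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * dW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * db
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * db^2
      mhW <- mW[[l]] / (1 - beta1^t_); vhW <- vW[[l]] / (1 - beta2^t_)
      mhb <- mb[[l]] / (1 - beta1^t_); vhb <- vb[[l]] / (1 - beta2^t_)
      W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  list(W = W, b = b, losses = losses)
}

.mlp_predict <- function(fit, X) {
  A <- X
  L <- length(fit$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% fit$W[[l]], 2L, fit$b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else Z
  }
  A[, 1]
}

#' Fit a baseline regressor on a descriptor table
#'
#' For the MLP, features are standardized to zero mean / unit variance using
#' the statistics of this training set only; the statistics travel with the
#' model. Tree and forest fit raw features. With `feature_set = "main"`,
#' [select_main_features()] is run on this training data (so inside each CV
#' fold when called from [run_cv()] — no leakage) unless an explicit
#' `selected_features` list is supplied.
#'
#' @param table Descriptor tibble (`molecule_id` + numeric columns).
#' @param targets Numeric targets aligned with the rows.
#' @param config A [baseline_config()].
#' @param selected_features Optional character vector overriding the
#'   fold-wise feature selection (the "one global list" mode).
#' @return A `baseline_fit` object.
#' @export
fit_baseline <- function(table, targets, config = baseline_config(),
                         selected_features = NULL) {
  stopifnot(inherits(config, "baseline_config"))
  tb <- tibble::as_tibble(table)
  feats <- setdiff(names(tb), "molecule_id")
  stopifnot(length(targets) == nrow(tb), nrow(tb) >= 1L)
  if (anyNA(tb[feats])) stop("NaN/NA features; impute first", call. = FALSE)
  if (stats::var(targets) == 0 && config$model != "mean") {
    warning("constant target vector", call. = FALSE)
  }
  if (config$feature_set == "main" && config$model != "mean") {
    if (is.null(selected_features)) {
      selected_features <- select_main_features(tb, targets, k = config$k,
                                                seed = config$seed)
    }
    feats <- selected_features
  }
  X <- as.matrix(tb[feats])

  fit <- switch(config$model,
    mean = list(mean = mean(targets)),
    mlp = {
      mu <- colMeans(X)
      sdv <- apply(X, 2L, stats::sd); sdv[sdv == 0 | !is.finite(sdv)] <- 1
      Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
      m <- .mlp_fit(Xs, as.numeric(targets), config$hidden, config$max_iter,
                    config$learning_rate, config$seed)
      c(m, list(center = mu, scale = sdv))
    },
    decision_tree = {
      df <- data.frame(.y = as.numeric(targets), X, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(
                     maxdepth = config$max_depth, minsplit = config$min_split,
                     cp = 0, xval = 0))
    },
    random_forest = ranger::ranger(
      x = as.data.frame(X), y = as.numeric(targets),
      num.trees = config$n_estimators, max.depth = config$max_depth,
      importance = "impurity", seed = config$seed, num.threads = 1L))

  structure(list(config = config, fit = fit, features = feats,
                 data_fingerprint = data_fingerprint(
                   list(ids = tb$molecule_id, X = X,
                        targets = as.numeric(targets)))),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat("<baseline_fit> ", x$config$model, " on ", length(x$features),
      " features\n", sep = "")
  invisible(x)
}

#' Predict from a fitted baseline
#'
#' @param object A `baseline_fit`.
#' @param table Descriptor tibble with (at least) the training feature
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row.
#' @export
predict.baseline_fit <- function(object, table, ...) {
  tb <- tibble::as_tibble(table)
  if (!nrow(tb)) return(numeric(0))
  if (object$config$model == "mean") {
    return(rep(object$fit$mean, nrow(tb)))
  }
  missing <- setdiff(object$features, names(tb))
  if (length(missing)) {
    stop("descriptor columns missing at prediction time: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(tb[object$features])
  switch(object$config$model,
    mlp = {
      Xs <- sweep(sweep(X, 2L, object$fit$center), 2L, object$fit$scale, "/")
      .mlp_predict(object$fit, Xs)
    },
    decision_tree = unname(stats::predict(
      object$fit, newdata = as.data.frame(X, check.names = FALSE))),
    random_forest = stats::predict(
      object$fit, data = as.data.frame(X), num.threads = 1L)$predictions)
}

#' Random-forest impurity importances of a fitted baseline
#'
#' Normalized to sum to one.
#' @param object A `baseline_fit` with `model = "random_forest"`.
#' @return Named numeric vector.
#' @export
forest_importance <- function(object) {
  stopifnot(inherits(object, "baseline_fit"),
            object$config$model == "random_forest")
  imp <- object$fit$variable.importance
  imp / sum(imp)
}
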