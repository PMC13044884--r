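# The graph attention network: readout modes, forward-pass structure,
# training behaviour and checkpointing.

test_that("readout implements the four pooling modes", {
  expect_equal(readout(c(1, 2, 3), "average"), 2)
  expect_equal(readout(c(1, 2, 3), "first_node"), 1)
  expect_equal(readout(c(1, 2, 3), "second_node"), 2)
  expect_equal(readout(c(1, 2, 3), "last_node"), 3)
  set.seed(8)
  v <- rnorm(17)
  expect_equal(readout(v, "average"), sum(v) / length(v))
  expect_warning(out <- readout(5, "second_node"), "first node")
  expect_equal(out, 5)
})

test_that("forward returns one finite value per node, deterministically", {
  mols <- fixture_molecules(16)
  fit <- train_gnn(mols$graph[1:6], mols$beta_true[1:6],
                   gnn_config(epochs = 50, seed = 1))
  g <- mols$graph[[1]]
  out <- forward(g, fit)
  expect_length(out, g$n_nodes)
  expect_true(all(is.finite(out)))
  expect_identical(out, forward(g, fit))

  bad <- g
  bad$node_features <- g$node_features[, 1:12, drop = FALSE]
  expect_error(forward(bad, fit), "dimension mismatch")
})

test_that("forward is permutation-equivariant", {
  mols <- fixture_molecules(16)
  fit <- train_gnn(mols$graph[1:6], mols$beta_true[1:6],
                   gnn_config(epochs = 50, seed = 2))
  g <- mols$graph[[which(vapply(mols$graph, function(x) x$n_nodes, 0L) >= 4)[1]]]
  set.seed(3)
  perm <- sample(g$n_nodes)
  gp <- g
  gp$node_features <- g$node_features[perm, , drop = FALSE]
  inv <- order(perm)
  gp$edges <- matrix(inv[g$edges], ncol = 2)
  out <- forward(g, fit)
  outp <- forward(gp, fit)
  expect_equal(outp, out[perm], tolerance = 1e-10)
})

test_that("average-readout prediction is invariant to node relabeling", {
  mols <- fixture_molecules(16)
  fit <- train_gnn(mols$graph[1:8], mols$beta_true[1:8],
                   gnn_config(epochs = 50, seed = 4))
  for (i in c(1, 5)) {
    g <- mols$graph[[i]]
    if (g$n_nodes < 2) next
    set.seed(i)
    perm <- sample(g$n_nodes)
    gp <- g
    gp$node_features <- g$node_features[perm, , drop = FALSE]
    inv <- order(perm)
    gp$edges <- matrix(inv[g$edges], ncol = 2)
    expect_equal(predict(fit, list(gp)), predict(fit, list(g)),
                 tolerance = 1e-5)
  }
})

test_that("global shape features are wired into the prediction", {
  mols <- fixture_molecules(16)
  fit <- train_gnn(mols$graph[1:8], mols$beta_true[1:8],
                   gnn_config(epochs = 100, seed = 5))
  g <- mols$graph[[1]]
  g2 <- g
  g2$node_features[, 13:16] <- g2$node_features[, 13:16] * 1.5
  expect_false(isTRUE(all.equal(predict(fit, list(g)), predict(fit, list(g2)))))
})

test_that("the network memorizes a single repeated molecule", {
  mols <- fixture_molecules(16)
  g10 <- rep(mols$graph[1], 10)
  fit <- train_gnn(g10, rep(1.7, 10), gnn_config(epochs = 500, seed = 1))
  expect_lt(utils::tail(fit$training_log, 1), 1e-3)
  expect_equal(predict(fit, mols$graph[1]), 1.7, tolerance = 0.05)
})

test_that("two distinct molecules are fitted to their targets", {
  mols <- fixture_molecules(16)
  fit <- train_gnn(mols$graph[1:2], c(0.5, 3),
                   gnn_config(epochs = 1500, seed = 1))
  p <- predict(fit, mols$graph[1:2])
  expect_equal(p, c(0.5, 3), tolerance = 0.05)
})

test_that("fixed-seed retraining reproduces the final loss", {
  mols <- fixture_molecules(16)
  f1 <- train_gnn(mols$graph[1:8], mols$beta_true[1:8],
                  gnn_config(epochs = 300, seed = 7))
  f2 <- train_gnn(mols$graph[1:8], mols$beta_true[1:8],
                  gnn_config(epochs = 300, seed = 7))
  expect_lt(abs(utils::tail(f1$training_log, 1) -
                utils::tail(f2$training_log, 1)), 1e-6)
  f3 <- train_gnn(mols$graph[1:8], mols$beta_true[1:8],
                  gnn_config(epochs = 300, seed = 8))
  expect_false(identical(f1$parameters, f3$parameters))
})

test_that("the loss trajectory is finite and decays", {
  mols <- fixture_molecules(16)
  fit <- train_gnn(mols$graph, mols$beta_true,
                   gnn_config(epochs = 600, seed = 9))
  l <- fit$training_log
  expect_true(all(is.finite(l)))
  ma <- stats::filter(l, rep(1 / 20, 20), sides = 1)
  ma <- ma[!is.na(ma)]
  # non-increasing 20-epoch moving average, up to a small jitter allowance
  expect_lt(max(diff(ma)), 1e-3 * ma[1])
  expect_lt(ma[length(ma)], ma[1])
})

test_that("per-repeat seeds and node readouts change the fit", {
  mols <- fixture_molecules(16)
  for (mode in c("first_node", "second_node", "last_node")) {
    fit <- train_gnn(mols$graph[1:6], mols$beta_true[1:6],
                     gnn_config(epochs = 50, seed = 1, readout = mode))
    p <- predict(fit, mols$graph[1:6])
    expect_length(p, 6)
    expect_true(all(is.finite(p)))
    # node readout equals the raw node output at the stated position
    g <- mols$graph[[2]]
    expect_equal(p[2], readout(forward(g, fit), mode, g$node_order))
  }
})

test_that("predict on an empty list returns an empty vector", {
  mols <- fixture_molecules(16)
  fit <- train_gnn(mols$graph[1:4], mols$beta_true[1:4],
                   gnn_config(epochs = 20, seed = 1))
  expect_identical(predict(fit, list()), numeric(0))
})

test_that("checkpoints round-trip through JSON", {
  mols <- fixture_molecules(16)
  fit <- train_gnn(mols$graph[1:6], mols$beta_true[1:6],
                   gnn_config(epochs = 100, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_gnn_checkpoint(fit, path)
  back <- read_gnn_checkpoint(path)
  expect_equal(predict(back, mols$graph[1:6]), predict(fit, mols$graph[1:6]),
               tolerance = 1e-12)
  expect_equal(back$data_fingerprint, fit$data_fingerprint)
})

test_that("tidiers expose the training log and architecture", {
  mols <- fixture_molecules(16)
  fit <- train_gnn(mols$graph[1:4], mols$beta_true[1:4],
                   gnn_config(epochs = 30, seed = 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 30)
  gl <- glance(fit)
  expect_equal(gl$n_layers, 4L)
  expect_equal(gl$channels, 28L)
  expect_gt(gl$n_parameters, 0)
})
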