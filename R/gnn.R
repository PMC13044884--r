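# R-facing surface of the graph attention network regressor: configuration,
# dataset batching, training, prediction and the four readout modes.

#' Graph attention network configuration
#'
#' Architecture and training schedule of the GAT regressor: `n_layers` GAT
#' layers (4 for the blood beta task; 5 for the logIE benchmark), 28
#' channels per hidden layer, tanh activation between layers (identity on
#' the single-channel output layer, since beta is unbounded), one attention
#' head, full-batch RMSprop on mean squared error.
#'
#' @param n_layers Number of GAT layers.
#' @param channels Hidden embedding size.
#' @param readout One of `"average"`, `"first_node"`, `"second_node"`,
#'   `"last_node"` — average pooling of the per-node outputs, or the output
#'   at the stated position of the SMILES atom order.
#' @param learning_rate RMSprop learning rate.
#' @param epochs Training epochs (full batch).
#' @param seed Integer seed for weight initialization.
#' @return A `gnn_config` list.
#' @export
gnn_config <- function(n_layers = 4L, channels = 28L,
                       readout = c("average", "first_node", "second_node",
                                   "last_node"),
                       learning_rate = 1e-3, epochs = 2000L, seed = 1L) {
  readout <- match.arg(readout)
  stopifnot(n_layers >= 1, channels >= 1, learning_rate > 0, epochs >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 channels = as.integer(channels),
                 activation = "tanh", readout = readout,
                 optimizer = "rmsprop", learning_rate = learning_rate,
                 epochs = as.integer(epochs), loss = "mse",
                 seed = as.integer(seed)),
            class = "gnn_config")
}

# Stack a list of mol_graphs into the node-batched arrays the C++ core
# consumes: node features, directed edges (both directions + self-loops),
# graph ids and the readout node per graph. All indices 0-based.
.batch_graphs <- function(graphs, readout) {
  nf <- vapply(graphs, function(g) ncol(g$node_features), 0L)
  if (length(unique(nf)) != 1L) {
    stop("node feature dimensionality differs across graphs", call. = FALSE)
  }
  sizes <- vapply(graphs, function(g) g$n_nodes, 0L)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  src <- integer(0); dst <- integer(0)
  for (i in seq_along(graphs)) {
    e <- graphs[[i]]$edges
    self <- seq_len(sizes[i])
    if (nrow(e)) {
      s <- c(e[, 1], e[, 2], self); d <- c(e[, 2], e[, 1], self)
    } else {
      s <- self; d <- self
    }
    src <- c(src, s + offs[i] - 1L)
    dst <- c(dst, d + offs[i] - 1L)
  }
  graph_id <- rep(seq_along(graphs) - 1L, sizes)
  readout_node <- vapply(seq_along(graphs), function(i) {
    n <- sizes[i]
    pos <- switch(readout,
      average = return(-1L),
      first_node = 1L,
      second_node = if (n >= 2L) 2L else {
        warning("second_node readout on a 1-atom molecule (",
                graphs[[i]]$molecule_id, "); falling back to first node",
                call. = FALSE)
        1L
      },
      last_node = n)
    offs[i] + graphs[[i]]$node_order[pos] - 1L
  }, 0L)
  list(X = X, src = src, dst = dst, graph_id = graph_id,
       readout_node = readout_node, sizes = sizes)
}

#' Train the GAT regressor
#'
#' Minimizes mean squared error between the readout and the target with
#' full-batch RMSprop. Node features are standardized to zero mean / unit
#' variance using the training set only; the statistics are stored in the
#' model and reapplied at prediction time.
#'
#' @param graphs List of featurized `mol_graph` objects (16 feature columns).
#' @param targets Numeric vector of regression targets (beta or logIE),
#'   aligned with `graphs`.
#' @param config A [gnn_config()].
#' @return A `gnn_fit` object: `config`, learned `parameters`,
#'   `training_log` (per-epoch loss), standardization statistics and a
#'   `data_fingerprint` (md5 of the training inputs).
#' @examples
#' \donttest{
#' mols <- featurize_molecules(generate_molecules(8, seed = 1))
#' mols <- assign_beta(mols, noise_sd = 0)
#' fit <- train_gnn(mols$graph, mols$beta_true,
#'                  gnn_config(epochs = 200, seed = 1))
#' predict(fit, mols$graph)
#' }
#' @export
train_gnn <- function(graphs, targets, config = gnn_config()) {
  stopifnot(inherits(config, "gnn_config"),
            length(graphs) == length(targets),
            length(graphs) >= 2L, all(is.finite(targets)))
  b <- .batch_graphs(graphs, config$readout)
  mu <- colMeans(b$X)
  sdv <- apply(b$X, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(b$X, 2L, mu), 2L, sdv, "/")

  res <- .gat_train_cpp(Xs, b$src, b$dst, b$graph_id, b$readout_node,
                        as.numeric(targets),
                        config$n_layers, config$channels,
                        config$epochs, config$learning_rate, config$seed)
  structure(list(
    config = config,
    parameters = res$layers,
    training_log = as.numeric(res$loss),
    feature_mean = mu, feature_sd = sdv,
    n_features = ncol(b$X),
    data_fingerprint = data_fingerprint(list(
      ids = vapply(graphs, function(g) g$molecule_id, ""),
      targets = as.numeric(targets)))
  ), class = "gnn_fit")
}

#' @export
print.gnn_fit <- function(x, ...) {
  cat("<gnn_fit> ", x$config$n_layers, " GAT layers x ", x$config$channels,
      " channels, readout ", x$config$readout,
      "; final training MSE ", signif(utils::tail(x$training_log, 1), 4),
      "\n", sep = "")
  invisible(x)
}

#' Per-node forward pass of a trained GAT
#'
#' Applies the trained network to one graph and returns the raw per-node
#' scalar outputs, before any readout.
#'
#' @param graph A featurized `mol_graph`.
#' @param model A `gnn_fit`.
#' @return Numeric vector with one finite value per node.
#' @export
forward <- function(graph, model) {
  stopifnot(inherits(model, "gnn_fit"), inherits(graph, "mol_graph"))
  if (ncol(graph$node_features) != model$n_features) {
    stop("feature dimension mismatch: graph has ", ncol(graph$node_features),
         " columns, model expects ", model$n_features, call. = FALSE)
  }
  b <- .batch_graphs(list(graph), "average")
  Xs <- sweep(sweep(b$X, 2L, model$feature_mean), 2L, model$feature_sd, "/")
  as.numeric(.gat_forward_cpp(Xs, b$src, b$dst, model$parameters))
}

#' Reduce per-node outputs to one molecular value
#'
#' Average pooling returns the arithmetic mean; the node modes return the
#' output at the first, second or last atom of the SMILES parse order.
#' `second_node` on a one-atom molecule falls back to the first node with a
#' warning.
#'
#' @param node_outputs Numeric vector of per-node outputs.
#' @param mode One of `"average"`, `"first_node"`, `"second_node"`,
#'   `"last_node"`.
#' @param node_order Atom indices in SMILES parse order (defaults to
#'   `seq_along(node_outputs)`).
#' @return A single number.
#' @examples
#' readout(c(1, 2, 3), "average")     # 2
#' readout(c(1, 2, 3), "last_node")   # 3
#' @export
readout <- function(node_outputs,
                    mode = c("average", "first_node", "second_node",
                             "last_node"),
                    node_order = seq_along(node_outputs)) {
  mode <- match.arg(mode)
  stopifnot(length(node_outputs) >= 1L)
  if (mode == "average") return(mean(node_outputs))
  pos <- switch(mode,
    first_node = 1L,
    second_node = if (length(node_outputs) >= 2L) 2L else {
      warning("second_node readout on a 1-atom molecule; using first node",
              call. = FALSE)
      1L
    },
    last_node = length(node_outputs))
  node_outputs[node_order[pos]]
}

#' Predict beta (or logIE) for a list of molecular graphs
#'
#' @param object A `gnn_fit`.
#' @param graphs List of featurized `mol_graph` objects.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per graph, order-preserving.
#' @export
predict.gnn_fit <- function(object, graphs, ...) {
  if (!length(graphs)) return(numeric(0))
  b <- .batch_graphs(graphs, object$config$readout)
  if (ncol(b$X) != object$n_features) {
    stop("feature dimension mismatch: graphs have ", ncol(b$X),
         " columns, model expects ", object$n_features, call. = FALSE)
  }
  Xs <- sweep(sweep(b$X, 2L, object$feature_mean), 2L, object$feature_sd, "/")
  node_out <- as.numeric(.gat_forward_cpp(Xs, b$src, b$dst, object$parameters))
  gid <- b$graph_id + 1L
  vapply(seq_along(graphs), function(g) {
    if (b$readout_node[g] >= 0) node_out[b$readout_node[g] + 1L]
    else mean(node_out[gid == g])
  }, 0)
}

#' Fingerprint of a training input
#'
#' md5 digest of a serialized R object; used to prove per-fold training-set
#' isolation in the cross-validation harness.
#' @param x Any R object.
#' @return A 32-character md5 string.
#' @export
data_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Serialize a trained GAT to a JSON checkpoint
#'
#' Config, weights, standardization statistics and data fingerprint in one
#' text file.
#' @param model A `gnn_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gnn_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gnn_fit"))
  payload <- list(
    config = unclass(model$config),
    parameters = lapply(model$parameters, function(l) {
      list(W = unname(l$W), b = as.numeric(l$b),
           a1 = as.numeric(l$a1), a2 = as.numeric(l$a2))
    }),
    training_log = model$training_log,
    feature_mean = as.numeric(model$feature_mean),
    feature_sd = as.numeric(model$feature_sd),
    n_features = model$n_features,
    data_fingerprint = model$data_fingerprint)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gnn_checkpoint
#' @export
read_gnn_checkpoint <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  cfg <- do.call(gnn_config, x$config[c("n_layers", "channels", "readout",
                                        "learning_rate", "epochs", "seed")])
  params <- lapply(seq_len(nrow_or_len(x$parameters)), function(i) {
    l <- if (is.data.frame(x$parameters)) lapply(x$parameters, `[[`, i)
         else x$parameters[[i]]
    list(W = as.matrix(l$W), b = as.numeric(l$b),
         a1 = as.numeric(l$a1), a2 = as.numeric(l$a2))
  })
  structure(list(config = cfg, parameters = params,
                 training_log = as.numeric(x$training_log),
                 feature_mean = as.numeric(x$feature_mean),
                 feature_sd = as.numeric(x$feature_sd),
                 n_features = as.integer(x$n_features),
                 data_fingerprint = x$data_fingerprint),
            class = "gnn_fit")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
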