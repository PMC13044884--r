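# broom-style tidiers and ggplot2 autoplot methods for the fitted objects
# and evaluation reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report
#'
#' One row per out-of-fold prediction: `molecule_id`, `run`, `target_true`,
#' `target_pred`, `abs_error`, `within_threshold`.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  t <- x$per_run$threshold[1]
  dplyr::mutate(x$predictions,
                abs_error = abs(.data$target_pred - .data$target_true),
                within_threshold = .data$abs_error < t)
}

#' Glance at an evaluation report
#'
#' One row: metric means and standard deviations over the repeated
#' trainings, plus the scheme and sizes.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
glance.eval_report <- function(x, ...) {
  s <- x$summary
  wide <- stats::setNames(
    as.list(c(s$mean, s$sd)),
    c(paste0(s$metric, "_mean"), paste0(s$metric, "_sd")))
  tibble::as_tibble(wide) |>
    dplyr::mutate(n_molecules = length(unique(x$predictions$molecule_id)),
                  n_repeats = max(x$per_run$run),
                  scheme = x$plan$scheme %||% NA_character_,
                  threshold = x$per_run$threshold[1])
}

#' Tidy a trained GAT: the loss trajectory
#' @param x A `gnn_fit`.
#' @param ... Unused.
#' @export
tidy.gnn_fit <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$training_log), loss = x$training_log)
}

#' Glance at a trained GAT
#' @param x A `gnn_fit`.
#' @param ... Unused.
#' @export
glance.gnn_fit <- function(x, ...) {
  n_par <- sum(vapply(x$parameters, function(l)
    length(l$W) + length(l$b) + length(l$a1) + length(l$a2), 0))
  tibble::tibble(n_layers = x$config$n_layers, channels = x$config$channels,
                 readout = x$config$readout, epochs = x$config$epochs,
                 n_parameters = n_par,
                 final_loss = utils::tail(x$training_log, 1))
}

#' Glance at a fitted baseline
#' @param x A `baseline_fit`.
#' @param ... Unused.
#' @export
glance.baseline_fit <- function(x, ...) {
  tibble::tibble(model = x$config$model, feature_set = x$config$feature_set,
                 n_features = length(x$features), seed = x$config$seed)
}

#' Predicted-versus-true plot of an evaluation report
#'
#' Out-of-fold predictions against ground truth with the identity line and
#' the accuracy band at the report's threshold (within the band, the
#' concentration estimate is within a factor of two for `t = ln 2`).
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tidy(object)
  t <- object$per_run$threshold[1]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$target_true,
                                  y = .data$target_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = c(-t, t),
                         linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$within_threshold),
                        alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      name = sprintf("|error| < %.3f", t)) +
    ggplot2::labs(x = "true target", y = "out-of-fold prediction") +
    ggplot2::theme_minimal()
}

#' Training-loss plot of a fitted GAT
#' @param object A `gnn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gnn_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training MSE") +
    ggplot2::theme_minimal()
}
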