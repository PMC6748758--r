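#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' estimated connectivity (coefficient heatmap), hyperparameter selection
#' curves (precision/recall/F1 versus alpha), stability-selection edge
#' frequencies, and fitted collocation trajectories over the raw
#' time-course measurements.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @name usdl-plots
NULL

#' @rdname usdl-plots
#' @export
autoplot.usdl_fit <- function(object, ...) {
  df <- tibble::tibble(
    variable = factor(rep(rownames(object$A_hat), times = ncol(object$A_hat)),
                      levels = rev(rownames(object$A_hat))),
    term = factor(rep(colnames(object$A_hat), each = nrow(object$A_hat)),
                  levels = colnames(object$A_hat)),
    estimate = as.numeric(object$A_hat)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$variable,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "dictionary atom", y = "target variable",
                  fill = "coefficient",
                  title = "Estimated connectivity matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname usdl-plots
#' @export
autoplot.usdl_alpha_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(object$scores,
                            cols = c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$value,
                                   color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_alpha, linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(x = expression(alpha), y = NULL,
                  title = "Score versus OMP stopping parameter",
                  subtitle = sprintf("selected alpha = %g", object$best_alpha)) +
    ggplot2::theme_minimal()
}

#' @rdname usdl-plots
#' @export
autoplot.usdl_stability <- function(object, ...) {
  df <- object$frequencies
  if (nrow(df) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No edges selected in any repeat"))
  }
  df$edge <- stats::reorder(paste(df$source, "→", df$target), df$frequency)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$edge)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$frequency,
                                       yend = .data$edge), color = "grey70") +
    ggplot2::geom_point(ggplot2::aes(color = .data$frequency >= object$threshold)) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey50"),
                                guide = "none") +
    ggplot2::labs(x = "selection frequency", y = NULL,
                  title = sprintf("Stability selection (%d repeats, consensus at %.0f%%)",
                                  object$B, 100 * object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot fitted collocation trajectories over the measurements
#'
#' @param fits tibble from [fit_experiment()] / [fit_all_experiments()].
#' @param data the long-format measurements the fits came from (optional;
#'   adds the raw points).
#' @param grid_n evaluation points per trajectory.
#' @return a ggplot object, faceted by experiment.
#' @export
plot_trajectories <- function(fits, data = NULL, grid_n = 201L) {
  fits <- as.data.frame(fits)
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
    tr <- fits$trajectory[[i]]
    if (is.null(tr)) return(NULL)
    g <- seq(tr$domain[1], tr$domain[2], length.out = grid_n)
    tibble::tibble(experiment = fits$experiment[i],
                   variable = fits$variable[i],
                   time = g, value = predict(tr, g))
  }))
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$value,
                                            color = .data$variable)) +
    ggplot2::geom_line()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = as.data.frame(data), alpha = 0.35,
                                 size = 0.8)
  }
  p + ggplot2::facet_wrap(~experiment) +
    ggplot2::labs(x = "time", y = "activity",
                  title = "Collocation fits over time-course measurements") +
    ggplot2::theme_minimal()
}
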