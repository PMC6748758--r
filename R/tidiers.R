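#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns one row per estimated quantity; `glance()` returns a
#' one-row model summary; `augment()` (trajectories) returns the data with
#' fitted values.
#'
#' @param x the fitted object.
#' @param ... unused.
#' @return a tibble.
#' @name usdl-tidiers
NULL

#' @rdname usdl-tidiers
#' @export
tidy.usdl_fit <- function(x, ...) {
  A <- x$A_hat
  tibble::tibble(
    variable = rep(rownames(A), times = ncol(A)),
    term = rep(colnames(A), each = nrow(A)),
    estimate = as.numeric(A)
  ) |>
    dplyr::filter(.data$estimate != 0) |>
    dplyr::arrange(.data$variable, .data$term)
}

#' @rdname usdl-tidiers
#' @export
glance.usdl_fit <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x$A_hat),
    n_atoms = ncol(x$A_hat),
    n_edges = nrow(x$edges),
    mip = x$mip,
    min_erc = suppressWarnings(min(x$diagnostics$erc, na.rm = TRUE)),
    mean_support = mean(x$diagnostics$support_size)
  )
}

#' @rdname usdl-tidiers
#' @export
tidy.usdl_sparse_solution <- function(x, ...) {
  labels <- x$labels %||% paste0("psi", seq_along(x$coefficients))
  tibble::tibble(
    term = labels[x$support],
    index = x$support,
    estimate = x$coefficients[x$support],
    order = seq_along(x$support)
  )
}

#' @rdname usdl-tidiers
#' @export
glance.usdl_sparse_solution <- function(x, ...) {
  tibble::tibble(
    support_size = length(x$support),
    residual_norm = tail(x$residual_norms, 1L),
    stop_reason = x$stop_reason,
    alpha = x$alpha,
    epsilon = x$epsilon
  )
}

#' @rdname usdl-tidiers
#' @export
glance.usdl_trajectory <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_coef = length(x$coef),
    lambda = x$lambda,
    rss = x$rss,
    rank_deficient = x$rank_deficient
  )
}

#' @rdname usdl-tidiers
#' @param t times at which to evaluate the trajectory (defaults to a dense
#'   grid over the domain).
#' @export
augment.usdl_trajectory <- function(x, t = NULL, ...) {
  if (is.null(t)) t <- seq(x$domain[1], x$domain[2], length.out = 201L)
  tibble::tibble(time = t, .fitted = predict(x, t))
}

#' @rdname usdl-tidiers
#' @export
tidy.usdl_stability <- function(x, ...) x$frequencies

#' @rdname usdl-tidiers
#' @export
tidy.usdl_alpha_selection <- function(x, ...) x$scores
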