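#' Penalized B-spline collocation for destructive time-course data
#'
#' Time-course data measure a different object (e.g. a different cell) at
#' every time instant, so no single object yields a trajectory. Collocation
#' approximates the underlying trajectory by a weighted sum of B-spline basis
#' functions fitted by penalized least squares: the coefficients minimize
#' the residual sum of squares plus `lambda` times the integrated squared
#' second derivative of the fit (a roughness penalty). Measurement noise is
#' treated as Gaussian. Repeated measurements at one time point all enter as
#' individual residual terms; they are not pre-averaged.
#'
#' @param samples a data frame with columns `time` and `value` (one
#'   variable's measurements within one experiment); at least two distinct
#'   times are required.
#' @param basis optional basis description from [colloc_basis()]. The
#'   default uses cubic B-splines with interior knots at the distinct sample
#'   times (capped at 25, thinned to quantiles beyond that).
#' @param lambda roughness-penalty weight: a non-negative number, or
#'   `"gcv"` to select it by generalized cross-validation over a log-spaced
#'   grid.
#' @param domain time interval `[0, T]` for the trajectory; defaults to
#'   `c(0, max(samples$time))` so the weak-form boundary terms are available
#'   at both endpoints.
#'
#' @return an object of class `usdl_trajectory`: B-spline knots/degree,
#'   fitted coefficients, `lambda` used, the residual summary, and the
#'   domain. Evaluate it with `predict(traj, t)`.
#'
#' @details With `lambda = 0` and a basis at least as rich as the number of
#'   distinct sample times, the fit reproduces the per-time sample means
#'   exactly (minimum-norm solution under rank deficiency). As
#'   `lambda` grows the fit approaches the straight line of best fit, the
#'   null space of the second-derivative penalty.
#' @export
fit_collocation <- function(samples, basis = NULL, lambda = "gcv",
                            domain = NULL) {
  samples <- as.data.frame(samples)
  if (!all(c("time", "value") %in% names(samples))) {
    abort("`samples` needs columns `time` and `value`.")
  }
  t_obs <- as.numeric(samples$time)
  y <- as.numeric(samples$value)
  ok <- is.finite(t_obs) & is.finite(y)
  t_obs <- t_obs[ok]; y <- y[ok]
  if (length(unique(t_obs)) < 2L) {
    abort("need measurements at >= 2 distinct sample times.")
  }
  if (is.null(domain)) domain <- c(min(0, min(t_obs)), max(t_obs))
  if (is.null(basis)) basis <- colloc_basis()
  bd <- build_basis(basis, t_obs, domain)
  B <- splines::splineDesign(bd$knots, t_obs, ord = bd$degree + 1L)
  Omega <- penalty_matrix(bd$knots, bd$degree)

  fit_at <- function(lam) {
    M <- crossprod(B) + lam * Omega
    rhs <- crossprod(B, y)
    # minimum-norm solve: tolerant to rank deficiency at lambda = 0
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-10
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
    list(coef = drop(coefs), rank_deficient = !all(pos))
  }

  gcv_score <- function(lam) {
    M <- crossprod(B) + lam * Omega
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-10
    Minv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    H <- B %*% Minv %*% t(B)
    fitted <- drop(H %*% y)
    rss <- sum((y - fitted)^2)
    trH <- sum(diag(H))
    n <- length(y)
    denom <- max(n - trH, 1e-8)
    n * rss / denom^2
  }

  gcv_table <- NULL
  if (identical(lambda, "gcv")) {
    # scale-aware grid around the magnitude of B'B
    s0 <- mean(diag(crossprod(B)))
    grid <- s0 * 10^seq(-8, 4, length.out = 30)
    scores <- vapply(grid, gcv_score, numeric(1))
    gcv_table <- tibble::tibble(lambda = grid, gcv = scores)
    lambda <- grid[which.min(scores)]
  } else if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    abort("`lambda` must be a non-negative number or \"gcv\".")
  }

  sol <- fit_at(lambda)
  fitted <- drop(B %*% sol$coef)
  structure(
    list(knots = bd$knots, degree = bd$degree, coef = sol$coef,
         lambda = lambda, domain = domain,
         rank_deficient = sol$rank_deficient,
         gcv_table = gcv_table,
         residuals = y - fitted,
         rss = sum((y - fitted)^2),
         n_obs = length(y)),
    class = "usdl_trajectory"
  )
}

#' Describe a collocation basis
#'
#' @param degree B-spline degree (default cubic).
#' @param max_interior_knots cap on the number of interior knots; interior
#'   knots sit at the distinct sample times, thinned to evenly spaced
#'   quantiles when there are more distinct times than the cap.
#' @param knots optional explicit interior knot vector overriding the
#'   data-driven placement.
#' @return a basis description for [fit_collocation()].
#' @export
colloc_basis <- function(degree = 3L, max_interior_knots = 25L, knots = NULL) {
  if (degree < 1) abort("`degree` must be >= 1.")
  structure(list(degree = as.integer(degree),
                 max_interior_knots = as.integer(max_interior_knots),
                 knots = knots),
            class = "usdl_colloc_basis")
}

build_basis <- function(basis, t_obs, domain) {
  stopifnot(inherits(basis, "usdl_colloc_basis"))
  d <- basis$degree
  if (!is.null(basis$knots)) {
    interior <- sort(basis$knots)
  } else {
    cand <- sort(unique(t_obs))
    cand <- cand[cand > domain[1] + 1e-12 & cand < domain[2] - 1e-12]
    if (length(cand) > basis$max_interior_knots) {
      probs <- seq(0, 1, length.out = basis$max_interior_knots + 2L)[-c(1L, basis$max_interior_knots + 2L)]
      cand <- unique(as.numeric(stats::quantile(cand, probs, type = 1)))
    }
    interior <- cand
  }
  knots <- c(rep(domain[1], d + 1L), interior, rep(domain[2], d + 1L))
  list(knots = knots, degree = d)
}

# exact integral of products of second derivatives of the B-spline basis:
# Gauss-Legendre per inter-knot interval (the integrand is piecewise
# polynomial of degree 2*(degree-2), so `degree` nodes are exact)
penalty_matrix <- function(knots, degree) {
  K <- length(knots) - degree - 1L
  if (degree < 2L) return(matrix(0, K, K))  # no second derivative to penalize
  uk <- unique(knots)
  ngauss <- max(2L, degree)
  Omega <- matrix(0, K, K)
  for (i in seq_len(length(uk) - 1L)) {
    a <- uk[i]; b <- uk[i + 1L]
    gl <- pracma::gaussLegendre(ngauss, a, b)
    D2 <- splines::splineDesign(knots, gl$x, ord = degree + 1L,
                                derivs = rep(2L, length(gl$x)))
    Omega <- Omega + t(D2) %*% (gl$w * D2)
  }
  Omega
}

#' @export
predict.usdl_trajectory <- function(object, t, deriv = 0L, ...) {
  tt <- pmin(pmax(t, object$domain[1]), object$domain[2])
  B <- splines::splineDesign(object$knots, tt, ord = object$degree + 1L,
                             derivs = rep(as.integer(deriv), length(tt)))
  drop(B %*% object$coef)
}

#' @export
print.usdl_trajectory <- function(x, ...) {
  cat(sprintf("<usdl_trajectory: degree-%d B-spline, %d coefficients on [%g, %g], lambda = %.3g, RSS = %.4g (n = %d)>\n",
              x$degree, length(x$coef), x$domain[1], x$domain[2],
              x$lambda, x$rss, x$n_obs))
  invisible(x)
}

#' Fit all variables of one experiment (multiple shooting)
#'
#' Each variable of each experiment gets its own independently fitted
#' trajectory, mirroring multiple shooting: interventions make trajectories
#' experiment-specific, so no coupling across experiments is imposed.
#'
#' @param data long-format data frame with columns `experiment`, `time`,
#'   `variable`, `value`.
#' @param experiment the experiment identifier to fit.
#' @param basis,lambda passed to [fit_collocation()].
#' @param baseline if `TRUE`, subtract each fitted trajectory's minimum
#'   (the state of no activity) via [baseline_adjust()].
#' @return a tibble with one row per variable: `experiment`, `variable`,
#'   `n_obs`, `lambda`, `rss` and a `trajectory` list-column of
#'   `usdl_trajectory` objects. Variables with fewer than two distinct
#'   sample times are skipped with a warning and appear with a `NULL`
#'   trajectory.
#' @export
fit_experiment <- function(data, experiment, basis = NULL, lambda = "gcv",
                           baseline = FALSE) {
  data <- as.data.frame(data)
  need <- c("experiment", "time", "variable", "value")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns experiment, time, variable, value.")
  }
  d <- data[data$experiment == experiment, , drop = FALSE]
  if (nrow(d) == 0L) abort(sprintf("experiment '%s' not found in data.", experiment))
  T_final <- max(d$time)
  vars <- unique(as.character(d$variable))
  rows <- lapply(vars, function(v) {
    dv <- d[d$variable == v, c("time", "value")]
    if (length(unique(dv$time)) < 2L) {
      warn(sprintf("variable '%s' in experiment '%s' has < 2 distinct time points; skipped.",
                   v, experiment))
      return(tibble::tibble(experiment = experiment, variable = v,
                            n_obs = nrow(dv), lambda = NA_real_,
                            rss = NA_real_, trajectory = list(NULL)))
    }
    tr <- fit_collocation(dv, basis = basis, lambda = lambda,
                          domain = c(0, T_final))
    if (baseline) tr <- baseline_adjust(tr)
    tibble::tibble(experiment = experiment, variable = v, n_obs = tr$n_obs,
                   lambda = tr$lambda, rss = tr$rss, trajectory = list(tr))
  })
  dplyr::bind_rows(rows)
}

#' Fit every experiment in a time-course dataset
#'
#' @inheritParams fit_experiment
#' @return row-bound [fit_experiment()] tibbles, one block per experiment.
#' @export
fit_all_experiments <- function(data, basis = NULL, lambda = "gcv",
                                baseline = FALSE) {
  exps <- unique(as.data.frame(data)$experiment)
  dplyr::bind_rows(lapply(exps, function(e) {
    fit_experiment(data, e, basis = basis, lambda = lambda, baseline = baseline)
  }))
}

#' Subtract a trajectory's minimum (baseline adjustment)
#'
#' The minimum of a fitted trajectory corresponds to the state of no
#' activity; subtracting it aligns trajectories measured on arbitrary
#' additive scales. The minimum is located on a dense grid (2001 points) and
#' subtracted exactly from the B-spline coefficients (B-splines form a
#' partition of unity on the domain).
#'
#' @param trajectory a `usdl_trajectory`.
#' @param grid_n number of grid points used to locate the minimum.
#' @return the adjusted `usdl_trajectory`; its minimum over the grid is 0.
#' @export
baseline_adjust <- function(trajectory, grid_n = 2001L) {
  stopifnot(inherits(trajectory, "usdl_trajectory"))
  g <- seq(trajectory$domain[1], trajectory$domain[2], length.out = grid_n)
  m <- min(predict(trajectory, g))
  trajectory$coef <- trajectory$coef - m
  trajectory$baseline_shift <- m
  trajectory
}
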