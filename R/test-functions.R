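#' Test-function families for the weak formulation
#'
#' A test-function family is a set of `M` smooth functions
#' \eqn{\varphi_m(t)} on a time interval `[0, T]` together with their exact
#' (closed-form) derivatives. The weak formulation integrates trajectories
#' and dictionary evaluations against these functions, so derivatives of the
#' *data* are never needed: only the test functions are differentiated, and
#' that differentiation is analytic.
#'
#' Three built-in kinds are provided:
#' * `tf_fourier()`: the constant function plus sine/cosine pairs at
#'   harmonics of the record length `T` (fundamental period `T`; the data
#'   are not assumed periodic).
#' * `tf_peaky_fourier()`: periodic, sharply localized bumps
#'   \eqn{\exp(\kappa(\cos(2\pi k (t - c)/T) - 1))}, two phase offsets per
#'   harmonic, plus the constant. Sharp peaks help separate signals whose
#'   correlations differ only over small time lags, e.g. stationary
#'   stochastic processes.
#' * `tf_bspline()`: a B-spline basis with uniform interior knots and exact
#'   piecewise-polynomial derivatives.
#'
#' @param T_final positive record length; the family lives on `[0, T_final]`,
#'   in the same time units as the data.
#' @param K harmonic order (`tf_fourier`, `tf_peaky_fourier`: the family has
#'   `2K + 1` members) or number of interior knots (`tf_bspline`).
#' @param kappa sharpness of the peaky bumps (> 0). Larger values give
#'   narrower peaks; as `kappa` tends to 0 every bump tends to the constant 1.
#' @param degree B-spline degree (>= 1 so that derivatives exist as
#'   functions).
#'
#' @return An object of class `usdl_test_family` with fields `kind`,
#'   `T_final`, `M` (number of members) and `params`. Evaluate it with
#'   [tf_evaluate()].
#'
#' @examples
#' fam <- tf_fourier(60, 20)   # 41 members: constant, 20 sines, 20 cosines
#' fam$M
#' phi <- tf_evaluate(fam, seq(0, 60, length.out = 5))
#' dim(phi)
#' @name test_functions
NULL

new_test_family <- function(kind, T_final, M, params, eval_fn) {
  structure(
    list(kind = kind, T_final = T_final, M = M, params = params,
         eval_fn = eval_fn),
    class = "usdl_test_family"
  )
}

#' @rdname test_functions
#' @export
tf_fourier <- function(T_final, K) {
  if (!is.numeric(T_final) || length(T_final) != 1L || !is.finite(T_final) ||
      T_final <= 0) {
    abort("`T_final` must be a single positive number.")
  }
  if (!is.numeric(K) || length(K) != 1L || K < 0 || K != round(K)) {
    abort("`K` must be a single non-negative integer.")
  }
  K <- as.integer(K)
  M <- 2L * K + 1L
  w <- 2 * pi / T_final
  eval_fn <- function(t, deriv = 0L) {
    out <- matrix(0, length(t), M)
    out[, 1L] <- if (deriv == 0L) 1 else 0
    if (K > 0L) {
      for (k in seq_len(K)) {
        wk <- w * k
        if (deriv == 0L) {
          out[, 2L * k] <- sin(wk * t)
          out[, 2L * k + 1L] <- cos(wk * t)
        } else {
          out[, 2L * k] <- wk * cos(wk * t)
          out[, 2L * k + 1L] <- -wk * sin(wk * t)
        }
      }
    }
    out
  }
  new_test_family("fourier", T_final, M, list(K = K), eval_fn)
}

#' @rdname test_functions
#' @export
tf_peaky_fourier <- function(T_final, K, kappa) {
  if (!is.numeric(T_final) || length(T_final) != 1L || !is.finite(T_final) ||
      T_final <= 0) {
    abort("`T_final` must be a single positive number.")
  }
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K)) {
    abort("`K` must be a single integer >= 1.")
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0) {
    abort("`kappa` must be a single positive number.")
  }
  K <- as.integer(K)
  M <- 2L * K + 1L
  # two phase offsets per harmonic k: peaks at T/(4k) (+ multiples of T/k)
  # and shifted by half a period, so all peaks are interior to [0, T]
  centers <- lapply(seq_len(K), function(k) {
    c(T_final / (4 * k), T_final / (4 * k) + T_final / (2 * k))
  })
  w <- 2 * pi / T_final
  eval_fn <- function(t, deriv = 0L) {
    out <- matrix(0, length(t), M)
    out[, 1L] <- if (deriv == 0L) 1 else 0
    for (k in seq_len(K)) {
      wk <- w * k
      for (j in 1:2) {
        ph <- wk * (t - centers[[k]][j])
        val <- exp(kappa * (cos(ph) - 1))
        col <- 2L * (k - 1L) + j + 1L
        out[, col] <- if (deriv == 0L) val else -kappa * wk * sin(ph) * val
      }
    }
    out
  }
  new_test_family("peaky_fourier", T_final, M,
                  list(K = K, kappa = kappa, centers = centers), eval_fn)
}

#' @rdname test_functions
#' @export
tf_bspline <- function(T_final, K, degree = 3L) {
  if (!is.numeric(T_final) || length(T_final) != 1L || !is.finite(T_final) ||
      T_final <= 0) {
    abort("`T_final` must be a single positive number.")
  }
  if (!is.numeric(degree) || length(degree) != 1L || degree < 1 ||
      degree != round(degree)) {
    abort("`degree` must be an integer >= 1 (degree-0 splines have no derivative function).")
  }
  if (!is.numeric(K) || length(K) != 1L || K < 0 || K != round(K)) {
    abort("`K` (number of interior knots) must be a non-negative integer.")
  }
  K <- as.integer(K); degree <- as.integer(degree)
  interior <- if (K > 0L) seq(0, T_final, length.out = K + 2L)[-c(1L, K + 2L)] else numeric(0)
  knots <- c(rep(0, degree + 1L), interior, rep(T_final, degree + 1L))
  M <- length(knots) - degree - 1L
  eval_fn <- function(t, deriv = 0L) {
    # clamp to the domain so the right endpoint is evaluable; derivatives at
    # exactly t = T use the left limit (splineDesign's half-open support
    # convention would return 0 there)
    tt <- pmin(pmax(t, 0), T_final)
    if (deriv > 0L) {
      shift <- T_final * 1e-10
      tt[tt >= T_final - shift] <- T_final - shift
    }
    splines::splineDesign(knots, tt, ord = degree + 1L,
                          derivs = rep(as.integer(deriv), length(tt)))
  }
  new_test_family("bspline", T_final, M,
                  list(K = K, degree = degree, knots = knots), eval_fn)
}

#' Evaluate a test-function family on a time grid
#'
#' @param family a `usdl_test_family`.
#' @param t numeric vector of times in `[0, T_final]`.
#' @param deriv 0 for function values, 1 for the exact first derivative.
#' @return a `length(t)` by `M` matrix; column `m` holds
#'   \eqn{\varphi_m(t)} (or \eqn{\dot\varphi_m(t)}).
#' @export
tf_evaluate <- function(family, t, deriv = 0L) {
  stopifnot(inherits(family, "usdl_test_family"))
  if (!is.numeric(t) || anyNA(t)) abort("`t` must be a numeric vector without NA.")
  if (any(t < -1e-9) || any(t > family$T_final * (1 + 1e-9))) {
    abort("`t` must lie within the family domain [0, T_final].")
  }
  deriv <- as.integer(deriv)
  if (!deriv %in% c(0L, 1L)) abort("`deriv` must be 0 or 1.")
  family$eval_fn(t, deriv)
}

#' Parse a test-function family specification string
#'
#' Specification strings configure families from the command line or config
#' files: `"fourier:K"`, `"peaky:K,kappa"`, `"bspline:K,degree"`. Because a
#' family needs the record length of the experiment it is applied to, the
#' parser returns a *constructor* `function(T_final)`.
#'
#' @param spec a specification string.
#' @return a function mapping a record length to a `usdl_test_family`.
#' @examples
#' make <- parse_family_spec("fourier:20")
#' make(60)$M   # 41
#' @export
parse_family_spec <- function(spec) {
  if (is.function(spec)) return(spec)
  if (inherits(spec, "usdl_test_family")) return(function(T_final) spec)
  if (!is.character(spec) || length(spec) != 1L) {
    abort("`spec` must be a string like \"fourier:20\", \"peaky:10,50\" or \"bspline:8,3\".")
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  args <- if (length(parts) > 1L) as.numeric(strsplit(parts[2], ",")[[1]]) else numeric(0)
  switch(kind,
    fourier = {
      if (length(args) != 1L) abort("fourier spec takes one parameter: \"fourier:K\".")
      function(T_final) tf_fourier(T_final, args[1])
    },
    peaky = {
      if (length(args) != 2L) abort("peaky spec takes two parameters: \"peaky:K,kappa\".")
      function(T_final) tf_peaky_fourier(T_final, args[1], args[2])
    },
    bspline = {
      if (length(args) != 2L) abort("bspline spec takes two parameters: \"bspline:K,degree\".")
      function(T_final) tf_bspline(T_final, args[1], args[2])
    },
    abort(sprintf("unknown test-function kind '%s'", kind))
  )
}

#' @export
print.usdl_test_family <- function(x, ...) {
  cat(sprintf("<usdl_test_family: %s, M = %d members on [0, %g]>\n",
              x$kind, x$M, x$T_final))
  invisible(x)
}
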