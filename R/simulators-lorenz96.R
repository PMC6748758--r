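#' Benchmark simulator: Lorenz96
#'
#' The cyclic Lorenz96 system from climate science,
#' \eqn{\dot x_k = (x_{k+1} - x_{k-2}) x_{k-1} - x_k + F} (indices mod `N`),
#' integrated with an adaptive solver. For the default forcing `F = 8` the
#' dynamics are chaotic, which is favorable for structure learning: chaotic
#' trajectories explore the state space and decorrelate the dictionary
#' columns. Ground truth is expressed over the quadratic dictionary of size
#' `(N + 3) N / 2`; the constant forcing `F` is reported separately
#' (`truth$forcing`) so it can be treated as a known contribution in
#' assembly, where a constant atom would be degenerate under Fourier test
#' functions that are orthogonal to constants.
#'
#' @param N state dimension (>= 4; the cyclic indices degenerate below).
#' @param F_forcing constant forcing term.
#' @param P number of trajectories, each from a random initial condition
#'   near the attractor (a perturbation of the fixed point `(F, ..., F)`
#'   evolved through a burn-in).
#' @param T_final recorded length of each trajectory.
#' @param dt_out output sampling step (quadrature grid downstream).
#' @param burn_in time discarded before recording (lets trajectories reach
#'   the attractor).
#' @param x0_jitter sd of the initial perturbation around the fixed point.
#' @param rtol,atol solver tolerances.
#' @param x0 optional fixed initial state used for every trajectory
#'   (skips the random perturbation and the burn-in; useful for
#'   deterministic checks such as the fixed point `(F, ..., F)`).
#' @param seed RNG seed (required).
#' @return a list with `experiments` (named list for [assemble()]), `truth`
#'   (`usdl_ground_truth` over the quadratic dictionary, with
#'   `truth$forcing`), and `config`.
#' @export
simulate_lorenz96 <- function(N = 8L, F_forcing = 8, P = 20L, T_final = 5,
                              dt_out = 0.01, burn_in = 5, x0_jitter = 1,
                              rtol = 1e-8, atol = 1e-10, x0 = NULL, seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (N < 4L) abort("`N` must be >= 4 (cyclic indices degenerate otherwise).")
  N <- as.integer(N)
  kp1 <- c(2:N, 1L)                # k + 1
  km1 <- c(N, 1:(N - 1L))         # k - 1
  km2 <- c(N - 1L, N, 1:(N - 2L)) # k - 2
  deriv <- function(t, y, parms) {
    list((y[kp1] - y[km2]) * y[km1] - y + parms)
  }
  vars <- paste0("x", seq_len(N))
  with_seed(seed, {
    grid <- seq(0, T_final, by = dt_out)
    experiments <- lapply(seq_len(P), function(p) {
      if (!is.null(x0)) {
        stopifnot(length(x0) == N)
        sol <- deSolve::ode(as.numeric(x0), grid, deriv, F_forcing,
                            rtol = rtol, atol = atol)
        st <- unname(sol[, -1, drop = FALSE])
        colnames(st) <- vars
        return(list(grid = grid, states = st))
      }
      y0 <- rep(F_forcing, N) + rnorm(N, sd = x0_jitter)
      if (burn_in > 0) {
        warm <- deSolve::ode(y0, c(0, burn_in), deriv, F_forcing,
                             rtol = rtol, atol = atol)
        y0 <- unname(warm[nrow(warm), -1])
      }
      sol <- deSolve::ode(y0, grid, deriv, F_forcing, rtol = rtol, atol = atol)
      st <- unname(sol[, -1, drop = FALSE])
      colnames(st) <- vars
      list(grid = grid, states = st)
    })
    names(experiments) <- paste0("traj", seq_len(P))

    dict <- dict_quadratic(N)
    A <- matrix(0, N, dict$Q, dimnames = list(vars, dict$labels))
    for (k in seq_len(N)) {
      A[k, k] <- -1
      ij <- sort(c(km1[k], kp1[k]))
      A[k, quad_index(ij[1], ij[2], N)] <- A[k, quad_index(ij[1], ij[2], N)] + 1
      ij <- sort(c(km2[k], km1[k]))
      A[k, quad_index(ij[1], ij[2], N)] <- A[k, quad_index(ij[1], ij[2], N)] - 1
    }
    truth <- new_ground_truth(A, variables = vars, labels = dict$labels,
                              config = list(system = "lorenz96", N = N,
                                            F_forcing = F_forcing, P = P,
                                            T_final = T_final,
                                            dt_out = dt_out),
                              seed = seed)
    truth$forcing <- F_forcing
    list(experiments = experiments, truth = truth, config = truth$config)
  })
}
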