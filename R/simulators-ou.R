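#' Benchmark simulator: multidimensional Ornstein-Uhlenbeck process
#'
#' Simulates `P` independent sample paths of the linear stochastic system
#' \eqn{\dot x = -Mx + \sigma \dot B} by Euler-Maruyama on a fine time step.
#' The drift matrix is built as the graph Laplacian of a random directed
#' graph with per-node out-degree at most `max_out_degree`, plus a diagonal
#' stabilizing shift `eps * I` (a pure Laplacian has a zero eigenvalue, so
#' no stationary law would exist without the shift). In the `"transient"`
#' regime paths start far from equilibrium and the drift dominates; in the
#' `"stationary"` regime paths start from a draw of the stationary law
#' (obtained by solving the Lyapunov equation
#' \eqn{M\Sigma + \Sigma M^\top = \sigma^2 I}) and stay at equilibrium,
#' where the diffusion dominates and the signal-to-noise ratio is near 1.
#'
#' @param N state dimension (>= 2).
#' @param P number of sample paths.
#' @param regime `"transient"` or `"stationary"`.
#' @param sigma diffusion intensity (>= 0; 0 gives a deterministic linear
#'   ODE).
#' @param T_final path length in time units.
#' @param dt Euler-Maruyama step.
#' @param record_every record the state every this many steps (the recorded
#'   grid is the quadrature grid downstream, so keep it fine).
#' @param max_out_degree maximum number of outgoing edges per node.
#' @param eps diagonal stabilizing shift added to the Laplacian.
#' @param weight_range range of the (positive) random edge weights.
#' @param x0_sd per-component sd of the far-from-equilibrium start
#'   (transient regime).
#' @param seed RNG seed (required).
#' @return a list with `experiments` (named list of `grid`/`states` pairs,
#'   ready for [assemble()]), `truth` (a `usdl_ground_truth`: the
#'   connectivity matrix `A = -M` in the \eqn{\dot x = Ax} convention over
#'   the linear dictionary, plus the signed edge list), and `config`.
#'   `truth$Sigma` holds the stationary covariance.
#' @export
simulate_ou <- function(N = 20L, P = 100L,
                        regime = c("transient", "stationary"),
                        sigma = 1, T_final = 8, dt = 0.004,
                        record_every = 2L, max_out_degree = 3L,
                        eps = 0.5, weight_range = c(0.5, 1.5),
                        x0_sd = 10, seed) {
  if (missing(seed)) abort("`seed` is required.")
  regime <- match.arg(regime)
  if (N < 2L) abort("`N` must be >= 2.")
  if (sigma < 0) abort("`sigma` must be >= 0.")

  with_seed(seed, {
    W <- ou_random_graph(N, max_out_degree, weight_range)
    L <- diag(rowSums(W)) - W
    M <- L + eps * diag(N)

    # stationary covariance: M Sigma + Sigma M' = sigma^2 I  (Lyapunov)
    Sigma <- if (sigma > 0) lyapunov_solve(M, sigma^2 * diag(N)) else matrix(0, N, N)

    n_steps <- round(T_final / dt)
    rec_idx <- seq(0L, n_steps, by = record_every)
    grid <- rec_idx * dt
    n_rec <- length(rec_idx)

    X <- if (regime == "transient") {
      matrix(rnorm(N * P, sd = x0_sd), N, P)
    } else {
      ch <- t(chol((Sigma + t(Sigma)) / 2))
      ch %*% matrix(rnorm(N * P), N, P)
    }
    states <- array(NA_real_, c(n_rec, N, P))
    rec_ptr <- 1L
    states[rec_ptr, , ] <- X
    sq <- sigma * sqrt(dt)
    for (s in seq_len(n_steps)) {
      X <- X - dt * (M %*% X)
      if (sigma > 0) X <- X + sq * matrix(rnorm(N * P), N, P)
      if (rec_ptr < n_rec && s == rec_idx[rec_ptr + 1L]) {
        rec_ptr <- rec_ptr + 1L
        states[rec_ptr, , ] <- X
      }
    }
    vars <- paste0("x", seq_len(N))
    experiments <- lapply(seq_len(P), function(p) {
      st <- states[, , p]
      colnames(st) <- vars
      list(grid = grid, states = st)
    })
    names(experiments) <- paste0("path", seq_len(P))

    A <- -M
    dimnames(A) <- list(vars, vars)
    truth <- new_ground_truth(A, variables = vars, labels = vars,
                              config = list(system = "ou", regime = regime,
                                            sigma = sigma, eps = eps,
                                            T_final = T_final, dt = dt,
                                            max_out_degree = max_out_degree),
                              seed = seed)
    truth$Sigma <- Sigma
    truth$drift <- M
    list(experiments = experiments, truth = truth,
         config = truth$config)
  })
}

# random directed graph: node j sends 1..max_out_degree edges to targets i,
# weight W[i, j] > 0 meaning j influences i
ou_random_graph <- function(N, max_out_degree, weight_range) {
  W <- matrix(0, N, N)
  for (j in seq_len(N)) {
    deg <- sample.int(max_out_degree, 1L)
    targets <- sample(setdiff(seq_len(N), j), deg)
    W[targets, j] <- runif(deg, weight_range[1], weight_range[2])
  }
  W
}

# solve M X + X M' = C by vectorization (moderate N only)
lyapunov_solve <- function(M, C) {
  N <- nrow(M)
  K <- kronecker(diag(N), M) + kronecker(M, diag(N))
  matrix(solve(K, as.numeric(C)), N, N)
}
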