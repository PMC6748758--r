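#' Orthogonal matching pursuit with a noise-energy stopping rule
#'
#' Greedy sparse signal recovery for `z = Psi a + e`. At each iteration the
#' column of `Psi` (normalized to unit l2 for selection) most correlated
#' with the current residual joins the active set, all active coefficients
#' are refit by least squares on the original columns, and the residual is
#' updated. Iterations stop when the residual l2 norm falls to the
#' estimated noise energy
#' \eqn{\epsilon = (1 + \alpha)\,\lVert z - \Psi a_{LS}\rVert_2}
#' (`a_LS` the full least-squares solution), when the support reaches
#' `kmax`, or when the residual is numerically zero. Larger `alpha` never
#' yields a larger support on the same inputs, so `alpha` is the sparsity
#' knob tuned by F1 in [select_alpha()].
#'
#' @param z response vector.
#' @param Psi design matrix (rows = projections, columns = dictionary
#'   atoms). Identically zero columns are excluded from selection.
#' @param alpha stopping parameter, >= 0.
#' @param kmax maximum support size (default `min(ncol(Psi), 10)`).
#' @param stop_rule `"noise-energy"` for the criterion above, or
#'   `"relative"` to stop when the relative residual energy
#'   \eqn{\lVert r\rVert_2^2 / \lVert z\rVert_2^2} drops below `alpha`.
#'   Both are monotone in `alpha`.
#' @return an object of class `usdl_sparse_solution`: `support` (ordered as
#'   selected), `coefficients` (full-length, exact zeros off support),
#'   `residual_norms` (`||r||_2` after 0, 1, ... iterations), `stop_reason`
#'   (`"noise-floor"`, `"max-support"` or `"zero-residual"`), `alpha` and
#'   the stopping threshold `epsilon`.
#' @examples
#' set.seed(1)
#' Psi <- matrix(rnorm(80), 20, 4)
#' z <- 2 * Psi[, 2] - Psi[, 4]
#' omp(z, Psi, alpha = 0.05)$support
#' @export
omp <- function(z, Psi, alpha = 0.05, kmax = NULL,
                stop_rule = c("noise-energy", "relative")) {
  stop_rule <- match.arg(stop_rule)
  Psi <- as.matrix(Psi)
  z <- as.numeric(z)
  if (length(z) != nrow(Psi)) abort("`z` must match the rows of `Psi`.")
  if (!all(is.finite(z)) || !all(is.finite(Psi))) abort("`z` and `Psi` must be finite.")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    abort("`alpha` must be a single number >= 0.")
  }
  Q <- ncol(Psi)
  if (is.null(kmax)) kmax <- min(Q, 10L)
  kmax <- min(kmax, Q, nrow(Psi))

  col_norms <- unname(sqrt(colSums(Psi^2)))
  selectable <- col_norms > 0
  if (!any(selectable)) abort("`Psi` must have at least one nonzero column.")
  Psi_bar <- sweep(Psi[, selectable, drop = FALSE], 2L,
                   col_norms[selectable], "/")
  sel_idx <- which(selectable)

  z_norm <- sqrt(sum(z^2))
  empty <- function(reason, eps) {
    structure(list(support = integer(0), coefficients = numeric(Q),
                   residual_norms = z_norm, stop_reason = reason,
                   alpha = alpha, epsilon = eps,
                   labels = colnames(Psi)),
              class = "usdl_sparse_solution")
  }
  if (z_norm == 0) return(empty("zero-residual", 0))

  a_ls <- min_norm_ls(Psi[, selectable, drop = FALSE], z)
  r_ls <- z - Psi[, selectable, drop = FALSE] %*% a_ls
  eps <- if (stop_rule == "noise-energy") {
    (1 + alpha) * sqrt(sum(r_ls^2))
  } else {
    sqrt(alpha) * z_norm    # ||r||^2 / ||z||^2 <= alpha
  }

  support <- integer(0)
  r <- z
  r_norms <- z_norm
  coef_active <- numeric(0)
  reason <- "noise-floor"
  if (sqrt(sum(r^2)) > eps) {
    repeat {
      if (length(support) >= kmax) { reason <- "max-support"; break }
      corr <- abs(crossprod(Psi_bar, r))
      corr[match(support, sel_idx)] <- -Inf   # never reselect
      q_star <- sel_idx[which.max(corr)]      # ties -> lowest index
      if (!is.finite(max(corr)) || max(corr) <= 1e-14 * z_norm) {
        reason <- "noise-floor"; break        # nothing correlates; stalled
      }
      support <- c(support, q_star)
      A <- Psi[, support, drop = FALSE]
      coef_active <- min_norm_ls(A, z)
      r <- z - drop(A %*% coef_active)
      r_norms <- c(r_norms, sqrt(sum(r^2)))
      if (r_norms[length(r_norms)] <= 1e-12 * z_norm) { reason <- "zero-residual"; break }
      if (r_norms[length(r_norms)] <= eps) { reason <- "noise-floor"; break }
      if (length(support) >= kmax) { reason <- "max-support"; break }
    }
  }
  coefficients <- numeric(Q)
  coefficients[support] <- coef_active
  structure(
    list(support = support, coefficients = coefficients,
         residual_norms = r_norms, stop_reason = reason,
         alpha = alpha, epsilon = eps, labels = colnames(Psi)),
    class = "usdl_sparse_solution"
  )
}

# minimum-norm least squares via SVD (unique LS solution when full rank)
min_norm_ls <- function(A, b) {
  sv <- svd(A)
  pos <- sv$d > max(sv$d, 0) * 1e-12
  if (!any(pos)) return(numeric(ncol(A)))
  drop(sv$v[, pos, drop = FALSE] %*%
         (crossprod(sv$u[, pos, drop = FALSE], b) / sv$d[pos]))
}

#' @export
print.usdl_sparse_solution <- function(x, ...) {
  supp <- if (length(x$support)) paste(x$support, collapse = ", ") else "(empty)"
  cat(sprintf("<usdl_sparse_solution: support {%s}, %d iterations, stop: %s (alpha = %g)>\n",
              supp, length(x$support), x$stop_reason, x$alpha))
  invisible(x)
}

#' Solve every variable's sparse-recovery problem in a weak system
#'
#' Runs [omp()] on each variable's stacked response and design. Variables
#' flagged un-inferable (no usable experiments) get an all-zero row and a
#' warning record.
#'
#' @param ws a `usdl_weak_system` from [assemble()].
#' @param alpha,kmax,stop_rule passed to [omp()].
#' @return a list with `A_hat` (`N` by `Q` estimated connectivity matrix,
#'   rows named by variables, columns by dictionary labels) and `solutions`
#'   (named list of `usdl_sparse_solution`).
#' @export
solve_system <- function(ws, alpha = 0.05, kmax = NULL,
                         stop_rule = "noise-energy") {
  stopifnot(inherits(ws, "usdl_weak_system"))
  N <- length(ws$variables); Q <- length(ws$labels)
  A_hat <- matrix(0, N, Q, dimnames = list(ws$variables, ws$labels))
  solutions <- vector("list", N)
  names(solutions) <- ws$variables
  for (v in ws$variables) {
    Psi <- ws_design(ws, v)
    if (is.null(Psi)) {
      warn(sprintf("variable '%s' has no usable experiments; row left at zero.", v))
      next
    }
    colnames(Psi) <- ws$labels
    sol <- omp(ws_response(ws, v), Psi, alpha = alpha, kmax = kmax,
               stop_rule = stop_rule)
    A_hat[v, ] <- sol$coefficients
    solutions[[v]] <- sol
  }
  list(A_hat = A_hat, solutions = solutions)
}
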