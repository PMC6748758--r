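#' Mutual incoherence parameter (MIP)
#'
#' The maximum absolute cosine similarity over distinct column pairs of a
#' design matrix: 0 for orthogonal designs, 1 when two columns are
#' collinear. An a priori recoverability indicator — small MIP guarantees
#' recovery, but MIP is conservative because it also penalizes correlated
#' columns that take no part in the solution.
#'
#' @param Psi design matrix with at least two columns, none identically zero.
#' @return a scalar in `[0, 1]`.
#' @examples
#' mip(diag(5))          # 0
#' mip(cbind(1:3, 2 * (1:3), c(1, 0, 0)))  # 1 (duplicated direction)
#' @export
mip <- function(Psi) {
  Psi <- as.matrix(Psi)
  if (ncol(Psi) < 2L) abort("`Psi` needs at least two columns.")
  nrm <- sqrt(colSums(Psi^2))
  if (any(nrm == 0)) {
    abort(sprintf("column %d of `Psi` is identically zero.", which(nrm == 0)[1]))
  }
  G <- crossprod(sweep(Psi, 2L, nrm, "/"))
  diag(G) <- 0
  max(abs(G))
}

#' Exact recovery coefficient (ERC)
#'
#' For a candidate support `S`,
#' \eqn{ERC(S) = 1 - \max_{q' \notin S} \lVert (\bar\Psi_S^\top \bar\Psi_S)^{-1} \bar\Psi_S^\top \bar\psi_{q'} \rVert_1}
#' over the unit-normalized columns \eqn{\bar\psi_q}. `ERC(S) > 0` at the
#' true support is necessary for OMP (and convex relaxation) to recover it
#' exactly; computed at the *estimated* support it serves as an a
#' posteriori accuracy indicator. When `S` covers every column the maximum
#' runs over an empty set and the value is 1 by convention.
#'
#' @param Psi design matrix.
#' @param S support: column indices (or labels) of the candidate solution.
#' @return a scalar `<= 1`.
#' @export
erc <- function(Psi, S) {
  Psi <- as.matrix(Psi)
  if (is.character(S)) S <- match(S, colnames(Psi))
  S <- as.integer(S)
  if (length(S) == 0L || anyNA(S) || any(S < 1L | S > ncol(Psi))) {
    abort("`S` must be a non-empty set of valid column indices.")
  }
  S <- unique(S)
  nrm <- sqrt(colSums(Psi^2))
  if (any(nrm == 0)) abort(sprintf("column %d of `Psi` is identically zero.",
                                   which(nrm == 0)[1]))
  Psi_bar <- sweep(Psi, 2L, nrm, "/")
  off <- setdiff(seq_len(ncol(Psi)), S)
  if (length(off) == 0L) return(1)
  A <- Psi_bar[, S, drop = FALSE]
  G <- crossprod(A)
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R) || rcond(G) < 1e-12) {
    abort("support columns are rank deficient; ERC is undefined for this support.")
  }
  # solve the normal equations for all off-support columns at once
  C <- backsolve(R, forwardsolve(t(R), crossprod(A, Psi_bar[, off, drop = FALSE])))
  1 - max(colSums(abs(C)))
}

#' Per-column signal-to-noise ratios
#'
#' `SNR(q) = ||psi_q||_2 / ||e||_2` for a residual/noise vector `e`.
#'
#' @param Psi design matrix.
#' @param e residual or noise vector.
#' @return a length-`Q` vector; `Inf` for every column when `e` is exactly
#'   zero (noiseless data).
#' @export
snr <- function(Psi, e) {
  Psi <- as.matrix(Psi)
  e_norm <- sqrt(sum(as.numeric(e)^2))
  nrm <- sqrt(colSums(Psi^2))
  if (e_norm == 0) return(rep(Inf, ncol(Psi)))
  nrm / e_norm
}

#' Smallest eigenvalue of the normalized support Gram matrix
#'
#' @param Psi design matrix.
#' @param S support column indices (or labels).
#' @return the smallest eigenvalue of
#'   \eqn{\bar\Psi_S^\top \bar\Psi_S}; lies in `(0, 1]` for full-rank
#'   normalized atoms, and 0 (with a warning) under rank deficiency.
#' @export
lambda_min <- function(Psi, S) {
  Psi <- as.matrix(Psi)
  if (is.character(S)) S <- match(S, colnames(Psi))
  S <- unique(as.integer(S))
  if (length(S) == 0L || anyNA(S) || any(S < 1L | S > ncol(Psi))) {
    abort("`S` must be a non-empty set of valid column indices.")
  }
  nrm <- sqrt(colSums(Psi[, S, drop = FALSE]^2))
  if (any(nrm == 0)) abort("support contains an identically zero column.")
  A <- sweep(Psi[, S, drop = FALSE], 2L, nrm, "/")
  ev <- min(eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-12) {
    warn("support columns are rank deficient; smallest Gram eigenvalue is 0.")
    ev <- max(ev, 0)
  }
  ev
}

#' Coefficient-magnitude recovery-guarantee check
#'
#' Under noise, OMP with the standard stopping criterion provably returns
#' the true support when every true coefficient is large enough relative to
#' the noise and the conditioning of the support:
#' \eqn{|a_q| \ge 2 / (SNR(q) \cdot ERC(S) \cdot \lambda_{min}(S))}.
#' Positivity of `ERC(S)` is a necessary condition; when it fails the
#' guarantee is reported as unavailable. In the noiseless limit the
#' thresholds vanish and every coefficient passes.
#'
#' @param a coefficient vector (length `Q`).
#' @param Psi design matrix.
#' @param S support column indices the guarantee is evaluated at.
#' @param e residual/noise vector.
#' @return a tibble with one row per column: `q`, `coefficient`,
#'   `threshold`, `passes`; the attribute `"available"` is `FALSE` (and
#'   `passes` is `NA`) when `ERC(S) <= 0` or the support is degenerate.
#' @export
guarantee_check <- function(a, Psi, S, e) {
  Psi <- as.matrix(Psi)
  Q <- ncol(Psi)
  stopifnot(length(a) == Q)
  erc_s <- erc(Psi, S)
  lmin <- lambda_min(Psi, S)
  snr_q <- snr(Psi, e)
  out <- tibble::tibble(q = seq_len(Q), coefficient = as.numeric(a))
  if (erc_s <= 0 || lmin <= 0) {
    out$threshold <- NA_real_
    out$passes <- NA
    attr(out, "available") <- FALSE
    attr(out, "erc") <- erc_s
    return(out)
  }
  out$threshold <- 2 / (snr_q * erc_s * lmin)   # 0 when SNR = Inf (noiseless)
  out$passes <- abs(out$coefficient) >= out$threshold
  attr(out, "available") <- TRUE
  attr(out, "erc") <- erc_s
  attr(out, "lambda_min") <- lmin
  out
}

#' Full recoverability diagnostics for a solved weak system
#'
#' Computes MIP once per variable's design, plus ERC, the smallest support
#' Gram eigenvalue and the residual norm at each variable's estimated
#' support (a posteriori, mirroring how the diagnostics accompany a fit in
#' practice where the true support is unknown).
#'
#' @param ws a `usdl_weak_system`.
#' @param solutions named list of `usdl_sparse_solution` from
#'   [solve_system()].
#' @return a tibble with one row per variable: `variable`, `mip`,
#'   `support_size`, `erc`, `lambda_min`, `residual_norm`.
#' @export
recovery_diagnostics <- function(ws, solutions) {
  rows <- lapply(ws$variables, function(v) {
    sol <- solutions[[v]]
    Psi <- ws_design(ws, v)
    if (is.null(Psi) || is.null(sol)) {
      return(tibble::tibble(variable = v, mip = NA_real_, support_size = 0L,
                            erc = NA_real_, lambda_min = NA_real_,
                            residual_norm = NA_real_))
    }
    e_val <- if (length(sol$support) > 0L) {
      tryCatch(erc(Psi, sol$support), error = function(err) NA_real_)
    } else NA_real_
    l_val <- if (length(sol$support) > 0L) {
      tryCatch(lambda_min(Psi, sol$support), error = function(err) NA_real_)
    } else NA_real_
    tibble::tibble(
      variable = v,
      mip = mip(Psi),
      support_size = length(sol$support),
      erc = e_val,
      lambda_min = l_val,
      residual_norm = tail(sol$residual_norms, 1L)
    )
  })
  dplyr::bind_rows(rows)
}

#' Random sparse-recovery benchmark instance
#'
#' A standard compressed-sensing test bed: a Gaussian design with
#' unit-normalized columns, a `k`-sparse coefficient vector with
#' magnitude-one entries of random sign, and optional additive Gaussian
#' noise. Used to validate OMP against exhaustive search and to check the
#' ERC necessary condition empirically.
#'
#' @param n_rows,n_cols design dimensions.
#' @param k sparsity of the true coefficient vector.
#' @param noise_sd standard deviation of additive Gaussian noise on `z`.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return a list with `Psi`, `a` (true coefficients), `support`
#'   (sorted true support) and `z`.
#' @export
recovery_instance <- function(n_rows = 20L, n_cols = 8L, k = 2L,
                              noise_sd = 0, seed) {
  if (missing(seed)) abort("`seed` is required.")
  with_seed(seed, {
    Psi <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
    Psi <- sweep(Psi, 2L, sqrt(colSums(Psi^2)), "/")
    support <- sort(sample.int(n_cols, k))
    a <- numeric(n_cols)
    a[support] <- sample(c(-1, 1), k, replace = TRUE)
    z <- drop(Psi %*% a)
    if (noise_sd > 0) z <- z + rnorm(n_rows, sd = noise_sd)
    list(Psi = Psi, a = a, support = support, z = z)
  })
}
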