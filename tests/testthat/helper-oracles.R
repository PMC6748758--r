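# independent oracles used across tests

# exhaustive best-subset search: smallest-residual support of size <= kmax
brute_force_support <- function(z, Psi, kmax) {
  Q <- ncol(Psi)
  best <- list(rss = Inf, support = integer(0))
  for (k in seq_len(kmax)) {
    for (S in utils::combn(Q, k, simplify = FALSE)) {
      fit <- qr.fitted(qr(Psi[, S, drop = FALSE]), z)
      rss <- sum((z - fit)^2)
      if (rss < best$rss - 1e-12) best <- list(rss = rss, support = S)
    }
  }
  best
}

# ERC by dense pseudo-inverse (independent of the normal-equations path)
erc_pinv <- function(Psi, S) {
  Psi_bar <- sweep(Psi, 2L, sqrt(colSums(Psi^2)), "/")
  off <- setdiff(seq_len(ncol(Psi)), S)
  if (length(off) == 0L) return(1)
  P <- pracma::pinv(Psi_bar[, S, drop = FALSE])
  1 - max(apply(abs(P %*% Psi_bar[, off, drop = FALSE]), 2L, sum))
}

# central-difference derivative of a test-function family on a grid
central_diff <- function(family, t, h = 1e-5) {
  (tf_evaluate(family, t + h) - tf_evaluate(family, t - h)) / (2 * h)
}

# noiseless linear-ODE experiment via the matrix exponential (no solver error)
linear_ode_experiment <- function(A, x0, T_final, n = 4001L) {
  g <- seq(0, T_final, length.out = n)
  X <- t(vapply(g, function(t) as.numeric(Matrix::expm(A * t) %*% x0),
                numeric(length(x0))))
  colnames(X) <- paste0("x", seq_along(x0))
  list(grid = g, states = X)
}
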