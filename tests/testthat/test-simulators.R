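test_that("protein time-course collapses onto the deterministic trajectory without noise", {
  sim <- simulate_protein_network(experiments = "none", times = c(0, 2, 5, 9),
                                  cells_per_time = 3, measurement_sd = 0,
                                  heterogeneity = 0, seed = 1)
  det <- protein_network_trajectory(c(0, 2, 5, 9))
  for (v in c("P1", "P2", "P3")) {
    d <- sim$data[sim$data$variable == v, ]
    expect_equal(d$value, det[match(d$time, c(0, 2, 5, 9)), v], tolerance = 1e-7)
  }
})

test_that("the high-uncertainty regime doubles every stochastic sd (4x variance)", {
  t_star <- 4
  v <- sapply(c("low", "high"), function(nz) {
    sim <- simulate_protein_network(experiments = "none", times = t_star,
                                    cells_per_time = 1000, noise = nz, seed = 33)
    stats::var(sim$data$value[sim$data$variable == "P2"])
  })
  ratio <- v["high"] / v["low"]
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("an inhibited species stays at baseline up to measurement noise", {
  sim <- simulate_protein_network(experiments = "inhibit_P2", times = 0:8,
                                  cells_per_time = 10, seed = 2)
  p2 <- sim$data$value[sim$data$variable == "P2"]
  expect_lt(max(abs(p2 - 0.2)), 5 * 0.05)
  expect_error(simulate_protein_network(experiments = "inhibit_P9", seed = 1),
               "invalid intervention")
})

test_that("protein simulation is reproducible and correctly annotated", {
  s1 <- simulate_protein_network(times = 0:4, cells_per_time = 2, seed = 10)
  s2 <- simulate_protein_network(times = 0:4, cells_per_time = 2, seed = 10)
  expect_identical(s1$data, s2$data)
  expect_setequal(unique(s1$interventions$type), c("none", "inhibition"))
  expect_equal(nrow(s1$truth$edges), 3L)  # coarse cycle P1 -> P2 -> P3 -| P1
  expect_equal(sort(s1$truth$edges$sign), c(-1, 1, 1))
})

test_that("the conserved moiety P1 + C is constant when its sinks are off", {
  r <- protein_rates(d1 = 0, kdC = 0)
  tr <- protein_network_trajectory(seq(0, 10, by = 0.5), rates = r)
  total <- tr[, "P1"] + tr[, "C"]
  expect_lt(diff(range(total)), 1e-6 * total[1])
})

test_that("drift-only OU decays monotonically from a transient start", {
  sim <- simulate_ou(N = 6, P = 3, regime = "transient", sigma = 0,
                     T_final = 6, seed = 5)
  for (ex in sim$experiments) {
    norms <- sqrt(rowSums(ex$states^2))
    expect_true(all(diff(norms) < 0))
  }
})

test_that("the random graph respects the out-degree cap and the shift stabilizes", {
  sim <- simulate_ou(N = 20, P = 1, T_final = 0.1, seed = 8)
  A <- sim$truth$A
  offdiag_per_col <- colSums(A != 0) - 1L   # column j: outgoing edges of node j
  expect_true(all(offdiag_per_col <= 3L))
  expect_true(all(offdiag_per_col >= 1L))
  expect_true(all(Re(eigen(sim$truth$drift, only.values = TRUE)$values) > 0))
  expect_true(all(A[row(A) != col(A)][A[row(A) != col(A)] != 0] > 0))
})

test_that("empirical stationary covariance satisfies the Lyapunov equation", {
  sim <- simulate_ou(N = 10, P = 20, regime = "stationary", sigma = 1,
                     T_final = 50, seed = 4)
  M <- sim$truth$drift
  X <- do.call(rbind, lapply(sim$experiments, function(e) e$states))
  S <- crossprod(X) / nrow(X)
  resid <- M %*% S + S %*% t(M) - diag(10)
  expect_lt(norm(resid, "F") / norm(diag(10), "F"), 0.15)
  # the exact Lyapunov solution is machine-precise
  St <- sim$truth$Sigma
  expect_lt(norm(M %*% St + St %*% t(M) - diag(10), "F"), 1e-10)
})

test_that("OU simulation is bit-reproducible from its seed", {
  s1 <- simulate_ou(N = 5, P = 2, T_final = 1, seed = 42)
  s2 <- simulate_ou(N = 5, P = 2, T_final = 1, seed = 42)
  expect_identical(s1$experiments, s2$experiments)
  expect_identical(s1$truth$A, s2$truth$A)
})

test_that("Lorenz96 stays at its fixed point and obeys the energy identity", {
  sim <- simulate_lorenz96(N = 6, P = 1, T_final = 2, x0 = rep(8, 6), seed = 1)
  st <- sim$experiments[[1]]$states
  expect_lt(max(abs(st - 8)), 1e-6)
  # energy identity d/dt sum x^2 = 2 sum x (F - x) along a chaotic trajectory
  sim2 <- simulate_lorenz96(N = 6, P = 1, T_final = 3, seed = 2)
  ex <- sim2$experiments[[1]]
  energy <- rowSums(ex$states^2)
  rhs <- 2 * rowSums(ex$states * (8 - ex$states))
  lhs_total <- energy[length(energy)] - energy[1]
  rhs_total <- quadrature(rhs, ex$grid)
  expect_equal(lhs_total, rhs_total, tolerance = 1e-4 * max(1, abs(lhs_total)))
  expect_error(simulate_lorenz96(N = 3, seed = 1), ">= 4")
})

test_that("Lorenz96 ground truth has the known sparse quadratic structure", {
  sim <- simulate_lorenz96(N = 8, P = 1, T_final = 0.1, seed = 3)
  A <- sim$truth$A
  expect_equal(ncol(A), (8 + 3) * 8 / 2)
  # per row: one linear term (self) and two quadratic terms; F is the known
  # forcing reported separately, completing the four terms of the equation
  expect_equal(unname(rowSums(A != 0)), rep(3, 8))
  expect_equal(sim$truth$forcing, 8)
  expect_equal(A[1, "x1"], -1)
  labels_row1 <- colnames(A)[A[1, ] != 0]
  expect_setequal(labels_row1, c("x1", "x2*x8", "x7*x8"))
})
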