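test_that("quadrature rules hit their exactness classes", {
  g <- seq(0, 1, by = 0.1)
  expect_equal(quadrature(g, g), 0.5)                 # trapezoid exact for linear
  expect_equal(quadrature(rep(1, 7), c(0, 0.1, 0.3, 0.35, 0.8, 1.4, 2)), 2)
  g2 <- seq(0, 2, length.out = 101)
  expect_equal(quadrature(g2^3, g2, "simpson"), 4, tolerance = 1e-10)
  # odd interval count: simpson falls back to trapezoid on the tail
  g3 <- seq(0, 1, length.out = 4)
  expect_equal(quadrature(rep(2, 4), g3, "simpson"), 2)
  expect_error(quadrature(1:3, c(0, 2, 1)), "increasing")
})

test_that("derivative projection by parts never differentiates the data", {
  g <- seq(0, 1, length.out = 101)
  fam_const <- tf_fourier(1, 0)
  expect_equal(drop(project_derivative(g, g, fam_const)), 1)  # x = t, phi = 1
  g2 <- seq(0, 2 * pi, length.out = 2001)
  fam <- tf_fourier(2 * pi, 1)
  z <- project_derivative(sin(g2), g2, fam)
  expect_lt(abs(z[2]), 1e-6)  # <cos, sin> = 0 over a full period
  # x = e^t against phi(t) = t: closed form integral of t e^t over [0,1] is 1
  g3 <- seq(0, 1, length.out = 2001)
  hat <- tf_bspline(1, 0, degree = 1)   # second member is exactly t on [0,1]
  z3 <- project_derivative(exp(g3), g3, hat)
  expect_equal(z3[2], 1, tolerance = 1e-6)
  expect_error(project_derivative(exp(g3), g3, tf_fourier(2, 1)), "domain")
})

test_that("parts projection equals direct quadrature of <xdot, phi> for all kinds", {
  g <- seq(0, 3, length.out = 6001)
  x <- sin(2 * g) + 0.5 * g          # analytic trajectory, xdot known
  xdot <- 2 * cos(2 * g) + 0.5
  fams <- list(tf_fourier(3, 5), tf_peaky_fourier(3, 3, 12), tf_bspline(3, 4, 3))
  for (fam in fams) {
    parts <- project_derivative(x, g, fam, rule = "simpson")
    phi <- tf_evaluate(fam, g)
    direct <- quadrature(phi * xdot, g, rule = "simpson")
    expect_lt(max(abs(parts - direct)), 1e-6)
  }
})

test_that("dictionary projection matches closed forms and a refinement oracle", {
  g <- seq(0, 1, length.out = 101)
  fam <- tf_fourier(1, 0)
  expect_equal(project_dictionary(matrix(1, 101, 1), g, fam)[1, 1], 1)
  g2 <- seq(0, 2 * pi, length.out = 2001)
  fam2 <- tf_fourier(2 * pi, 1)
  P <- project_dictionary(matrix(sin(g2)), g2, fam2)
  expect_lt(abs(P[3, 1]), 1e-6)       # <sin, cos> = 0
  # refinement oracle: coarse-grid projection near a 10x-finer re-quadrature
  f <- function(t) cbind(sin(3 * t), exp(-t))
  gc <- seq(0, 2, length.out = 2001); gf <- seq(0, 2, length.out = 20001)
  fam3 <- tf_fourier(2, 3)
  expect_lt(max(abs(project_dictionary(f(gc), gc, fam3) -
                    project_dictionary(f(gf), gf, fam3))), 1e-6)
  expect_error(project_dictionary(matrix(c(1, NA), 2, 1), c(0, 2), fam3))
})

test_that("assembly stacks blocks with correct shapes and bookkeeping", {
  ex <- linear_ode_experiment(matrix(c(-1, 0.4, 0, -0.7), 2, 2, byrow = TRUE),
                              c(2, -1), T_final = 4, n = 401)
  fam <- tf_fourier(4, 2)                      # M = 5
  dict <- dict_quadratic(2)                    # Q = 5
  ws <- assemble(list(e1 = ex), dict, fam)
  expect_equal(dim(ws_design(ws, "x1")), c(5L, 5L))
  expect_length(ws_response(ws, "x1"), 5L)
  # replication invariance: stacking identical experiments leaves LS unchanged
  ws3 <- assemble(list(e1 = ex, e2 = ex, e3 = ex), dict, fam)
  a1 <- qr.solve(ws_design(ws, "x1"), ws_response(ws, "x1"))
  a3 <- qr.solve(ws_design(ws3, "x1"), ws_response(ws3, "x1"))
  expect_equal(a1, a3, tolerance = 1e-8)
})

test_that("experiment order permutes rows consistently", {
  A <- matrix(c(-0.5, 0.2, 0.1, -0.9), 2, 2, byrow = TRUE)
  ex1 <- linear_ode_experiment(A, c(1, 2), 3, n = 801)
  ex2 <- linear_ode_experiment(A, c(-2, 1), 3, n = 801)
  dict <- dict_linear(2); fam <- tf_fourier(3, 4)
  ws_a <- assemble(list(p = ex1, q = ex2), dict, fam)
  ws_b <- assemble(list(q = ex2, p = ex1), dict, fam)
  for (v in c("x1", "x2")) {
    sa <- qr.solve(ws_design(ws_a, v), ws_response(ws_a, v))
    sb <- qr.solve(ws_design(ws_b, v), ws_response(ws_b, v))
    expect_equal(sa, sb, tolerance = 1e-10)
  }
})

test_that("noiseless linear dynamics satisfy the weak system at quadrature error", {
  A <- matrix(c(-1, 0, 0.2, 0.5, -0.8, 0, 0, 0.3, -0.6), 3, 3, byrow = TRUE)
  ex <- linear_ode_experiment(A, c(3, -2, 1), T_final = 10, n = 8001)
  ws <- assemble(list(e = ex), dict_linear(3), tf_fourier(10, 20), rule = "simpson")
  for (n in 1:3) {
    v <- paste0("x", n)
    r <- ws_response(ws, v) - ws_design(ws, v) %*% A[n, ]
    expect_lt(sqrt(sum(r^2)), 1e-6)
  }
})

test_that("interventions mask a variable's own equation; forcing is subtracted", {
  A <- matrix(c(-0.5, 0, 0.3, -0.8), 2, 2, byrow = TRUE)
  ex1 <- linear_ode_experiment(A, c(2, 1), 3, n = 801)
  ex2 <- linear_ode_experiment(A, c(1, -1), 3, n = 801)
  iv <- data.frame(experiment = "e2", variable = "x1", type = "inhibition")
  ws <- assemble(list(e1 = ex1, e2 = ex2), dict_linear(2), tf_fourier(3, 3),
                 interventions = iv)
  expect_equal(unname(ws$mask["x1", ]), c(TRUE, FALSE))
  expect_equal(length(ws_response(ws, "x1")), 7L)   # one block of M = 7
  expect_equal(length(ws_response(ws, "x2")), 14L)  # both blocks
  # all experiments masked -> un-inferable
  iv2 <- data.frame(experiment = c("e1", "e2"), variable = "x1",
                    type = "inhibition")
  expect_warning(
    ws2 <- assemble(list(e1 = ex1, e2 = ex2), dict_linear(2), tf_fourier(3, 3),
                    interventions = iv2),
    "un-inferable")
  expect_null(ws_design(ws2, "x1"))
  # known forcing: xdot = -x + F with F known reduces to the linear part
  Ff <- 2
  g <- seq(0, 5, length.out = 4001)
  x <- Ff + (1 - Ff) * exp(-g)       # solution of xdot = -(x) + F, x(0) = 1
  ex_f <- list(grid = g, states = cbind(x1 = x, x2 = exp(-g)))
  ws_f <- assemble(list(e = ex_f), dict_linear(2), tf_fourier(5, 6),
                   known_contributions = list(x1 = Ff))
  a <- qr.solve(ws_design(ws_f, "x1"), ws_response(ws_f, "x1"))
  expect_equal(unname(a), c(-1, 0), tolerance = 1e-5)
})

test_that("weak systems export and import losslessly as text + JSON", {
  ex <- linear_ode_experiment(matrix(c(-1, 0.4, 0, -0.7), 2, 2, byrow = TRUE),
                              c(2, -1), 4, n = 401)
  ws <- assemble(list(e1 = ex), dict_linear(2), tf_fourier(4, 2))
  dir <- withr::local_tempdir()
  export_weak_system(ws, dir)
  ws2 <- import_weak_system(dir)
  expect_equal(ws2$blocks[[1]]$Psi, ws$blocks[[1]]$Psi, tolerance = 1e-12)
  expect_equal(ws2$blocks[[1]]$Z, ws$blocks[[1]]$Z, tolerance = 1e-12)
  expect_equal(ws2$mask, ws$mask)
  expect_equal(ws2$labels, ws$labels)
})
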