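test_that("edge lists are derived from nonzero entries with sign semantics", {
  A0 <- matrix(0, 3, 3, dimnames = list(paste0("x", 1:3), paste0("x", 1:3)))
  expect_equal(nrow(edges_from_matrix(A0)), 0L)
  A <- A0; A["x2", "x1"] <- 3
  e <- edges_from_matrix(A)
  expect_equal(e$source, "x1"); expect_equal(e$target, "x2")
  expect_equal(e$sign, 1)
  # diagonal handling
  A["x1", "x1"] <- -1
  expect_equal(nrow(edges_from_matrix(A)), 1L)
  expect_equal(nrow(edges_from_matrix(A, include_diagonal = TRUE)), 2L)
  # quadratic atoms become hyper-edges labeled by the atom
  Aq <- matrix(0, 3, 9, dimnames = list(paste0("x", 1:3), dict_quadratic(3)$labels))
  Aq["x3", "x1*x2"] <- 2
  eq <- edges_from_matrix(Aq)
  expect_equal(eq$source, "x1*x2"); expect_equal(eq$target, "x3")
})

test_that("precision, recall and F1 follow their counting definitions", {
  truth <- tibble::tibble(source = c("a", "b", "c", "d"), target = "z",
                          coefficient = 1, sign = 1)
  expect_equal(unlist(precision_recall(truth, truth)[, c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))
  pred <- rbind(truth, tibble::tibble(source = "e", target = "z",
                                      coefficient = 1, sign = 1))
  pr <- precision_recall(pred, truth)
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 1)
  expect_equal(pr$f1, 8 / 9)
  # empty prediction convention: precision 1, recall 0, f1 0
  pr0 <- precision_recall(truth[0, ], truth)
  expect_equal(unlist(pr0[, c("precision", "recall", "f1")]),
               c(precision = 1, recall = 0, f1 = 0))
})

test_that("scores agree with an exhaustively counted confusion matrix", {
  set.seed(6)
  for (rep in 1:20) {
    A_t <- matrix(rbinom(25, 1, 0.3) * rnorm(25), 5, 5,
                  dimnames = list(paste0("x", 1:5), paste0("x", 1:5)))
    A_p <- matrix(rbinom(25, 1, 0.3) * rnorm(25), 5, 5,
                  dimnames = dimnames(A_t))
    pr <- precision_recall(edges_from_matrix(A_p), edges_from_matrix(A_t))
    tp <- fp <- fn <- 0L
    for (i in 1:5) for (j in 1:5) {
      if (i == j) next
      p <- A_p[i, j] != 0; t <- A_t[i, j] != 0
      tp <- tp + (p && t); fp <- fp + (p && !t); fn <- fn + (!p && t)
    }
    expect_equal(pr$tp, tp); expect_equal(pr$fp, fp); expect_equal(pr$fn, fn)
  }
})

test_that("sign-aware matching penalizes sign flips", {
  truth <- tibble::tibble(source = "a", target = "b", coefficient = 1, sign = 1)
  pred <- tibble::tibble(source = "a", target = "b", coefficient = -2, sign = -1)
  expect_equal(precision_recall(pred, truth)$f1, 1)
  expect_equal(precision_recall(pred, truth, sign_aware = TRUE)$f1, 0)
})

test_that("rmse follows its elementwise definition", {
  A <- matrix(rnorm(16), 4, 4)
  expect_equal(rmse(A, A), 0)
  B <- A; B[2, 3] <- B[2, 3] + 0.8
  expect_equal(rmse(B, A), 0.8 / 4)
  C <- matrix(rnorm(16), 4, 4)
  expect_equal(rmse(A, C), sqrt(mean((A - C)^2)))
  expect_error(rmse(A, matrix(0, 2, 2)), "shape")
})

test_that("alpha selection maximizes F1 with a complete score table", {
  sim <- simulate_ou(N = 5, P = 10, regime = "transient", sigma = 0.2,
                     T_final = 6, x0_sd = 5, seed = 12)
  cfg <- usdl_config(test_functions = "fourier:6", kmax = 4)
  one <- select_alpha(sim, sim$truth, alpha_grid = 0.1, config = cfg)
  expect_equal(one$best_alpha, 0.1)
  sel <- select_alpha(sim, sim$truth, alpha_grid = seq(0.01, 0.5, length.out = 8),
                      config = cfg)
  expect_equal(nrow(sel$scores), 8L)
  expect_true(all(is.finite(sel$scores$f1)))
  expect_equal(max(sel$scores$f1), 1)  # noiseless-ish recoverable system
  expect_equal(sel$scores$f1[sel$scores$alpha == sel$best_alpha],
               max(sel$scores$f1))
})

test_that("stability selection reduces to a single run at B = 1 and is binary at fraction 1", {
  sim <- simulate_ou(N = 5, P = 8, regime = "transient", sigma = 0.1,
                     T_final = 6, x0_sd = 5, seed = 13)
  cfg <- usdl_config(test_functions = "fourier:6", kmax = 4, alpha = 0.1)
  single <- run_usdl(sim, cfg)
  st1 <- stability_selection(sim, cfg, B = 1, fraction = 1, threshold = 0.8, seed = 1)
  expect_setequal(paste(st1$consensus$source, st1$consensus$target),
                  paste(single$edges$source, single$edges$target))
  st <- stability_selection(sim, cfg, B = 5, fraction = 1, threshold = 0.8, seed = 1)
  expect_true(all(st$frequencies$frequency %in% c(0, 1)))
  # strong-signal consensus equals the truth
  st20 <- stability_selection(sim, cfg, B = 20, fraction = 0.8, threshold = 0.8, seed = 2)
  expect_setequal(paste(st20$consensus$source, st20$consensus$target),
                  paste(sim$truth$edges$source, sim$truth$edges$target))
})

test_that("the pipeline runs end to end deterministically on both data modes", {
  sim <- simulate_ou(N = 4, P = 6, regime = "transient", sigma = 0.1,
                     T_final = 5, x0_sd = 5, seed = 14)
  cfg <- usdl_config(test_functions = "fourier:5", kmax = 3, alpha = 0.2)
  f1 <- run_usdl(sim, cfg)
  f2 <- run_usdl(sim, cfg)
  expect_identical(f1$A_hat, f2$A_hat)
  expect_s3_class(f1$diagnostics, "tbl_df")
  expect_true(all(c("mip", "erc", "support_size") %in% names(f1$diagnostics)))
  # time-course mode goes through collocation on long-format data
  simp <- simulate_protein_network(times = 0:8, cells_per_time = 4, seed = 3)
  cfg_tc <- usdl_config(mode = "timecourse", test_functions = "fourier:8", kmax = 3,
                        alpha = 0.2)
  fit_tc <- run_usdl(simp$data, cfg_tc, interventions = simp$interventions)
  expect_equal(rownames(fit_tc$A_hat), c("P1", "P2", "P3"))
  expect_equal(colnames(fit_tc$A_hat), c("P1", "P2", "P3"))
  expect_true(is.finite(fit_tc$mip))
})

test_that("tidiers and autoplot methods produce well-formed objects", {
  sim <- simulate_ou(N = 4, P = 6, regime = "transient", sigma = 0.1,
                     T_final = 5, x0_sd = 5, seed = 15)
  cfg <- usdl_config(test_functions = "fourier:5", kmax = 3, alpha = 0.2)
  fit <- run_usdl(sim, cfg)
  td <- tidy(fit)
  expect_true(all(c("variable", "term", "estimate") %in% names(td)))
  expect_true(all(td$estimate != 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_s3_class(autoplot(fit), "ggplot")
  sel <- select_alpha(sim, sim$truth, alpha_grid = c(0.1, 0.3), config = cfg)
  expect_s3_class(autoplot(sel), "ggplot")
  expect_equal(nrow(tidy(sel)), 2L)
  st <- stability_selection(sim, cfg, B = 2, fraction = 0.8, seed = 1)
  expect_s3_class(autoplot(st), "ggplot")
  tr <- fit_collocation(data.frame(time = 0:10, value = sin(0:10)), lambda = 1)
  expect_s3_class(glance(tr), "tbl_df")
  expect_equal(nrow(augment(tr, t = c(0, 5, 10))), 3L)
})
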