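#' Numerical quadrature on a (possibly uneven) time grid
#'
#' @param values function values on the grid (vector), or a matrix with one
#'   column per function (each column integrated separately).
#' @param grid strictly increasing time grid with at least two points.
#' @param rule `"trapezoid"` (valid on uneven grids) or `"simpson"`
#'   (composite; falls back to the trapezoid rule on uneven grids, and on
#'   the trailing interval when the number of intervals is odd).
#' @return the integral approximation: a scalar, or one value per column.
#' @export
quadrature <- function(values, grid, rule = c("trapezoid", "simpson")) {
  rule <- match.arg(rule)
  w <- quad_weights(grid, rule)
  if (is.matrix(values)) {
    if (nrow(values) != length(grid)) abort("`values` rows must match `grid` length.")
    drop(crossprod(values, w))
  } else {
    if (length(values) != length(grid)) abort("`values` must match `grid` length.")
    sum(w * values)
  }
}

# quadrature weights so that integral ~= sum(w * f(grid))
quad_weights <- function(grid, rule = "trapezoid") {
  n <- length(grid)
  if (n < 2L) abort("quadrature needs >= 2 grid points.")
  h <- diff(grid)
  if (any(h <= 0)) abort("`grid` must be strictly increasing.")
  w <- numeric(n)
  if (rule == "simpson") {
    even <- diff(range(h)) <= 1e-8 * mean(h)
    if (even && n >= 3L) {
      hh <- mean(h)
      n_int <- n - 1L
      n_pairs <- n_int %/% 2L
      idx <- 1L
      for (p in seq_len(n_pairs)) {
        w[idx] <- w[idx] + hh / 3
        w[idx + 1L] <- w[idx + 1L] + 4 * hh / 3
        w[idx + 2L] <- w[idx + 2L] + hh / 3
        idx <- idx + 2L
      }
      if (n_int %% 2L == 1L) {  # trailing odd interval: trapezoid
        w[n - 1L] <- w[n - 1L] + hh / 2
        w[n] <- w[n] + hh / 2
      }
      return(w)
    }
    # uneven grid: fall back to trapezoid
  }
  w[1L] <- h[1L] / 2
  w[n] <- h[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (h[-length(h)] + h[-1L]) / 2
  w
}

#' Project a trajectory's derivative onto test functions by parts
#'
#' Computes \eqn{z_m = \langle \dot x, \varphi_m\rangle} for every member of
#' a test-function family via the integration-by-parts identity
#' \eqn{z_m = x(t)\varphi_m(t)\big|_0^T - \langle x, \dot\varphi_m\rangle},
#' so the data are never differentiated; only the test functions are, and
#' their derivatives are exact. The boundary term is retained (test
#' functions are not forced to vanish at the endpoints). For stochastic
#' paths the same identity applies pathwise with deterministic smooth test
#' functions; the diffusion contribution lands in the residual.
#'
#' @param x trajectory values on `grid`.
#' @param grid strictly increasing times spanning the family domain
#'   `[0, T_final]` (both endpoints must be on the grid, since the boundary
#'   term needs them).
#' @param family a [usdl_test_family][test_functions].
#' @param rule quadrature rule, see [quadrature()].
#' @return a length-`M` vector, one entry per test function.
#' @export
project_derivative <- function(x, grid, family, rule = "trapezoid") {
  stopifnot(inherits(family, "usdl_test_family"))
  n <- length(grid)
  if (length(x) != n) abort("`x` must match `grid` length.")
  tol <- 1e-8 * max(family$T_final, 1)
  if (abs(grid[1]) > tol || abs(grid[n] - family$T_final) > tol) {
    abort("the family domain [0, T_final] must coincide with the trajectory span (boundary values are required).")
  }
  phi0 <- tf_evaluate(family, grid[1])
  phiT <- tf_evaluate(family, grid[n])
  dphi <- tf_evaluate(family, grid, deriv = 1L)
  boundary <- x[n] * drop(phiT) - x[1] * drop(phi0)
  boundary - quadrature(dphi * x, grid, rule)
}

#' Project dictionary evaluations onto test functions
#'
#' Computes the design block \eqn{\Psi_{mq} = \langle \psi_q(x), \varphi_m\rangle}.
#'
#' @param psi_values `length(grid)` by `Q` matrix of dictionary evaluations
#'   along the trajectory.
#' @param grid strictly increasing times inside the family domain.
#' @param family a [usdl_test_family][test_functions].
#' @param rule quadrature rule.
#' @return an `M` by `Q` matrix.
#' @export
project_dictionary <- function(psi_values, grid, family, rule = "trapezoid") {
  stopifnot(inherits(family, "usdl_test_family"))
  psi_values <- as.matrix(psi_values)
  if (nrow(psi_values) != length(grid)) abort("`psi_values` rows must match `grid`.")
  if (!all(is.finite(psi_values))) abort("non-finite dictionary values supplied.")
  w <- quad_weights(grid, rule)
  phi <- tf_evaluate(family, grid)          # n x M
  out <- crossprod(phi * w, psi_values)     # M x Q
  colnames(out) <- colnames(psi_values)
  out
}

#' Assemble the weak-form linear system across experiments
#'
#' Stacks per-experiment projection blocks into the atemporal system
#' `z_n = Psi a_n` for each variable `n`. Experiments in which variable `n`
#' is itself intervened on (inhibited/activated) are excluded from `z_n`'s
#' rows — its equation is not learned from data where it was clamped — while
#' its measured trajectory still feeds the design columns for the other
#' variables. Known contributions to the dynamics (e.g. a constant forcing)
#' are projected onto the test functions and subtracted from `z_n` before
#' solving.
#'
#' @param experiments a list of experiments; each is a list with elements
#'   `grid` (strictly increasing times starting at 0) and `states`
#'   (`length(grid)` by `N` matrix with variable names as column names).
#'   Use [trajectories_to_experiments()] for collocation fits and
#'   [data_to_experiments()] for long-format time series.
#' @param dictionary a `usdl_dictionary` (arity `N`).
#' @param family a `usdl_test_family`, or a constructor `function(T_final)`
#'   (each experiment defines its own record length).
#' @param rule quadrature rule passed to the projections.
#' @param interventions optional data frame (`experiment`, `variable`,
#'   `type`) with `type` in `c("inhibition", "activation", "none")`;
#'   non-`"none"` rows mask that experiment out of that variable's response.
#' @param known_contributions optional named list mapping a variable name to
#'   a known forcing: a constant or a `function(t)`, subtracted from the
#'   response after projection.
#' @return an object of class `usdl_weak_system` holding per-experiment
#'   design blocks, per-variable response blocks, the usable-experiment
#'   mask, and labels.
#' @export
assemble <- function(experiments, dictionary, family, rule = "trapezoid",
                     interventions = NULL, known_contributions = NULL) {
  stopifnot(inherits(dictionary, "usdl_dictionary"))
  if (length(experiments) == 0L) abort("no experiments supplied.")
  fam_of <- if (inherits(family, "usdl_test_family")) {
    function(T_final) family
  } else {
    parse_family_spec(family)
  }
  exp_names <- names(experiments) %||% as.character(seq_along(experiments))
  vars <- colnames(experiments[[1]]$states)
  if (is.null(vars)) abort("experiment state matrices must have variable names as column names.")
  if (dictionary$N != length(vars)) {
    abort(sprintf("dictionary arity %d does not match the %d observed variables.",
                  dictionary$N, length(vars)))
  }
  N <- length(vars)

  blocks <- vector("list", length(experiments))
  for (p in seq_along(experiments)) {
    ex <- experiments[[p]]
    if (!identical(colnames(ex$states), vars)) {
      abort("all experiments must share the same variable names in the same order.")
    }
    fam <- fam_of(max(ex$grid))
    psi <- dict_evaluate(dictionary, ex$states)
    Psi <- project_dictionary(psi, ex$grid, fam, rule)
    Z <- vapply(seq_len(N), function(n) {
      project_derivative(ex$states[, n], ex$grid, fam, rule)
    }, numeric(fam$M))
    colnames(Z) <- vars
    # subtract known forcing: z_n <- z_n - <g_n, phi>
    if (!is.null(known_contributions)) {
      phi <- tf_evaluate(fam, ex$grid)
      w <- quad_weights(ex$grid, rule)
      for (v in intersect(names(known_contributions), vars)) {
        g <- known_contributions[[v]]
        gv <- if (is.function(g)) g(ex$grid) else rep(as.numeric(g), length(ex$grid))
        Z[, v] <- Z[, v] - drop(crossprod(phi, w * gv))
      }
    }
    blocks[[p]] <- list(Psi = Psi, Z = Z, M = fam$M)
  }

  mask <- matrix(TRUE, N, length(experiments),
                 dimnames = list(vars, exp_names))
  if (!is.null(interventions)) {
    iv <- as.data.frame(interventions)
    iv <- iv[!is.na(iv$type) & iv$type != "none", , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      e <- match(as.character(iv$experiment[i]), exp_names)
      v <- match(as.character(iv$variable[i]), vars)
      if (!is.na(e) && !is.na(v)) mask[v, e] <- FALSE
    }
  }
  uninferable <- vars[rowSums(mask) == 0L]
  if (length(uninferable) > 0L) {
    warn(paste0("variable(s) with zero usable experiments (un-inferable): ",
                paste(uninferable, collapse = ", ")))
  }
  structure(
    list(blocks = blocks, mask = mask, variables = vars,
         labels = dictionary$labels, dictionary = dictionary,
         family_kind = fam_of(max(experiments[[1]]$grid))$kind,
         rule = rule, experiment_names = exp_names,
         uninferable = uninferable),
    class = "usdl_weak_system"
  )
}

#' Stacked design matrix and response for one variable
#'
#' @param ws a `usdl_weak_system`.
#' @param variable variable name.
#' @return `ws_design()`: the row-stacked design matrix over the experiments
#'   usable for that variable; `ws_response()`: the matching stacked
#'   response vector.
#' @export
ws_design <- function(ws, variable) {
  stopifnot(inherits(ws, "usdl_weak_system"))
  v <- match(variable, ws$variables)
  if (is.na(v)) abort(sprintf("unknown variable '%s'.", variable))
  use <- which(ws$mask[v, ])
  if (length(use) == 0L) return(NULL)
  do.call(rbind, lapply(ws$blocks[use], `[[`, "Psi"))
}

#' @rdname ws_design
#' @export
ws_response <- function(ws, variable) {
  stopifnot(inherits(ws, "usdl_weak_system"))
  v <- match(variable, ws$variables)
  if (is.na(v)) abort(sprintf("unknown variable '%s'.", variable))
  use <- which(ws$mask[v, ])
  if (length(use) == 0L) return(NULL)
  unlist(lapply(ws$blocks[use], function(b) b$Z[, v]), use.names = FALSE)
}

#' @export
print.usdl_weak_system <- function(x, ...) {
  M <- sum(vapply(x$blocks, `[[`, numeric(1), "M"))
  cat(sprintf("<usdl_weak_system: %d variables, %d dictionary atoms, %d experiments, %d stacked projection rows (%s test functions, %s rule)>\n",
              length(x$variables), length(x$labels), length(x$blocks), M,
              x$family_kind, x$rule))
  if (length(x$uninferable)) {
    cat("  un-inferable variables:", paste(x$uninferable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert fitted trajectories to weak-form experiment inputs
#'
#' Evaluates each experiment's fitted trajectories on a dense regular grid
#' over its own `[0, T]` so they can be projected onto test functions.
#'
#' @param fits tibble from [fit_experiment()] / [fit_all_experiments()].
#' @param grid_n number of evaluation points per experiment (default 512).
#' @return a named list of experiments for [assemble()].
#' @export
trajectories_to_experiments <- function(fits, grid_n = 512L) {
  fits <- as.data.frame(fits)
  exps <- unique(fits$experiment)
  out <- lapply(exps, function(e) {
    fe <- fits[fits$experiment == e, , drop = FALSE]
    fe <- fe[!vapply(fe$trajectory, is.null, logical(1)), , drop = FALSE]
    if (nrow(fe) == 0L) return(NULL)
    T_final <- max(vapply(fe$trajectory, function(tr) tr$domain[2], numeric(1)))
    grid <- seq(0, T_final, length.out = grid_n)
    states <- vapply(fe$trajectory, function(tr) predict(tr, grid),
                     numeric(grid_n))
    colnames(states) <- fe$variable
    list(grid = grid, states = states)
  })
  names(out) <- as.character(exps)
  out[!vapply(out, is.null, logical(1))]
}

#' Convert long-format time series to weak-form experiment inputs
#'
#' For repeated-measurement time series the observed sampling grid is used
#' directly (no collocation); the grid need not be evenly spaced.
#'
#' @param data long-format data frame (`experiment`, `time`, `variable`,
#'   `value`) with one value per (experiment, time, variable).
#' @return a named list of experiments for [assemble()].
#' @export
data_to_experiments <- function(data) {
  data <- as.data.frame(data)
  need <- c("experiment", "time", "variable", "value")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns experiment, time, variable, value.")
  }
  vars <- unique(as.character(data$variable))
  exps <- unique(data$experiment)
  out <- lapply(exps, function(e) {
    d <- data[data$experiment == e, , drop = FALSE]
    times <- sort(unique(d$time))
    states <- matrix(NA_real_, length(times), length(vars),
                     dimnames = list(NULL, vars))
    for (v in vars) {
      dv <- d[d$variable == v, , drop = FALSE]
      states[match(dv$time, times), v] <- dv$value
    }
    if (anyNA(states)) {
      abort(sprintf("experiment '%s' is not a complete time series (every variable must be measured at every time).", e))
    }
    list(grid = times, states = states)
  })
  names(out) <- as.character(exps)
  out
}

#' Export / import a weak system as plain-text matrices plus JSON metadata
#'
#' @param ws a `usdl_weak_system`.
#' @param dir directory to write `psi_<p>.tsv`, `z_<p>.tsv` and
#'   `weak_system.json` into.
#' @return `export_weak_system()`: the directory, invisibly;
#'   `import_weak_system()`: the reconstructed `usdl_weak_system`.
#' @export
export_weak_system <- function(ws, dir) {
  stopifnot(inherits(ws, "usdl_weak_system"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_along(ws$blocks)) {
    utils::write.table(ws$blocks[[p]]$Psi, file.path(dir, sprintf("psi_%d.tsv", p)),
                       sep = "\t", row.names = FALSE, col.names = ws$labels)
    utils::write.table(ws$blocks[[p]]$Z, file.path(dir, sprintf("z_%d.tsv", p)),
                       sep = "\t", row.names = FALSE, col.names = ws$variables)
  }
  meta <- list(variables = ws$variables, labels = ws$labels,
               experiment_names = ws$experiment_names,
               mask = ws$mask, family_kind = ws$family_kind, rule = ws$rule,
               n_blocks = length(ws$blocks))
  jsonlite::write_json(meta, file.path(dir, "weak_system.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' @rdname export_weak_system
#' @export
import_weak_system <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "weak_system.json"),
                              simplifyVector = TRUE)
  blocks <- lapply(seq_len(meta$n_blocks), function(p) {
    Psi <- as.matrix(utils::read.table(file.path(dir, sprintf("psi_%d.tsv", p)),
                                       sep = "\t", header = TRUE, check.names = FALSE))
    Z <- as.matrix(utils::read.table(file.path(dir, sprintf("z_%d.tsv", p)),
                                     sep = "\t", header = TRUE, check.names = FALSE))
    list(Psi = `colnames<-`(unname(Psi), meta$labels),
         Z = `colnames<-`(unname(Z), meta$variables), M = nrow(Psi))
  })
  mask <- matrix(as.logical(meta$mask), nrow = length(meta$variables),
                 dimnames = list(meta$variables, meta$experiment_names))
  structure(
    list(blocks = blocks, mask = mask, variables = meta$variables,
         labels = meta$labels, dictionary = NULL,
         family_kind = meta$family_kind, rule = meta$rule,
         experiment_names = meta$experiment_names,
         uninferable = meta$variables[rowSums(mask) == 0L]),
    class = "usdl_weak_system"
  )
}
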