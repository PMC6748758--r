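#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end inference pipeline so
#' [run_usdl()], [select_alpha()] and [stability_selection()] share one
#' contract.
#'
#' @param mode `"timeseries"` (repeated measurements: the observed grid is
#'   used directly and collocation is skipped) or `"timecourse"`
#'   (destructive sampling: penalized-spline collocation first).
#' @param dictionary `"linear"`, `"quadratic"`, a `usdl_dictionary`, or a
#'   constructor `function(N)`.
#' @param test_functions a family spec string (`"fourier:20"`,
#'   `"peaky:10,50"`, `"bspline:8,3"`), a `usdl_test_family`, or a
#'   constructor `function(T_final)`.
#' @param alpha OMP stopping parameter.
#' @param kmax maximum OMP support size per variable.
#' @param rule quadrature rule (`"trapezoid"` or `"simpson"`).
#' @param stop_rule OMP stopping criterion, see [omp()].
#' @param grid_n dense-grid size for evaluating collocation trajectories
#'   before projection (timecourse mode).
#' @param lambda collocation smoothing weight or `"gcv"`.
#' @param basis collocation basis, see [colloc_basis()].
#' @param baseline subtract each fitted trajectory's minimum?
#' @param known_contributions named list of known forcings per variable,
#'   subtracted from the response after projection (see [assemble()]).
#' @param include_diagonal include self-loops in the reported edge set?
#' @return a list of class `usdl_config`.
#' @export
usdl_config <- function(mode = c("timeseries", "timecourse"),
                        dictionary = "linear",
                        test_functions = "fourier:20",
                        alpha = 0.05, kmax = 10L,
                        rule = "trapezoid",
                        stop_rule = "noise-energy",
                        grid_n = 512L, lambda = "gcv", basis = NULL,
                        baseline = FALSE, known_contributions = NULL,
                        include_diagonal = FALSE) {
  structure(
    list(mode = match.arg(mode), dictionary = dictionary,
         test_functions = test_functions, alpha = alpha, kmax = kmax,
         rule = rule, stop_rule = stop_rule, grid_n = grid_n,
         lambda = lambda, basis = basis, baseline = baseline,
         known_contributions = known_contributions,
         include_diagonal = include_diagonal),
    class = "usdl_config"
  )
}

# normalize the accepted data shapes to a named experiment list
as_experiments <- function(data, config) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$experiments)) {
    data <- data$experiments   # simulator output
  }
  if (is.data.frame(data)) {
    if (config$mode == "timecourse") {
      fits <- fit_all_experiments(data, basis = config$basis,
                                  lambda = config$lambda,
                                  baseline = config$baseline)
      return(trajectories_to_experiments(fits, grid_n = config$grid_n))
    }
    return(data_to_experiments(data))
  }
  if (is.list(data)) return(data)  # already an experiment list
  abort("`data` must be a long-format data frame, a simulator result, or an experiment list.")
}

prepare_weak_system <- function(data, config, interventions = NULL) {
  experiments <- as_experiments(data, config)
  if (length(experiments) == 0L) abort("no usable experiments in `data`.")
  N <- ncol(experiments[[1]]$states)
  dict <- parse_dictionary_spec(config$dictionary)(N)
  dict <- dict_set_variables(dict, colnames(experiments[[1]]$states))
  assemble(experiments, dict, config$test_functions, rule = config$rule,
           interventions = interventions,
           known_contributions = config$known_contributions)
}

#' Run the full inference pipeline
#'
#' Executes the algorithm end to end: (time-course data only) collocation;
#' weak-form assembly of `z_n = Psi a_n`; the a priori mutual incoherence of
#' the design; per-variable sparse recovery by OMP; and the a posteriori
#' exact-recovery coefficient at each estimated support. Diagnostics are
#' always computed from the same design matrix used for inference.
#'
#' @param data a long-format data frame (`experiment`, `time`, `variable`,
#'   `value`), a simulator result, or an experiment list.
#' @param config a [usdl_config()].
#' @param interventions optional interventions table (`experiment`,
#'   `variable`, `type`); experiments where a variable is intervened on are
#'   excluded from that variable's own equation.
#' @return an object of class `usdl_fit`: `A_hat` (estimated connectivity),
#'   `mip`, `diagnostics` (per-variable tibble incl. ERC at the estimated
#'   support), `edges` (tibble), `solutions`, `weak_system`, `config`.
#' @examples
#' sim <- simulate_ou(N = 5, P = 10, sigma = 0, T_final = 6, seed = 1)
#' fit <- run_usdl(sim, usdl_config(alpha = 0.05, test_functions = "fourier:5"))
#' fit$edges
#' @export
run_usdl <- function(data, config = usdl_config(), interventions = NULL) {
  ws <- prepare_weak_system(data, config, interventions)
  solved <- solve_system(ws, alpha = config$alpha, kmax = config$kmax,
                         stop_rule = config$stop_rule)
  diagnostics <- recovery_diagnostics(ws, solved$solutions)
  full_design <- do.call(rbind, lapply(ws$blocks, `[[`, "Psi"))
  structure(
    list(A_hat = solved$A_hat,
         mip = mip(full_design),
         diagnostics = diagnostics,
         edges = edges_from_matrix(solved$A_hat,
                                   include_diagonal = config$include_diagonal),
         solutions = solved$solutions,
         weak_system = ws,
         config = config),
    class = "usdl_fit"
  )
}

#' @export
print.usdl_fit <- function(x, ...) {
  cat(sprintf("<usdl_fit: %d variables, %d dictionary atoms, MIP = %.3f, %d edges>\n",
              nrow(x$A_hat), ncol(x$A_hat), x$mip, nrow(x$edges)))
  print(x$diagnostics)
  invisible(x)
}

#' Select the OMP stopping parameter by F1 score
#'
#' Runs the pipeline for every value of `alpha_grid`, scores the resulting
#' edge set against ground truth, and returns the value maximizing F1 (ties
#' broken toward the smallest alpha). Collocation and weak-form assembly do
#' not depend on alpha, so they are performed once and only the sparse
#' recovery is repeated.
#'
#' @param data,config,interventions as in [run_usdl()].
#' @param truth a `usdl_ground_truth` or an edge tibble.
#' @param alpha_grid non-empty numeric vector of candidate values.
#' @param sign_aware score with sign-aware edge matching?
#' @return an object of class `usdl_alpha_selection`: `best_alpha`,
#'   `scores` (one row per grid value: alpha, tp, fp, fn, precision,
#'   recall, f1), and the `usdl_fit` at the best alpha.
#' @export
select_alpha <- function(data, truth, alpha_grid = seq(0.01, 0.5, length.out = 20),
                         config = usdl_config(), interventions = NULL,
                         sign_aware = FALSE) {
  if (length(alpha_grid) == 0L) abort("`alpha_grid` must be non-empty.")
  alpha_grid <- sort(alpha_grid)
  ws <- prepare_weak_system(data, config, interventions)
  fits <- lapply(alpha_grid, function(a) {
    solved <- solve_system(ws, alpha = a, kmax = config$kmax,
                           stop_rule = config$stop_rule)
    edges <- edges_from_matrix(solved$A_hat,
                               include_diagonal = config$include_diagonal)
    list(solved = solved, edges = edges,
         score = precision_recall(edges, truth, sign_aware = sign_aware))
  })
  scores <- dplyr::bind_rows(lapply(fits, `[[`, "score"))
  scores <- dplyr::bind_cols(tibble::tibble(alpha = alpha_grid), scores)
  best_i <- which.max(scores$f1)   # first maximum = smallest alpha
  best <- fits[[best_i]]
  diagnostics <- recovery_diagnostics(ws, best$solved$solutions)
  full_design <- do.call(rbind, lapply(ws$blocks, `[[`, "Psi"))
  best_fit <- structure(
    list(A_hat = best$solved$A_hat, mip = mip(full_design),
         diagnostics = diagnostics, edges = best$edges,
         solutions = best$solved$solutions, weak_system = ws,
         config = utils::modifyList(config, list(alpha = alpha_grid[best_i]))),
    class = "usdl_fit"
  )
  structure(
    list(best_alpha = alpha_grid[best_i], scores = scores, fit = best_fit),
    class = "usdl_alpha_selection"
  )
}

#' @export
print.usdl_alpha_selection <- function(x, ...) {
  cat(sprintf("<usdl_alpha_selection: best alpha = %g (F1 = %.3f over %d grid values)>\n",
              x$best_alpha, max(x$scores$f1), nrow(x$scores)))
  invisible(x)
}

#' Stability selection over data subsamples
#'
#' Repeats inference `B` times on random subsamples of the data and reports
#' the consensus edges: those appearing in at least `threshold` of the
#' repeats. The subsampling unit is the experiment when more than one
#' experiment is available, otherwise time points.
#'
#' @param data,config,interventions as in [run_usdl()].
#' @param B number of repeats (default 100).
#' @param fraction fraction of the data kept in each repeat (default 0.8).
#' @param threshold consensus frequency (default 0.8).
#' @param seed RNG seed for the subsampling.
#' @return an object of class `usdl_stability`: `consensus` (edge tibble
#'   with `frequency` and mean `coefficient`), `frequencies` (all edges
#'   ever selected), `B`, `fraction`, `threshold`.
#' @export
stability_selection <- function(data, config = usdl_config(), B = 100L,
                                fraction = 0.8, threshold = 0.8,
                                interventions = NULL, seed = 1L) {
  if (B < 1L) abort("`B` must be >= 1.")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  ws <- prepare_weak_system(data, config, interventions)
  P <- length(ws$blocks)
  runs <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      ws_b <- if (P > 1L) {
        keep <- sort(sample.int(P, max(1L, round(fraction * P))))
        subset_weak_system(ws, keep)
      } else {
        # single experiment: subsample time points and re-project
        resample_rows_weak_system(data, config, interventions, fraction)
      }
      solved <- solve_system(ws_b, alpha = config$alpha, kmax = config$kmax,
                             stop_rule = config$stop_rule)
      edges_from_matrix(solved$A_hat,
                        include_diagonal = config$include_diagonal)
    })
  })
  all_edges <- dplyr::bind_rows(runs, .id = "repeat_id")
  if (nrow(all_edges) == 0L) {
    freq <- tibble::tibble(source = character(0), target = character(0),
                           frequency = numeric(0), coefficient = numeric(0))
  } else {
    freq <- all_edges |>
      dplyr::group_by(.data$source, .data$target) |>
      dplyr::summarise(frequency = dplyr::n() / B,
                       coefficient = mean(.data$coefficient),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$frequency))
  }
  consensus <- freq[freq$frequency >= threshold, , drop = FALSE]
  consensus$sign <- sign(consensus$coefficient)
  structure(
    list(consensus = consensus, frequencies = freq, B = B,
         fraction = fraction, threshold = threshold),
    class = "usdl_stability"
  )
}

subset_weak_system <- function(ws, keep) {
  ws$blocks <- ws$blocks[keep]
  ws$mask <- ws$mask[, keep, drop = FALSE]
  ws$experiment_names <- ws$experiment_names[keep]
  ws$uninferable <- ws$variables[rowSums(ws$mask) == 0L]
  ws
}

resample_rows_weak_system <- function(data, config, interventions, fraction) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$experiments)) {
    data <- data$experiments
  }
  if (is.data.frame(data)) {
    times <- unique(data$time)
    keep_t <- sort(sample(times, max(2L, round(fraction * length(times)))))
    data_b <- data[data$time %in% keep_t, , drop = FALSE]
    return(prepare_weak_system(data_b, config, interventions))
  }
  # experiment list with one experiment: subsample its grid
  ex <- data[[1]]
  n <- length(ex$grid)
  keep <- sort(sample.int(n, max(2L, round(fraction * n))))
  keep <- union(c(1L, n), keep)   # keep endpoints for the boundary term
  data[[1]] <- list(grid = ex$grid[sort(keep)],
                    states = ex$states[sort(keep), , drop = FALSE])
  prepare_weak_system(data, config, interventions)
}

#' @export
print.usdl_stability <- function(x, ...) {
  cat(sprintf("<usdl_stability: %d consensus edges at threshold %.0f%% over %d repeats (fraction %.2f)>\n",
              nrow(x$consensus), 100 * x$threshold, x$B, x$fraction))
  print(x$consensus)
  invisible(x)
}
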