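#' Candidate-function dictionaries
#'
#' A dictionary is an ordered set of `Q` scalar candidate functions
#' \eqn{\psi_q : R^N \to R} of the state vector, hypothesized to span the
#' right-hand side of the dynamics \eqn{\dot x = A \psi(x)}. The inference
#' problem is linear in the unknown coefficient matrix `A`, so nonlinear
#' dynamics are accommodated by nonlinear dictionary members.
#'
#' * `dict_linear(N)`: the identity dictionary \eqn{\psi(x) = x}
#'   (single-reactant mass-action kinetics); `Q = N`.
#' * `dict_quadratic(N)`: linear terms followed by all products
#'   \eqn{x_i x_j}, `i <= j`, in upper-triangular row-major order
#'   (two-reactant kinetics); `Q = (N + 3) N / 2`.
#' * `dict_custom(members, N)`: arbitrary labeled scalar functions.
#'
#' @param N state dimension (number of measured variables), >= 1.
#' @param members named list of functions, each taking an `N`-vector and
#'   returning a scalar; names are the member labels and must be unique.
#'
#' @return An object of class `usdl_dictionary` with fields `kind`, `N`,
#'   `Q` and `labels`.
#' @examples
#' d <- dict_quadratic(3)
#' d$labels
#' dict_evaluate(d, rbind(c(1, 2, 3)))
#' @name dictionaries
NULL

new_dictionary <- function(kind, N, labels, eval_fn) {
  structure(
    list(kind = kind, N = as.integer(N), Q = length(labels),
         labels = labels, eval_fn = eval_fn),
    class = "usdl_dictionary"
  )
}

check_N <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N)) {
    abort("`N` must be a single integer >= 1.")
  }
  as.integer(N)
}

#' @rdname dictionaries
#' @export
dict_linear <- function(N) {
  N <- check_N(N)
  new_dictionary("linear", N, paste0("x", seq_len(N)), function(X) X)
}

# column order of the quadratic block: (1,1),(1,2),...,(1,N),(2,2),...,(N,N)
quad_pairs <- function(N) {
  i <- rep(seq_len(N), times = N - seq_len(N) + 1L)
  j <- unlist(lapply(seq_len(N), function(i) i:N))
  cbind(i = i, j = j)
}

#' @rdname dictionaries
#' @export
dict_quadratic <- function(N) {
  N <- check_N(N)
  pairs <- quad_pairs(N)
  labels <- c(paste0("x", seq_len(N)),
              unname(ifelse(pairs[, "i"] == pairs[, "j"],
                            paste0("x", pairs[, "i"], "^2"),
                            paste0("x", pairs[, "i"], "*x", pairs[, "j"]))))
  eval_fn <- function(X) {
    cbind(X, X[, pairs[, "i"], drop = FALSE] * X[, pairs[, "j"], drop = FALSE])
  }
  d <- new_dictionary("quadratic", N, labels, eval_fn)
  d$pairs <- pairs
  d
}

#' Column index of the product `x_i * x_j` in the quadratic dictionary
#'
#' @param i,j variable indices with `i <= j`.
#' @param N state dimension.
#' @return the dictionary column index of the atom `x_i * x_j`.
#' @export
quad_index <- function(i, j, N) {
  stopifnot(i >= 1, j >= i, j <= N)
  # linear block occupies 1..N; block for row i starts after
  # sum_{r < i} (N - r + 1) product entries
  N + (i - 1) * N - (i - 1) * (i - 2) / 2 + (j - i + 1)
}

#' @rdname dictionaries
#' @export
dict_custom <- function(members, N) {
  N <- check_N(N)
  if (!is.list(members) || length(members) == 0L) {
    abort("`members` must be a non-empty named list of functions.")
  }
  labels <- names(members)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    abort("`members` must have unique non-empty names (duplicate labels are not allowed).")
  }
  if (!all(vapply(members, is.function, logical(1)))) {
    abort("every dictionary member must be a function of the state vector.")
  }
  eval_fn <- function(X) {
    out <- vapply(members, function(f) apply(X, 1L, function(x) f(x)),
                  numeric(nrow(X)))
    matrix(out, nrow = nrow(X), ncol = length(members))
  }
  new_dictionary("custom", N, labels, eval_fn)
}

#' Evaluate a dictionary along a sequence of states
#'
#' @param dict a `usdl_dictionary`.
#' @param states numeric matrix (rows = time points, columns = the `N` state
#'   variables) or a data frame coercible to one.
#' @param drop_constant if `TRUE`, columns whose variance over the supplied
#'   states falls below `1e-12` are flagged via the `"constant_columns"`
#'   attribute (constant-over-time candidates introduce collinearity that
#'   can imperil recovery); no column is removed.
#' @return a `nrow(states)` by `Q` matrix with columns named by the member
#'   labels.
#' @export
dict_evaluate <- function(dict, states, drop_constant = FALSE) {
  stopifnot(inherits(dict, "usdl_dictionary"))
  X <- as.matrix(states)
  if (ncol(X) != dict$N) {
    abort(sprintf("state dimension %d does not match dictionary arity %d.",
                  ncol(X), dict$N))
  }
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite state value at time index %d, variable %d.",
                  bad[1], bad[2]))
  }
  out <- dict$eval_fn(X)
  colnames(out) <- dict$labels
  if (!all(is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)[1, ]
    abort(sprintf("dictionary member '%s' produced a non-finite value at time index %d.",
                  dict$labels[bad[2]], bad[1]))
  }
  if (drop_constant) {
    v <- apply(out, 2L, stats::var)
    attr(out, "constant_columns") <- which(v < 1e-12)
  }
  out
}

#' Relabel dictionary atoms with the observed variable names
#'
#' Linear and quadratic dictionaries are built with generic `x1..xN` labels;
#' when the data carry meaningful variable names this substitutes them
#' (e.g. `"P1"`, `"P1*P3"`) so that edge lists read naturally and self-loop
#' (diagonal) entries can be recognized.
#'
#' @param dict a `usdl_dictionary`.
#' @param vars character vector of `N` variable names.
#' @return the relabeled dictionary.
#' @export
dict_set_variables <- function(dict, vars) {
  stopifnot(inherits(dict, "usdl_dictionary"))
  if (length(vars) != dict$N) abort("`vars` must have length N.")
  if (dict$kind == "linear") {
    dict$labels <- vars
  } else if (dict$kind == "quadratic") {
    pairs <- dict$pairs
    dict$labels <- c(vars,
                     unname(ifelse(pairs[, "i"] == pairs[, "j"],
                                   paste0(vars[pairs[, "i"]], "^2"),
                                   paste0(vars[pairs[, "i"]], "*", vars[pairs[, "j"]]))))
  }
  dict
}

#' Parse a dictionary specification
#'
#' Accepts `"linear"`, `"quadratic"`, or an existing `usdl_dictionary`.
#' Returns a constructor `function(N)` so the pipeline can size the
#' dictionary from the data.
#'
#' @param spec specification string or dictionary object.
#' @return a function mapping the state dimension to a `usdl_dictionary`.
#' @export
parse_dictionary_spec <- function(spec) {
  if (is.function(spec)) return(spec)
  if (inherits(spec, "usdl_dictionary")) return(function(N) spec)
  if (!is.character(spec) || length(spec) != 1L) {
    abort("`spec` must be \"linear\", \"quadratic\" or a usdl_dictionary.")
  }
  switch(spec,
    linear = dict_linear,
    quadratic = dict_quadratic,
    abort(sprintf("unknown dictionary kind '%s'", spec))
  )
}

#' @export
print.usdl_dictionary <- function(x, ...) {
  cat(sprintf("<usdl_dictionary: %s, Q = %d members over %d state variables>\n",
              x$kind, x$Q, x$N))
  invisible(x)
}
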