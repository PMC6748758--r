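#' Ground-truth container
#'
#' Holds a true connectivity matrix over a named dictionary, the signed
#' directed edge list derived from its off-diagonal support, and the
#' generating configuration and seed.
#'
#' @param A true connectivity matrix (`N` variables by `Q` atoms).
#' @param variables row (target variable) names.
#' @param labels column (dictionary atom) names.
#' @param config generating parameters.
#' @param seed generating seed.
#' @return an object of class `usdl_ground_truth` with fields `A`, `edges`
#'   (tibble from [edges_from_matrix()]), `config`, `seed`.
#' @export
new_ground_truth <- function(A, variables = rownames(A), labels = colnames(A),
                             config = list(), seed = NA_integer_) {
  dimnames(A) <- list(variables, labels)
  structure(
    list(A = A, variables = variables, labels = labels,
         edges = edges_from_matrix(A), config = config, seed = seed),
    class = "usdl_ground_truth"
  )
}

#' @export
print.usdl_ground_truth <- function(x, ...) {
  cat(sprintf("<usdl_ground_truth: %s, %d variables, %d off-diagonal edges (seed %s)>\n",
              x$config$system %||% "custom", length(x$variables),
              nrow(x$edges), x$seed))
  invisible(x)
}

#' Signed directed edges of a connectivity matrix
#'
#' Every nonzero entry `A[n, q]` maps the dictionary atom `q` to the target
#' variable `n`: for a linear dictionary this is a variable-to-variable
#' edge; for nonlinear atoms (e.g. `x1*x2`) the edge is labeled by the
#' atom. Positive coefficients denote up-regulation (arrow), negative
#' down-regulation (bar). Diagonal entries (an atom equal to the target
#' variable itself, i.e. self-degradation) are excluded by default since
#' benchmark ground-truth graphs are drawn over off-diagonal interactions.
#'
#' @param A_hat coefficient matrix with variable rownames and atom colnames.
#' @param include_diagonal include self-loop entries?
#' @return a tibble with columns `source` (atom label), `target`
#'   (variable), `coefficient`, `sign` (+1 / -1).
#' @export
edges_from_matrix <- function(A_hat, include_diagonal = FALSE) {
  A_hat <- as.matrix(A_hat)
  vars <- rownames(A_hat) %||% paste0("x", seq_len(nrow(A_hat)))
  labels <- colnames(A_hat) %||% paste0("psi", seq_len(ncol(A_hat)))
  nz <- which(A_hat != 0, arr.ind = TRUE)
  out <- tibble::tibble(
    source = labels[nz[, "col"]],
    target = vars[nz[, "row"]],
    coefficient = A_hat[nz],
    sign = sign(A_hat[nz])
  )
  if (!include_diagonal) out <- out[out$source != out$target, , drop = FALSE]
  dplyr::arrange(out, .data$target, .data$source)
}

#' Precision, recall and F1 of a predicted edge set
#'
#' Matching is over the unsigned directed support (`source`, `target`) by
#' default; `sign_aware = TRUE` additionally requires the predicted sign to
#' match. An empty prediction scores precision 1 and recall 0 (over-sparse
#' solutions are penalized through recall only).
#'
#' @param predicted,truth edge tibbles ([edges_from_matrix()]) or objects
#'   carrying `$edges` (a `usdl_ground_truth` or [run_usdl()] fit).
#' @param sign_aware count a sign mismatch as an error?
#' @return a one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
precision_recall <- function(predicted, truth, sign_aware = FALSE) {
  pe <- edge_keys(predicted, sign_aware)
  te <- edge_keys(truth, sign_aware)
  tp <- length(intersect(pe, te))
  fp <- length(setdiff(pe, te))
  fn <- length(setdiff(te, pe))
  precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1)
}

edge_keys <- function(x, sign_aware) {
  if (!is.data.frame(x) && !is.null(x$edges)) x <- x$edges
  x <- as.data.frame(x)
  if (nrow(x) == 0L) return(character(0))
  key <- paste(x$source, x$target, sep = "->")
  if (sign_aware) key <- paste(key, x$sign)
  unique(key)
}

#' Root-mean-squared error between connectivity matrices
#'
#' @param A_hat,A_true matrices of identical shape.
#' @return the root mean square over all entries.
#' @export
rmse <- function(A_hat, A_true) {
  A_hat <- as.matrix(A_hat); A_true <- as.matrix(A_true)
  if (!identical(dim(A_hat), dim(A_true))) {
    abort("`A_hat` and `A_true` must have the same shape.")
  }
  sqrt(mean((A_hat - A_true)^2))
}
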