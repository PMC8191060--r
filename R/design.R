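#' Column-center a numeric matrix
#'
#' Subtracts the column mean from every column so that each column sums to
#' zero. Both the design matrix and the response matrix of the linear model
#' are column-centered before any test statistic is formed.
#'
#' @param M numeric matrix (or vector, treated as a one-column matrix) with at
#'   least one row.
#' @return a numeric matrix of the same dimensions whose columns sum to zero.
#' @examples
#' center_columns(c(1, 0, 1, 0, 0))  # -> (3/5, -2/5, 3/5, -2/5, -2/5)
#' @export
center_columns <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 1L || length(M) == 0L)
    stop("cannot center an empty matrix")
  if (!is.numeric(M)) stop("matrix must be numeric")
  sweep(M, 2L, colMeans(M), "-")
}

#' Per-set indicator variables
#'
#' Builds one 0/1 column per matched set, with entry 1 when the sample belongs
#' to that set. Including these indicators as the first submodel of the design
#' constrains all tested contrasts to within-set comparisons. Centering and
#' orthonormalization are applied later by [build_design()].
#'
#' @param set_ids vector of per-sample set labels (any atomic type).
#' @return an `n x S` numeric 0/1 matrix, columns ordered by first appearance
#'   of each set and named by set label.
#' @export
make_set_indicators <- function(set_ids) {
  if (length(set_ids) < 1L) stop("need at least one sample")
  if (anyNA(set_ids)) stop("set_ids must not contain NA")
  lev <- unique(set_ids)  # first-appearance order
  Z <- outer(set_ids, lev, "==") * 1
  colnames(Z) <- paste0("set:", as.character(lev))
  Z
}

#' Project a variable off a nuisance span
#'
#' Column-centers `v`, then removes its projection onto the column span of
#' `basis`. The result is orthogonal to every column of `basis` (and to the
#' constant vector). When `basis` consists of set indicators this is exactly
#' within-set demeaning.
#'
#' @param v numeric vector (one variable).
#' @param basis numeric matrix (or vector) whose column span is projected off;
#'   `NULL` means centering only. Columns need not be orthonormal; the span is
#'   what matters.
#' @param center logical; column-center `v` first (default `TRUE`).
#' @return numeric vector orthogonal to `basis` and summing to zero.
#' @examples
#' z <- make_set_indicators(c(1, 1, 2, 2, 2))
#' project_off(c(1, 0, 1, 0, 0), z)  # (1/2, -1/2, 2/3, -1/3, -1/3)
#' @export
project_off <- function(v, basis = NULL, center = TRUE) {
  v <- as.numeric(v)
  if (center) v <- v - mean(v)
  if (is.null(basis) || length(basis) == 0L) return(v)
  B <- as.matrix(basis)
  stopifnot(nrow(B) == length(v))
  # least-squares projection via QR so a rank-deficient or non-orthonormal
  # basis is handled by its span
  qB <- qr(B)
  v - qr.fitted(qB, v)
}

#' Balance of a variable across matched sets
#'
#' A variable is balanced when its within-set sum is proportional to the set
#' size with a common constant, i.e. the within-set mean is identical across
#' sets. For a balanced variable, column centering alone zeroes its within-set
#' sums, so tests are identical with and without set-indicator adjustment
#' under within-set permutation.
#'
#' @param v numeric per-sample variable.
#' @param set_ids per-sample set labels.
#' @param tol numeric tolerance on the spread of within-set means.
#' @return `TRUE` if balanced, `FALSE` otherwise.
#' @export
check_balance <- function(v, set_ids, tol = 1e-10) {
  stopifnot(length(v) == length(set_ids))
  m <- tapply(as.numeric(v), set_ids, mean)
  max(m) - min(m) <= tol * max(1, max(abs(m)))
}

#' Describe a matched-set design
#'
#' Bundles per-sample set membership with an ordered list of submodels
#' (variable groups to be tested sequentially) and optional sample-level
#' confounders. Submodel order is meaningful: the test of submodel `k` is
#' adjusted for all earlier submodels (and for the nuisance block).
#'
#' @param set_ids per-sample set labels; every sample belongs to exactly one
#'   set.
#' @param submodels named list of numeric vectors/matrices, one entry per
#'   submodel of interest, in testing order.
#' @param confounders optional numeric vector/matrix of sample-level
#'   confounding covariates, placed in the nuisance block.
#' @param adjust_set_id logical; include per-set indicators in the nuisance
#'   block (default `TRUE`, the recommended strategy).
#' @param sample_ids optional sample identifiers.
#' @return an object of class `"matched_design"`.
#' @export
matched_design <- function(set_ids, submodels, confounders = NULL,
                           adjust_set_id = TRUE, sample_ids = NULL) {
  n <- length(set_ids)
  if (n < 2L) stop("need at least two samples")
  if (anyNA(set_ids)) stop("set_ids must not contain NA")
  if (!is.list(submodels)) submodels <- list(trait = submodels)
  if (is.null(names(submodels)) || any(!nzchar(names(submodels))))
    names(submodels) <- paste0("submodel", seq_along(submodels))
  submodels <- lapply(submodels, function(s) {
    s <- as.matrix(s)
    if (nrow(s) != n) stop("submodel length does not match set_ids")
    if (anyNA(s) || any(!is.finite(s))) stop("submodel variables must be finite")
    s
  })
  if (!is.null(confounders)) {
    confounders <- as.matrix(confounders)
    if (nrow(confounders) != n) stop("confounder length does not match set_ids")
    if (anyNA(confounders)) stop("confounders must be finite")
  }
  if (is.null(sample_ids)) sample_ids <- seq_len(n)
  structure(list(sample_ids = sample_ids, set_ids = set_ids,
                 submodels = submodels, confounders = confounders,
                 adjust_set_id = isTRUE(adjust_set_id)),
            class = "matched_design")
}

#' @export
print.matched_design <- function(x, ...) {
  sz <- table(x$set_ids)
  cat("Matched-set design:", length(x$set_ids), "samples in", length(sz),
      "sets (sizes", paste(sort(unique(as.integer(sz))), collapse = "/"), ")\n")
  cat("  submodels:", paste(names(x$submodels), collapse = " -> "), "\n")
  cat("  nuisance :",
      if (x$adjust_set_id) "set indicators" else "none",
      if (!is.null(x$confounders))
        paste0("+ ", ncol(x$confounders), " confounder(s)") else "", "\n")
  invisible(x)
}

# modified Gram-Schmidt of one raw column against accepted columns Q;
# returns NULL when the column is numerically inside span(Q)
.mgs_column <- function(col, Q, tol) {
  v <- col - mean(col)
  pre <- sqrt(sum(v^2))
  if (pre == 0) return(NULL)
  if (!is.null(Q) && ncol(Q) > 0L) {
    v <- v - Q %*% crossprod(Q, v)   # project twice for stability
    v <- v - Q %*% crossprod(Q, v)
  }
  nrm <- sqrt(sum(v^2))
  if (nrm < tol * pre) return(NULL)
  as.numeric(v) / nrm
}

#' Build the orthonormalized design matrix
#'
#' Constructs the sequential-orthonormal block design: the nuisance block
#' (centered set indicators, then sample-level confounders, when present)
#' followed by the submodels of interest, each column-centered and made
#' orthonormal to all earlier columns by modified Gram-Schmidt. Columns whose
#' post-projection norm falls below `tol` times the pre-projection norm are
#' numerically in the span of earlier columns and are dropped (with S sets,
#' only S-1 centered indicator columns are independent; the one for the last
#' set in first-appearance order is the dropped one).
#'
#' @param design a [matched_design()].
#' @param tol relative drop tolerance for post-projection column norms.
#' @return an object of class `"model_matrix"`: list with `blocks` (ordered
#'   list of orthonormal column matrices), `block_names`, `roles`
#'   (`"nuisance"`/`"tested"`), `tested` (indices of tested blocks, named by
#'   submodel), `pure_set_nuisance` (`TRUE` when the nuisance block contains
#'   set indicators only), `n_samples`, `set_ids`, `dropped_columns`.
#' @seealso [project_off()], [check_balance()]
#' @export
build_design <- function(design, tol = 1e-8) {
  stopifnot(inherits(design, "matched_design"))
  n <- length(design$set_ids)
  blocks <- list(); block_names <- character(); roles <- character()
  dropped <- character()
  Q <- NULL
  add_block <- function(raw, name, role, Q) {
    kept <- NULL
    raw <- as.matrix(raw)
    cn <- colnames(raw)
    if (is.null(cn)) cn <- paste0(name, seq_len(ncol(raw)))
    for (j in seq_len(ncol(raw))) {
      u <- .mgs_column(raw[, j], if (is.null(Q)) NULL else Q, tol)
      if (is.null(u)) { dropped <<- c(dropped, cn[j]); next }
      kept <- cbind(kept, u)
      Q <- cbind(Q, u)
    }
    if (!is.null(kept)) {
      blocks[[length(blocks) + 1L]] <<- kept
      block_names <<- c(block_names, name)
      roles <<- c(roles, role)
    }
    Q
  }
  has_conf <- !is.null(design$confounders)
  if (design$adjust_set_id || has_conf) {
    nuis <- NULL
    if (design$adjust_set_id) nuis <- make_set_indicators(design$set_ids)
    if (has_conf) nuis <- cbind(nuis, design$confounders)
    Q <- add_block(nuis, "nuisance", "nuisance", Q)
  }
  for (k in seq_along(design$submodels)) {
    nm <- names(design$submodels)[k]
    n_before <- length(blocks)
    Q <- add_block(design$submodels[[k]], nm, "tested", Q)
    if (length(blocks) == n_before)
      stop("trait '", nm, "' inestimable under matching: it lies in the span ",
           "of the set indicators / preceding submodels")
  }
  tested <- which(roles == "tested")
  names(tested) <- block_names[tested]
  structure(list(blocks = blocks, block_names = block_names, roles = roles,
                 tested = tested,
                 pure_set_nuisance = design$adjust_set_id && !has_conf,
                 n_samples = n, set_ids = design$set_ids,
                 dropped_columns = dropped),
            class = "model_matrix")
}

#' @export
print.model_matrix <- function(x, ...) {
  cat("Orthonormal design:", x$n_samples, "samples;",
      length(x$blocks), "blocks\n")
  for (i in seq_along(x$blocks))
    cat(sprintf("  [%d] %-12s %s (%d col%s)\n", i, x$block_names[i],
                x$roles[i], ncol(x$blocks[[i]]),
                if (ncol(x$blocks[[i]]) == 1L) "" else "s"))
  if (length(x$dropped_columns))
    cat("  dropped:", paste(x$dropped_columns, collapse = ", "), "\n")
  invisible(x)
}
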