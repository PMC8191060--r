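# Distances, Gower centering and the signed eigen-embedding used by the
# PERMANOVA test.

.rel_abund <- function(table) {
  X <- as.matrix(table)
  if (any(X < 0)) stop("counts must be non-negative")
  tot <- rowSums(X)
  if (any(tot <= 0)) stop("every sample must have a positive total count")
  X / tot
}

#' Bray-Curtis distance on relative abundances
#'
#' `d(a,b) = sum_j |f_aj - f_bj| / sum_j (f_aj + f_bj)` computed on the
#' relative-abundance (frequency) scale, so `d` lies in `[0, 1]`.
#'
#' @param table samples x OTUs count matrix (or data.frame).
#' @return symmetric `n x n` distance matrix with zero diagonal and a
#'   `"metric"` attribute.
#' @export
bray_curtis <- function(table) {
  f <- .rel_abund(table)
  D <- as.matrix(vegan::vegdist(f, method = "bray"))
  attr(D, "metric") <- "bray"
  D
}

#' Hellinger distance on relative abundances
#'
#' `d(a,b) = sqrt(sum_j (sqrt(f_aj) - sqrt(f_bj))^2)`, i.e. Euclidean
#' distance between square-root frequency profiles.
#'
#' @inheritParams bray_curtis
#' @return symmetric distance matrix with a `"metric"` attribute.
#' @export
hellinger <- function(table) {
  f <- .rel_abund(table)
  D <- as.matrix(stats::dist(sqrt(f)))
  attr(D, "metric") <- "hellinger"
  D
}

#' Gower-center a squared distance matrix
#'
#' Computes `Delta = -1/2 * C (D o D) C` with `C = I - (1/n) 1 1'`, the
#' double-centering that converts squared distances into an inner-product
#' (Gower) matrix. All row and column sums of the result are zero.
#'
#' @param D symmetric distance matrix (distances, not squared).
#' @return the Gower-centered matrix `Delta`.
#' @export
gower_center <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  A <- -0.5 * D^2
  rm <- rowMeans(A); gm <- mean(A)
  sweep(sweep(A, 1L, rm, "-"), 2L, rm, "-") + gm
}

#' Signed eigen-embedding of a Gower-centered matrix
#'
#' Factorizes `Delta = Y S Y'` where `S` is diagonal with entries +1/-1 for
#' the positive/negative eigenvalues of `Delta` and the columns of `Y` are
#' eigenvectors scaled by the square root of the absolute eigenvalue.
#' Negative-eigenvalue axes (present for non-Euclidean distances such as
#' Bray-Curtis) are retained with sign -1, not truncated. Eigenvalues with
#' `|lambda| <= tol * max|lambda|` are discarded.
#'
#' @param Delta Gower-centered matrix from [gower_center()].
#' @param tol relative eigenvalue cutoff.
#' @return list with `embedding` (`n x r` matrix Y), `signs` (length-r
#'   vector of +/-1) and `eigenvalues` (the retained eigenvalues).
#' @export
decompose_gower <- function(Delta, tol = 1e-8) {
  ee <- eigen(Delta, symmetric = TRUE)
  keep <- abs(ee$values) > tol * max(abs(ee$values), .Machine$double.eps)
  lam <- ee$values[keep]
  Y <- ee$vectors[, keep, drop = FALSE] %*% diag(sqrt(abs(lam)), sum(keep))
  list(embedding = Y, signs = sign(lam), eigenvalues = lam)
}

#' PERMANOVA pseudo-F statistic
#'
#' `F_k = tr(X_k' Delta X_k) / tr(R Delta R)` where `Delta = Y S Y'` and
#' `R = I - sum_k X_k X_k'` is the residual projector of the full model. The
#' numerator is computed as `sum_s S_s ||X_k' y_s||^2` without forming
#' `Delta`. Degrees-of-freedom constants are omitted; permutation p-values
#' are invariant to them.
#'
#' @param model a `"model_matrix"` from [build_design()].
#' @param decomp a decomposition from [decompose_gower()].
#' @param k block index of the tested submodel within `model$blocks`.
#' @return the pseudo-F statistic (a single number).
#' @export
pseudo_F <- function(model, decomp, k) {
  stopifnot(inherits(model, "model_matrix"))
  if (k < 1L || k > length(model$blocks) || is.null(model$blocks[[k]]) ||
      ncol(model$blocks[[k]]) == 0L)
    stop("statistic undefined: tested submodel has no retained columns")
  Y <- decomp$embedding; s <- decomp$signs
  num <- sum(s * colSums(crossprod(model$blocks[[k]], Y)^2))
  expl <- 0
  for (B in model$blocks) expl <- expl + colSums(crossprod(B, Y)^2)
  den <- sum(s * (colSums(Y^2) - expl))
  num / den
}
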