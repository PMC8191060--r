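#' Describe a permutation scheme
#'
#' @param mode `"within_set"` (restricted permutation among samples of the
#'   same matched set, the recommended scheme) or `"free"` (unrestricted).
#' @param n_perm number of random permutations B.
#' @param seed integer seed; the permutation stream is fully reproducible and
#'   depends only on `seed`, `mode` and the set structure.
#' @param set_ids per-sample set labels; required for `"within_set"`.
#' @param enumerate logical; enumerate all distinct within-set permutations
#'   instead of sampling (small designs only).
#' @param enumerate_cap maximum number of enumerated permutations allowed.
#' @return an object of class `"permutation_plan"`.
#' @export
permutation_plan <- function(mode = c("within_set", "free"), n_perm = 10000L,
                             seed = 1L, set_ids = NULL, enumerate = FALSE,
                             enumerate_cap = 1e6) {
  mode <- match.arg(mode)
  if (mode == "within_set" && is.null(set_ids))
    stop("within_set permutation requires set_ids")
  structure(list(mode = mode, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), set_ids = set_ids,
                 enumerate = isTRUE(enumerate),
                 enumerate_cap = enumerate_cap),
            class = "permutation_plan")
}

# all s! permutations of 1:s as an s! x s integer matrix (s small)
.perm_table <- function(s) {
  if (s == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perm_table(s - 1L)
  out <- matrix(0L, 0L, s)
  for (pos in seq_len(s)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], s,
                 sub[, seq(pos, s - 1L)[seq_len(s - pos)], drop = FALSE])
    out <- rbind(out, blk)
  }
  storage.mode(out) <- "integer"
  out
}

# positions of each set, in first-appearance order
.set_positions <- function(set_ids) {
  split(seq_along(set_ids), factor(set_ids, levels = unique(set_ids)))
}

# enumerate all within-set permutations (identity included) as rows
.enumerate_within <- function(set_ids, cap) {
  pos <- .set_positions(set_ids)
  total <- prod(factorial(lengths(pos)))
  if (total > cap)
    stop("enumeration would require ", format(total), " permutations (cap ",
         format(cap), ")")
  n <- length(set_ids)
  P <- matrix(seq_len(n), 1L, n)
  for (p in pos) {
    s <- length(p)
    if (s == 1L) next
    tab <- .perm_table(s)
    P <- P[rep(seq_len(nrow(P)), each = nrow(tab)), , drop = FALSE]
    P[, p] <- matrix(p[t(tab[rep(seq_len(nrow(tab)),
                                 times = nrow(P) / nrow(tab)), ])],
                     nrow(P), s, byrow = TRUE)
  }
  P
}

#' Draw permutations under a plan
#'
#' Returns row orderings as a `B x n` integer matrix; row `b` holds the
#' permuted index for each sample. Within-set orderings map every sample to a
#' sample of the same set. Random draws are independent and may include the
#' identity ordering (the `(1 + count)/(1 + B)` p-value estimator remains
#' valid, and on small designs the Monte-Carlo p-value then converges to the
#' exact enumerated one); in enumerated mode all distinct within-set
#' orderings, identity included, are returned. When every set is a singleton
#' only the identity exists and it is returned as the single row.
#'
#' @param plan a [permutation_plan()].
#' @param n_samples number of samples n.
#' @return integer matrix of orderings, one per row.
#' @export
draw_permutations <- function(plan, n_samples) {
  stopifnot(inherits(plan, "permutation_plan"))
  n <- as.integer(n_samples)
  if (plan$mode == "within_set") {
    if (length(plan$set_ids) != n) stop("set_ids must cover all samples")
    pos <- .set_positions(plan$set_ids)
    if (plan$enumerate) return(.enumerate_within(plan$set_ids, plan$enumerate_cap))
    if (all(lengths(pos) == 1L)) return(matrix(seq_len(n), 1L, n))
  } else if (plan$enumerate) {
    stop("enumeration is only supported for within_set permutation")
  }
  B <- plan$n_perm
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(plan$seed)
  draw <- function(B) {
    P <- matrix(rep(seq_len(n), each = B), B, n)
    if (plan$mode == "free") {
      for (b in seq_len(B)) P[b, ] <- sample.int(n)
    } else {
      for (p in pos) {
        s <- length(p)
        if (s == 1L) next
        if (s <= 7L) {
          tab <- .perm_table(s)
          ids <- sample.int(nrow(tab), B, replace = TRUE)
          P[, p] <- matrix(p[t(tab[ids, , drop = FALSE])], B, s, byrow = TRUE)
        } else {
          for (b in seq_len(B)) P[b, p] <- p[sample.int(s)]
        }
      }
    }
    P
  }
  draw(B)
}

#' Permutation p-value
#'
#' Converts an observed statistic and its permutation replicates into a
#' p-value. In random mode the estimator is `(1 + #\{permuted >= observed\}) /
#' (1 + B)`, which is valid for any B; in enumerated mode the permutation
#' distribution is exhaustive (identity included among `permuted`) and the
#' p-value is the exact fraction `#\{>= observed\} / #permutations`. Ties
#' count as exceedances.
#'
#' @param observed observed statistic.
#' @param permuted numeric vector of permuted statistics.
#' @param enumerated logical; `permuted` is the full enumeration (including
#'   the identity ordering's statistic).
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, permuted, enumerated = FALSE) {
  if (!length(permuted)) stop("need at least one permuted statistic")
  if (!is.finite(observed) || any(!is.finite(permuted)))
    stop("non-finite statistics")
  if (enumerated) sum(permuted >= observed) / length(permuted)
  else (1 + sum(permuted >= observed)) / (1 + length(permuted))
}
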