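# Distance-based PERMANOVA test for matched-set data.

# Expand a metadata variable reference to a numeric column matrix.
# "a:b" denotes the elementwise product of the raw (pre-centering) columns;
# factors/characters expand to indicator columns (first observed level is
# the reference).
.expand_var <- function(metadata, name) {
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    cols <- lapply(parts, .expand_var, metadata = metadata)
    if (any(vapply(cols, ncol, 1L) != 1L))
      stop("interaction terms require single-column variables")
    out <- Reduce(`*`, cols)
    colnames(out) <- name
    return(out)
  }
  if (!name %in% names(metadata)) stop("variable '", name, "' not in metadata")
  v <- metadata[[name]]
  if (anyNA(v)) stop("missing values in variable '", name, "'")
  if (is.numeric(v)) {
    out <- matrix(as.numeric(v), ncol = 1L, dimnames = list(NULL, name))
  } else {
    f <- factor(v, levels = unique(v))
    if (nlevels(f) < 2L) stop("variable '", name, "' is constant")
    out <- outer(as.integer(f), 2:nlevels(f), "==") * 1
    colnames(out) <- paste0(name, ".", levels(f)[-1L])
  }
  out
}

.design_from_metadata <- function(table, metadata, trait, set_col,
                                  confounders, adjust_set_id) {
  if (nrow(metadata) != nrow(as.matrix(table)))
    stop("metadata rows must align with count-table rows")
  if (!set_col %in% names(metadata)) stop("set column '", set_col, "' missing")
  subm <- lapply(trait, .expand_var, metadata = metadata)
  names(subm) <- trait
  conf <- if (length(confounders))
    do.call(cbind, lapply(confounders, .expand_var, metadata = metadata))
  else NULL
  matched_design(metadata[[set_col]], subm, confounders = conf,
                 adjust_set_id = adjust_set_id,
                 sample_ids = rownames(as.matrix(table)))
}

#' PERMANOVA test for matched-set microbiome data
#'
#' Community-level permutation test of the association between one or more
#' traits and microbiome composition, in a matched-set design. Per-set
#' indicator variables are placed in the first design block (when
#' `adjust_set_id = TRUE`) so that tested contrasts are orthogonal to set
#' means, and the orthonormalized trait block is permuted within sets. The
#' pseudo-F statistic is formed on the signed eigen-embedding of the Gower-
#' centered squared distance matrix, retaining negative-eigenvalue axes with
#' sign -1.
#'
#' @param table samples x OTUs count matrix.
#' @param metadata data.frame aligned with the rows of `table`.
#' @param trait character vector of metadata variables to test, in submodel
#'   order; each entry is tested adjusted for the preceding ones. `"a:b"`
#'   denotes an interaction (elementwise product of the raw columns).
#' @param set_col name of the set-label column in `metadata`.
#' @param confounders optional character vector of sample-level confounder
#'   columns, placed in the nuisance block.
#' @param distance `"bray"`, `"hellinger"`, or a precomputed symmetric
#'   distance matrix.
#' @param adjust_set_id include per-set indicators in the nuisance block.
#' @param permute `"within_set"` (recommended) or `"free"`.
#' @param n_perm number of permutations B.
#' @param seed integer seed for the permutation stream.
#' @param enumerate exhaustively enumerate the within-set permutations
#'   (small designs); p-values are then exact.
#' @return an object of class `"permanova_fit"` with components `statistic`
#'   (pseudo-F per tested submodel), `p.value`, `n_perm`, `permute`,
#'   `enumerated`, `metric` and `model`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_sets = 10, n_otus = 40, beta = 0.5,
#'                                    seed = 1))
#' permanova_test(sim$counts, sim$metadata, trait = "trait", n_perm = 99)
#' @export
permanova_test <- function(table, metadata, trait, set_col = "set_id",
                           confounders = NULL, distance = "bray",
                           adjust_set_id = TRUE,
                           permute = c("within_set", "free"),
                           n_perm = 10000L, seed = 1L, enumerate = FALSE) {
  permute <- match.arg(permute)
  md <- .design_from_metadata(table, metadata, trait, set_col, confounders,
                              adjust_set_id)
  model <- build_design(md)
  if (is.matrix(distance)) {
    D <- distance; metric <- attr(distance, "metric") %||% "user"
  } else {
    metric <- match.arg(distance, c("bray", "hellinger"))
    D <- switch(metric, bray = bray_curtis(table), hellinger = hellinger(table))
  }
  decomp <- decompose_gower(gower_center(D))
  plan <- permutation_plan(permute, n_perm, seed, set_ids = md$set_ids,
                           enumerate = enumerate)
  Pidx <- draw_permutations(plan, model$n_samples)
  Fv <- pv <- stats::setNames(numeric(length(model$tested)), names(model$tested))
  for (i in seq_along(model$tested)) {
    k <- model$tested[i]
    st <- .perm_stats(decomp$embedding, decomp$signs, model, k, Pidx,
                      .needs_reproject(model, k, permute))
    Fv[i] <- st$F[1]
    pv[i] <- permutation_pvalue(st$F[1], st$F[-1], enumerated = plan$enumerate)
  }
  structure(list(statistic = Fv, p.value = pv, n_perm = nrow(Pidx),
                 permute = permute, enumerated = plan$enumerate,
                 metric = metric, model = model, seed = seed,
                 call = match.call()),
            class = "permanova_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.permanova_fit <- function(x, ...) {
  cat("Matched-set PERMANOVA (", x$metric, " distance, ",
      if (x$enumerated) "exhaustive " else "", x$n_perm, " ",
      x$permute, " permutations)\n", sep = "")
  print(data.frame(submodel = names(x$statistic),
                   pseudo.F = signif(x$statistic, 5),
                   p.value = signif(x$p.value, 5), row.names = NULL))
  invisible(x)
}

#' @export
summary.permanova_fit <- function(object, ...) {
  print(object)
  cat("p-value resolution:", signif(1 / (1 + object$n_perm), 3), "\n")
  invisible(object)
}
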