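# LDM-style global and per-OTU tests on the frequency and arcsin-root
# scales, with min-p omnibus combination over scales and permutation-based
# OTU discovery.

#' Relative-abundance response matrix
#'
#' Converts counts to relative abundances (rows sum to 1) and column-centers
#' the result, giving the frequency-scale response of the linear model.
#'
#' @param table samples x OTUs count matrix with positive row totals.
#' @return column-centered samples x OTUs numeric matrix.
#' @export
to_frequency <- function(table) {
  center_columns(.rel_abund(table))
}

#' Arcsin-root transformed response matrix
#'
#' Applies `asin(sqrt(f))` elementwise to a frequency matrix (values in
#' `[0, 1]`), a variance-stabilizing transformation for proportions, then
#' column-centers.
#'
#' @param freqs matrix of relative abundances in `[0, 1]` (not yet centered).
#' @return column-centered transformed matrix.
#' @export
arcsin_root <- function(freqs) {
  f <- as.matrix(freqs)
  if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
  center_columns(asin(sqrt(f)))
}

#' Filter rarely observed OTUs
#'
#' Retains OTUs with at least `min_nonzero` samples having a positive count.
#'
#' @param table samples x OTUs count matrix.
#' @param min_nonzero minimum number of non-zero entries (default 5).
#' @return the filtered count matrix.
#' @export
filter_otus <- function(table, min_nonzero = 5L) {
  X <- as.matrix(table)
  keep <- colSums(X > 0) >= min_nonzero
  if (!any(keep)) stop("all OTUs removed by the non-zero filter")
  X[, keep, drop = FALSE]
}

#' LDM global and per-OTU statistics
#'
#' For tested block `k`, the per-OTU statistic is
#' `F_kj = ||X_k' y_j||^2 / ||y_j - sum_k' X_k' X_k'' y_j||^2` (full-model
#' residual) and the global statistic is the ratio of the summed numerators
#' to the summed residuals. Both are functions of `X_k' Y` only.
#'
#' @param model a `"model_matrix"` from [build_design()].
#' @param Y column-centered response matrix (see [to_frequency()]).
#' @param k tested block index within `model$blocks`.
#' @return list with `global` (single statistic) and `per_otu` (named
#'   vector, one statistic per response column).
#' @export
ldm_statistics <- function(model, Y, k) {
  stopifnot(inherits(model, "model_matrix"))
  Y <- as.matrix(Y)
  if (k < 1L || k > length(model$blocks) || ncol(model$blocks[[k]]) == 0L)
    stop("tested submodel has no retained columns")
  num <- colSums(crossprod(model$blocks[[k]], Y)^2)
  expl <- 0
  for (B in model$blocks) expl <- expl + colSums(crossprod(B, Y)^2)
  resid <- colSums(Y^2) - expl
  if (all(resid <= 0)) stop("zero residual for every OTU")
  per <- num / resid
  names(per) <- colnames(Y)
  list(global = sum(num) / sum(resid), per_otu = per)
}

#' OTU discovery at a nominal FDR
#'
#' Benjamini-Hochberg step-up applied to per-OTU permutation p-values.
#'
#' @param p per-OTU p-values in (0, 1].
#' @param nominal_fdr nominal false discovery rate (default 0.10).
#' @return list with `detected` (indices, named if `p` is named) and `q`
#'   (BH-adjusted q-values).
#' @export
detect_otus <- function(p, nominal_fdr = 0.10) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(detected = which(q <= nominal_fdr), q = q)
}

#' LDM-style test for matched-set microbiome data
#'
#' Community-level and OTU-level permutation tests on the frequency and/or
#' arcsin-root scales, combined by a min-p omnibus over a shared permutation
#' stream. The design and permutation strategy are the same as in
#' [permanova_test()]: set indicators in the nuisance block, restricted
#' permutation of the orthonormalized trait block within sets.
#'
#' Per-OTU p-values come from the same permutation stream; OTU discovery
#' applies Benjamini-Hochberg to the per-OTU omnibus p-values at
#' `nominal_fdr`. Their resolution is bounded by `1/(1+n_perm)`: a small
#' `n_perm` coarsens the attainable q-values.
#'
#' @inheritParams permanova_test
#' @param scales character subset of `c("freq", "arcsin")`.
#' @param nominal_fdr nominal FDR for [detect_otus()].
#' @param test_otus compute per-OTU p-values and detections (set `FALSE` to
#'   save time when only the global test is needed).
#' @param min_nonzero drop OTUs with fewer non-zero entries before testing
#'   (0 = keep all; the simulation studies use 5).
#' @return an object of class `"ldm_fit"`: `global` (data.frame of
#'   submodel/scale statistics and p-values), `omnibus_p` (named per
#'   submodel), `otu` (per-submodel data.frames of per-OTU statistics,
#'   p-values, q-values and detection flags), `n_perm`, `scales`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_sets = 10, n_otus = 40, beta = 0.5,
#'                                    seed = 1))
#' fit <- ldm_test(sim$counts, sim$metadata, trait = "trait", n_perm = 99)
#' fit$omnibus_p
#' @export
ldm_test <- function(table, metadata, trait, set_col = "set_id",
                     confounders = NULL, adjust_set_id = TRUE,
                     scales = c("freq", "arcsin"),
                     permute = c("within_set", "free"),
                     n_perm = 10000L, seed = 1L, enumerate = FALSE,
                     nominal_fdr = 0.10, test_otus = TRUE,
                     min_nonzero = 0L) {
  permute <- match.arg(permute)
  scales <- match.arg(scales, c("freq", "arcsin"), several.ok = TRUE)
  table <- as.matrix(table)
  if (min_nonzero > 0L) table <- filter_otus(table, min_nonzero)
  f <- .rel_abund(table)
  Ys <- lapply(stats::setNames(scales, scales), function(s)
    if (s == "freq") center_columns(f) else arcsin_root(f))
  md <- .design_from_metadata(table, metadata, trait, set_col, confounders,
                              adjust_set_id)
  model <- build_design(md)
  plan <- permutation_plan(permute, n_perm, seed, set_ids = md$set_ids,
                           enumerate = enumerate)
  Pidx <- draw_permutations(plan, model$n_samples)
  B <- nrow(Pidx)
  glob <- NULL; omni <- c(); otu_res <- list()
  for (i in seq_along(model$tested)) {
    k <- model$tested[i]; nm <- names(model$tested)[i]
    repr <- .needs_reproject(model, k, permute)
    st <- lapply(Ys, .perm_stats, signs = NULL, model = model, k = k,
                 Pidx = Pidx, reproject = repr, per_feature = test_otus)
    ranks <- vapply(st, function(s) .p_ranks(s$F), numeric(B + 1L))
    m <- if (length(scales) > 1L) do.call(pmin, asplit(ranks, 2L)) else ranks[, 1L]
    omni[nm] <- if (plan$enumerate) mean(m[-1L] <= m[1L]) else
      (1 + sum(m[-1L] <= m[1L])) / (1 + B)
    for (s in scales)
      glob <- rbind(glob, data.frame(
        submodel = nm, scale = s, statistic = st[[s]]$F[1],
        p.value = permutation_pvalue(st[[s]]$F[1], st[[s]]$F[-1],
                                     enumerated = plan$enumerate)))
    if (test_otus) {
      J <- ncol(table)
      pJ <- sapply(st, function(s) {
        FJ <- s$F_feature
        if (plan$enumerate)
          colMeans(FJ[-1L, , drop = FALSE] >=
                     matrix(FJ[1L, ], B, J, byrow = TRUE))
        else (1 + colSums(FJ[-1L, , drop = FALSE] >=
                            matrix(FJ[1L, ], B, J, byrow = TRUE))) / (1 + B)
      })
      if (!is.matrix(pJ))
        pJ <- matrix(pJ, nrow = J, dimnames = list(NULL, names(st)))
      RJ <- lapply(st, function(s) apply(s$F_feature, 2L, .p_ranks))
      MJ <- Reduce(pmin, RJ)
      pJo <- if (plan$enumerate)
        colMeans(MJ[-1L, , drop = FALSE] <=
                   matrix(MJ[1L, ], B, J, byrow = TRUE))
      else (1 + colSums(MJ[-1L, , drop = FALSE] <=
                          matrix(MJ[1L, ], B, J, byrow = TRUE))) / (1 + B)
      det <- detect_otus(pJo, nominal_fdr)
      df <- data.frame(otu = colnames(table) %||% paste0("otu", seq_len(J)),
                       row.names = NULL)
      for (s in scales) {
        df[[paste0("stat.", s)]] <- st[[s]]$F_feature[1L, ]
        df[[paste0("p.", s)]] <- pJ[, s]
      }
      df$p.omnibus <- pJo
      df$q <- det$q
      df$detected <- det$q <= nominal_fdr
      otu_res[[nm]] <- df
    }
  }
  structure(list(global = glob, omnibus_p = omni, otu = otu_res,
                 n_perm = B, scales = scales, permute = permute,
                 enumerated = plan$enumerate, nominal_fdr = nominal_fdr,
                 model = model, seed = seed, call = match.call()),
            class = "ldm_fit")
}

#' @export
print.ldm_fit <- function(x, ...) {
  cat("Matched-set LDM test (scales: ", paste(x$scales, collapse = "+"),
      "; ", if (x$enumerated) "exhaustive " else "", x$n_perm, " ",
      x$permute, " permutations)\n", sep = "")
  g <- x$global
  g$statistic <- signif(g$statistic, 5); g$p.value <- signif(g$p.value, 5)
  print(g, row.names = FALSE)
  cat("omnibus p:",
      paste(names(x$omnibus_p), signif(x$omnibus_p, 5), sep = " = ",
            collapse = ", "), "\n")
  for (nm in names(x$otu))
    cat(sum(x$otu[[nm]]$detected), " OTU(s) detected for '", nm,
        "' at nominal FDR ", x$nominal_fdr, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ldm_fit <- function(object, n = 10L, ...) {
  print(object)
  for (nm in names(object$otu)) {
    df <- object$otu[[nm]]
    df <- df[order(df$p.omnibus), , drop = FALSE]
    cat("\nTop OTUs for '", nm, "':\n", sep = "")
    print(utils::head(df, n), row.names = FALSE)
  }
  invisible(object)
}
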