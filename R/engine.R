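# Shared permutation-statistic engine for the PERMANOVA and LDM tests.
#
# The tested block X_k is permuted by rows (equivalent to permuting residuals
# of Y in the Freedman-Lane scheme). Re-orthogonalization of the permuted
# block against the fixed blocks is performed only when within-set
# permutation can break orthogonality: within-set permutation preserves
# orthogonality to set-indicator columns exactly (within-set sums are
# permutation-invariant), so when the only fixed block is the pure
# set-indicator nuisance no re-projection is needed; with sample-level
# confounders or additional fixed submodels, the permuted block is
# re-projected off all fixed columns and re-orthonormalized. Unrestricted
# ("free") permutation deliberately permutes rows without re-projection and
# keeps the orthogonality-based residual formula, mirroring what the
# decomposition software does when handed a free permutation scheme; with
# strong between-set heterogeneity the nominal residual trace can then go
# negative for permuted draws, which is the mechanism behind the documented
# anti-conservatism/conservatism of the unrestricted strategy.

.needs_reproject <- function(model, k, mode) {
  fixed <- setdiff(seq_along(model$blocks), k)
  if (!length(fixed)) return(FALSE)
  if (mode == "free") return(FALSE)
  !(length(fixed) == 1L && model$roles[fixed] == "nuisance" &&
      isTRUE(model$pure_set_nuisance))
}

# Permuted versions of the tested block, re-orthonormalized when required.
# Returns a list of n x (B+1) matrices, one per column of X_k; column 1 of
# each is the observed (identity) ordering.
.permuted_block <- function(model, k, Pidx, reproject) {
  Xk <- model$blocks[[k]]
  n <- nrow(Xk); B <- nrow(Pidx)
  fixed <- setdiff(seq_along(model$blocks), k)
  N <- if (length(fixed)) do.call(cbind, model$blocks[fixed]) else NULL
  tidx <- as.vector(t(Pidx))
  out <- vector("list", ncol(Xk))
  for (cc in seq_len(ncol(Xk))) {
    x <- Xk[, cc]
    Xp <- cbind(x, matrix(x[tidx], n, B))
    if (reproject) {
      if (!is.null(N)) Xp <- Xp - N %*% crossprod(N, Xp)
      if (cc > 1L) for (pp in seq_len(cc - 1L)) {
        d <- colSums(out[[pp]] * Xp)
        Xp <- Xp - sweep(out[[pp]], 2L, d, "*")
      }
      nrm <- sqrt(colSums(Xp^2))
      ok <- nrm > 1e-12 * max(nrm)
      Xp <- sweep(Xp, 2L, ifelse(ok, nrm, 1), "/")
      Xp[, !ok] <- 0
    }
    out[[cc]] <- Xp
  }
  out
}

# Core statistic streams for one tested block.
#
# Y: n x r response (LDM scale matrix, or the signed embedding); signs: NULL
# for LDM, +/-1 vector for PERMANOVA. Returns the observed-first F stream
# (length B+1) and, for per_feature = TRUE, the (B+1) x r per-feature F
# matrix. F is num/(tot - num) with tot the permutation-invariant part of the
# residual trace, valid because the permuted block is orthonormal to the
# fixed blocks.
.perm_stats <- function(Y, signs, model, k, Pidx, reproject,
                        per_feature = FALSE) {
  Xp <- .permuted_block(model, k, Pidx, reproject)
  fixed <- setdiff(seq_along(model$blocks), k)
  fixed_expl <- if (length(fixed)) {
    N <- do.call(cbind, model$blocks[fixed])
    colSums(crossprod(N, Y)^2)
  } else rep(0, ncol(Y))
  tot_r <- colSums(Y^2) - fixed_expl          # residual-plus-tested, per axis
  numR <- 0
  for (cc in seq_along(Xp)) numR <- numR + crossprod(Xp[[cc]], Y)^2
  safe_ratio <- function(num, den) {
    Fg <- num / den                            # negative dens rank low
    Fg[num > 0 & den == 0] <- .Machine$double.xmax
    Fg[num == 0 & den <= 0] <- 0
    Fg[is.nan(Fg)] <- 0
    Fg
  }
  if (is.null(signs)) {                        # LDM
    num <- rowSums(numR)
    tot <- sum(tot_r)
    res <- list(F = as.numeric(safe_ratio(num, tot - num)),
                num = as.numeric(num), tot = tot)
    if (per_feature)
      res$F_feature <- safe_ratio(numR, sweep(-numR, 2L, tot_r, "+"))
    res
  } else {                                     # PERMANOVA (signed axes)
    num <- as.numeric(numR %*% signs)
    tot <- sum(signs * tot_r)
    list(F = as.numeric(safe_ratio(num, tot - num)), num = num, tot = tot)
  }
}

# exceedance p-ranks of every entry of an observed-first stream:
# r_b = #\{b': F_b' >= F_b\} / (B+1); smaller means more extreme
.p_ranks <- function(Fs) {
  (length(Fs) + 1 - rank(Fs, ties.method = "min")) / length(Fs)
}
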