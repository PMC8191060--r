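# Fixtures are generated programmatically; no stored data.

# small random count table with named samples/OTUs
rand_table <- function(n, J, seed = 1, depth = 2000) {
  set.seed(seed)
  f <- matrix(rgamma(n * J, shape = 0.5), n, J)
  f <- f / rowSums(f)
  counts <- t(vapply(seq_len(n), function(i)
    as.integer(rmultinom(1, depth, f[i, ])), integer(J)))
  dimnames(counts) <- list(paste0("s", seq_len(n)), paste0("otu", seq_len(J)))
  counts
}

# matched-pair null/effect dataset via the package simulator
paired_sim <- function(n_sets = 10, n_otus = 40, beta = 0, seed = 1, ...) {
  simulate_dataset(sim_config(n_sets = n_sets, n_otus = n_otus, beta = beta,
                              seed = seed, ...))
}

# OLS F oracle: (RSS_reduced - RSS_full) / RSS_full for one response,
# independent of the package's projection arithmetic
ols_F <- function(y, X_nuisance, X_test) {
  full <- cbind(X_nuisance, X_test)
  rss <- function(X) {
    if (is.null(X)) return(sum((y - mean(y))^2))
    sum(resid(lm(y ~ X))^2)
  }
  (rss(X_nuisance) - rss(full)) / rss(full)
}

expect_simplex <- function(p, tol = 1e-10) {
  expect_true(all(p >= -tol))
  expect_lt(abs(sum(p) - 1), tol)
}
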