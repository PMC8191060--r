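test_that("frequency and arcsin-root responses are centered transforms", {
  tab <- rbind(a = c(2, 2, 0), b = c(1, 1, 2))
  f <- tab / rowSums(tab)
  expect_equal(unname(f["a", ]), c(0.5, 0.5, 0))
  Yf <- to_frequency(tab)
  expect_lt(max(abs(colSums(Yf))), 1e-12)
  expect_equal(asin(sqrt(0)), 0)
  expect_equal(asin(sqrt(1)), pi / 2)
  expect_equal(asin(sqrt(0.25)), pi / 6, tolerance = 1e-12)
  fs <- seq(0, 1, 0.1)
  expect_true(all(diff(asin(sqrt(fs))) > 0))  # monotone
  Ya <- arcsin_root(f)
  expect_lt(max(abs(colSums(Ya))), 1e-12)
  expect_error(arcsin_root(matrix(c(-0.1, 0.5), 1)), "\\[0, 1\\]")
  # single constant column centers to zero
  expect_equal(unname(to_frequency(matrix(c(4, 7), 2))), matrix(0, 2, 1))
})

test_that("the OTU prevalence filter applies the non-zero threshold", {
  tab <- cbind(rare = c(1, 1, 1, 1, 0, 0), edge = c(1, 1, 1, 1, 1, 0),
               common = rep(2, 6))
  kept <- filter_otus(tab, 5)
  expect_equal(colnames(kept), c("edge", "common"))
  expect_equal(filter_otus(tab, 0), tab)
  expect_error(filter_otus(tab, 7), "all OTUs removed")
})

test_that("LDM statistics equal the regression oracle per OTU", {
  tab <- rand_table(8, 20, seed = 6)
  sets <- rep(1:4, each = 2)
  set.seed(6)
  conf <- rnorm(8)
  md <- matched_design(sets, list(t = rep(c(1, 0), 4)), confounders = conf)
  mm <- build_design(md)
  Y <- to_frequency(tab)
  st <- ldm_statistics(mm, Y, mm$tested["t"])
  Z <- cbind(center_columns(make_set_indicators(sets))[, 1:3], conf)
  xt <- rep(c(1, 0), 4)
  for (j in seq_len(ncol(Y)))
    expect_equal(unname(st$per_otu[j]), ols_F(Y[, j], Z, xt),
                 tolerance = 1e-10)
  # global equals summed numerators over summed residuals
  num <- colSums(crossprod(mm$blocks[[mm$tested["t"]]], Y)^2)
  expect_equal(st$global, sum(num) / sum(num / st$per_otu), tolerance = 1e-10)
  # response orthogonal to the tested block gives a zero statistic
  xt <- mm$blocks[[mm$tested["t"]]]
  yo <- center_columns(rnorm(8))
  yo <- yo - xt %*% crossprod(xt, yo)
  expect_equal(ldm_statistics(mm, yo, mm$tested["t"])$global, 0,
               tolerance = 1e-12)
})

test_that("statistics ignore per-set constants when set IDs are adjusted", {
  tab <- rand_table(10, 15, seed = 9)
  sets <- rep(1:5, each = 2)
  md <- matched_design(sets, list(t = rep(c(1, 0), 5)))
  mm <- build_design(md)
  Y <- to_frequency(tab)
  Y2 <- Y
  Y2[sets == 3, 4] <- Y2[sets == 3, 4] + 11
  s1 <- ldm_statistics(mm, center_columns(Y), mm$tested["t"])
  s2 <- ldm_statistics(mm, center_columns(Y2), mm$tested["t"])
  expect_equal(s1$per_otu, s2$per_otu, tolerance = 1e-8)
})

test_that("explained plus residual sums of squares give the total", {
  tab <- rand_table(12, 30, seed = 2)
  sets <- rep(1:6, each = 2)
  set.seed(2)
  md <- matched_design(sets, list(t = rep(c(1, 0), 6), u = rnorm(12)))
  mm <- build_design(md)
  Y <- to_frequency(tab)
  expl <- sum(vapply(mm$blocks, function(B) sum(crossprod(B, Y)^2), numeric(1)))
  resid <- sum(Y^2) - expl
  expect_equal(expl + resid, sum(Y^2), tolerance = 1e-8)
  expect_gt(resid, 0)
})

test_that("BH detection behaves as the step-up procedure", {
  p <- c(rep(0.001, 10), rep(1, 90))
  det <- detect_otus(p, 0.10)
  expect_equal(det$detected, 1:10)
  expect_equal(detect_otus(rep(1, 20), 0.10)$detected, integer(0))
  # monotone in the nominal rate
  p2 <- runif(50)^2
  d1 <- detect_otus(p2, 0.05)$detected
  d2 <- detect_otus(p2, 0.20)$detected
  expect_true(all(d1 %in% d2))
  expect_error(detect_otus(c(0, 0.5), 0.1), "\\(0, 1\\]")
})

test_that("ldm_test returns coherent global, omnibus and per-OTU results", {
  sim <- paired_sim(n_sets = 12, n_otus = 40, beta = 0.6, seed = 23)
  fit <- ldm_test(sim$counts, sim$metadata, "trait", n_perm = 499, seed = 3,
                  min_nonzero = 5)
  expect_true(all(fit$global$p.value > 0 & fit$global$p.value <= 1))
  B <- fit$n_perm
  expect_lte(fit$omnibus_p, max(fit$global$p.value) + 1 / (1 + B))
  df <- fit$otu$trait
  expect_true(all(df$detected == (df$q <= 0.10)))
  expect_true(all(df$otu %in% colnames(sim$counts)))
  # single-scale omnibus equals the scale p-value
  f1 <- ldm_test(sim$counts, sim$metadata, "trait", scales = "freq",
                 n_perm = 499, seed = 3, test_otus = FALSE)
  expect_equal(unname(f1$omnibus_p), f1$global$p.value, tolerance = 1e-12)
  expect_output(print(fit), "omnibus")
})

test_that("set-ID adjustment leaves balanced-design p-values bitwise unchanged", {
  sim <- paired_sim(n_sets = 10, n_otus = 30, beta = 0.2, seed = 29)
  a <- ldm_test(sim$counts, sim$metadata, "trait", adjust_set_id = TRUE,
                n_perm = 400, seed = 8)
  b <- ldm_test(sim$counts, sim$metadata, "trait", adjust_set_id = FALSE,
                n_perm = 400, seed = 8)
  expect_identical(a$omnibus_p, b$omnibus_p)
  expect_identical(a$otu$trait$p.omnibus, b$otu$trait$p.omnibus)
})
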