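test_that("the geometric baseline composition is a decreasing simplex", {
  expect_equal(make_baseline_composition(3, 0.5), c(4, 2, 1) / 7,
               tolerance = 1e-14)
  expect_equal(make_baseline_composition(5, 1), rep(0.2, 5))
  p <- make_baseline_composition(856)
  expect_simplex(p)
  expect_true(all(diff(p) < 0))
  expect_error(make_baseline_composition(10, 0), "shape")
})

test_that("the Dirichlet mean/overdispersion link has the right total mass", {
  m <- c(0.5, 0.3, 0.2)
  expect_equal(sum(dirichlet_from_mean(m, 0.5)), 1)
  expect_equal(sum(dirichlet_from_mean(m, 0.02)), 49)
  expect_error(dirichlet_from_mean(m, 1.2), "theta")
  # Monte-Carlo mean check
  set.seed(5)
  a <- dirichlet_from_mean(m, 0.05)
  g <- matrix(rgamma(3000 * 3, shape = rep(a, each = 3000)), 3000, 3)
  P <- g / rowSums(g)
  se <- sqrt(m * (1 - m) * 0.05 / 3000)
  expect_true(all(abs(colMeans(P) - m) < 4 * se))
})

test_that("trait assignment gives one case per binary set and U[0,1] otherwise", {
  tr <- assign_traits(c(2, 3, 4), "binary")
  expect_equal(as.vector(tapply(tr, rep(1:3, c(2, 3, 4)), sum)), rep(1, 3))
  set.seed(1)
  tc <- assign_traits(rep(2, 50), "continuous")
  expect_true(all(tc >= 0 & tc <= 1))
})

test_that("causal-set assignment follows the two mechanisms", {
  base <- make_baseline_composition(856)
  cs <- assign_causal_sets(base, "S1", seed = 2)
  expect_equal(length(cs$trait_minus), 214)
  expect_equal(length(cs$trait_plus_a), 107)
  expect_equal(length(cs$trait_plus_m), 107)
  expect_false(any(cs$trait_minus %in% c(cs$trait_plus_a, cs$trait_plus_m)))
  expect_false(any(1:3 %in% c(cs$trait_minus, cs$trait_plus_a, cs$trait_plus_m)))
  cs2 <- assign_causal_sets(base, "S2", seed = 2)
  expect_true(all(sort(c(cs2$trait_minus, cs2$trait_plus_a, cs2$trait_plus_m))
                  == 1:10))
  expect_true(all(sort(c(cs2$int_minus, cs2$int_plus)) == c(1:5, 11:15)))
  expect_error(assign_causal_sets(make_baseline_composition(8), "S2"), "S2")
})

test_that("the trait effect matches the hand example and interpolates", {
  cs <- structure(list(trait_minus = 1L, trait_plus_a = 2L, trait_plus_m = 3L),
                  class = "causal_sets")
  pi0 <- c(0.4, 0.3, 0.2, 0.1)
  full <- apply_trait_effect(pi0, 0.5, cs, 1)
  expect_equal(full, c(0.2, 0.4, 0.3, 0.1), tolerance = 1e-14)
  expect_equal(apply_trait_effect(pi0, 0, cs, 1), pi0)
  half <- apply_trait_effect(pi0, 0.5, cs, 0.5)
  expect_equal(half, (pi0 + full) / 2, tolerance = 1e-14)
  expect_simplex(full)
})

test_that("covariate, confounder and interaction effects conserve mass", {
  cs <- structure(list(set_minus = 1L, set_plus = 2:3,
                       sam_minus = 2L, sam_plus = c(1L, 3L),
                       int_minus = 3L, int_plus = 1:2),
                  class = "causal_sets")
  p <- c(0.5, 0.3, 0.2)
  expect_equal(apply_set_covariate(p, 0, causal = cs), p)
  q <- apply_set_covariate(p, 1, 0.2, cs)
  expect_simplex(q)
  expect_equal(q[1], 0.4)
  expect_equal(q[2:3], p[2:3] + 0.1 * p[2:3] / 0.5, tolerance = 1e-14)
  expect_equal(apply_sample_confounder(p, 0, causal = cs), p)
  expect_simplex(apply_sample_confounder(p, 1, 0.5, cs))
  expect_equal(apply_interaction(p, 0, 1, 0.5, cs), p)
  expect_equal(apply_interaction(p, 1, 0, 0.5, cs), p)
  expect_simplex(apply_interaction(p, 1, 1, 0.5, cs))
})

test_that("read depths follow the floored Poisson-multinomial scheme", {
  set.seed(7)
  n <- replicate(300, sum(draw_counts(c(0.6, 0.4), depth_mean = 600,
                                      depth_floor = 500)))
  expect_true(all(n >= 500))
  cnt <- draw_counts(c(0, 1, 0), seed = 1)
  expect_equal(which(cnt > 0), 2L)
  d <- replicate(400, sum(draw_counts(c(0.5, 0.5), depth_mean = 10000)))
  expect_lt(abs(mean(d) - 10000) / 10000, 0.01)
})

test_that("simulate_dataset composes the hierarchy with recorded truth", {
  sim <- simulate_dataset(sim_config(n_sets = 10, n_otus = 60, beta = 0.5,
                                     set_covariate = TRUE,
                                     sample_confounder = TRUE, seed = 4))
  expect_equal(dim(sim$counts), c(20L, 60L))
  expect_true(all(rowSums(sim$counts) >= 500))
  for (M in sim$truth[c("pi_bar", "pi0", "pi")])
    expect_lt(max(abs(rowSums(M) - 1)), 1e-10)
  expect_true(all(sim$truth$pi >= 0))
  expect_true(all(c("x_set", "x_sam") %in% names(sim$metadata)))
  # null dataset carries no signal flag
  expect_equal(sim_config(beta = 0)$beta, 0)
})

test_that("scenario presets and design grids match the stated layouts", {
  s2 <- sim_scenario(2, n_otus = 50)
  expect_equal(s2$m, rep(1:2, each = 25))
  expect_equal(sum(1 + s2$m), 125L)
  s7 <- sim_scenario(7, n_otus = 50, beta_int = 0.4)
  expect_true(s7$set_covariate && s7$interaction)
  expect_equal(s7$beta, 0.5)
  for (m in 1:5)
    expect_equal(sum(1 + design_grid("fixed_total_90", m)), 90L)
  expect_equal(design_grid("fixed_sets_50", 3), rep(3L, 50))
})

test_that("between-set overdispersion is recovered by method of moments", {
  base <- make_baseline_composition(150)
  set.seed(10)
  a <- dirichlet_from_mean(base, 0.02)
  P <- matrix(rgamma(500 * 150, shape = rep(a, each = 500)), 500, 150)
  P <- P / rowSums(P)
  th <- mom_overdispersion(P, base)
  expect_lt(abs(th - 0.02) / 0.02, 0.30)
})

test_that("case and control samples are exchangeable under the null", {
  set.seed(33)
  # within-pair frequency difference of a fixed OTU has symmetric sign
  d <- replicate(80, {
    sim <- paired_sim(n_sets = 6, n_otus = 30, beta = 0,
                      seed = sample.int(1e6, 1))
    f <- sim$counts / rowSums(sim$counts)
    mean(f[sim$metadata$trait == 1, 1] - f[sim$metadata$trait == 0, 1])
  })
  expect_gt(binom.test(sum(d > 0), length(d))$p.value, 0.01)
})
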