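test_that("Bray-Curtis and Hellinger distances match hand computations", {
  tab <- rbind(a = c(10, 10, 0), b = c(5, 5, 10), c = c(10, 10, 0))
  D <- bray_curtis(tab)
  expect_equal(unname(D["a", "c"]), 0)
  expect_equal(unname(D["a", "b"]), 0.5)   # (0.25+0.25+0.5)/2
  disj <- rbind(x = c(5, 0), y = c(0, 7))
  expect_equal(unname(bray_curtis(disj)["x", "y"]), 1)
  H <- hellinger(rbind(x = c(5, 5), y = c(10, 0)))
  expect_equal(unname(H["x", "y"]), sqrt((sqrt(0.5) - 1)^2 + 0.5),
               tolerance = 1e-12)
  expect_equal(unname(hellinger(rbind(c(4, 0), c(0, 4)))[1, 2]), sqrt(2))
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 2))), "positive total")
})

test_that("Gower centering zeroes margins and matches the 2-sample form", {
  D2 <- matrix(c(0, 3, 3, 0), 2)
  expect_equal(gower_center(D2), (9 / 4) * matrix(c(1, -1, -1, 1), 2))
  D <- bray_curtis(rand_table(7, 30, seed = 5))
  Dl <- gower_center(D)
  expect_lt(max(abs(rowSums(Dl))), 1e-10)
  expect_lt(max(abs(colSums(Dl))), 1e-10)
  expect_equal(gower_center(matrix(0, 4, 4)), matrix(0, 4, 4))
})

test_that("the signed eigen-embedding reconstructs the Gower matrix", {
  Dl <- gower_center(bray_curtis(rand_table(6, 25, seed = 8)))
  dec <- decompose_gower(Dl)
  rec <- dec$embedding %*% (dec$signs * t(dec$embedding))
  expect_lt(max(abs(rec - Dl)), 1e-8 * max(abs(Dl)))
  # Bray-Curtis is non-Euclidean: negative axes appear (and are kept)
  dec_big <- decompose_gower(gower_center(bray_curtis(rand_table(20, 40,
                                                                 seed = 8))))
  expect_true(any(dec_big$signs == -1))
  rec_big <- dec_big$embedding %*% (dec_big$signs * t(dec_big$embedding))
  expect_lt(max(abs(rec_big - gower_center(bray_curtis(rand_table(20, 40,
                                                                  seed = 8))))),
            1e-8 * max(abs(rec_big)))
  # Euclidean-embeddable case: all signs positive
  Y <- center_columns(matrix(rnorm(40), 8))
  decE <- decompose_gower(gower_center(as.matrix(dist(Y))))
  expect_true(all(decE$signs == 1))
  # 2-sample case: one axis, ||y||^2 = d^2/2
  d2 <- decompose_gower(gower_center(matrix(c(0, 3, 3, 0), 2)))
  expect_equal(ncol(d2$embedding), 1L)
  expect_equal(d2$signs, 1)
  expect_equal(sum(d2$embedding^2), 9 / 2, tolerance = 1e-12)
})

test_that("pseudo-F equals the least-squares oracle and honours invariances", {
  # 1 embedding dimension: F = SSR/SSE of univariate regression
  set.seed(12)
  sets <- rep(1:4, each = 2)
  y <- rnorm(8)
  D <- as.matrix(dist(y))
  md <- matched_design(sets, list(t = rep(c(1, 0), 4)))
  mm <- build_design(md)
  dec <- decompose_gower(gower_center(D))
  expect_equal(ncol(dec$embedding), 1L)
  Z <- center_columns(make_set_indicators(sets))[, 1:3]
  xt <- rep(c(1, 0), 4)
  expect_equal(pseudo_F(mm, dec, mm$tested["t"]), ols_F(y, Z, xt),
               tolerance = 1e-10)
  # orthogonal block gives 0
  dec0 <- list(embedding = mm$blocks[[1]][, 1, drop = FALSE], signs = 1)
  expect_equal(pseudo_F(mm, dec0, mm$tested["t"]), 0, tolerance = 1e-12)
  # scale invariance of the F-ratio
  dec2 <- decompose_gower(gower_center(2 * D))
  expect_equal(pseudo_F(mm, dec, mm$tested["t"]),
               pseudo_F(mm, dec2, mm$tested["t"]), tolerance = 1e-10)
  # adding a set-level constant to the embedding rows of a set changes nothing
  E <- dec$embedding
  E[sets == 2, ] <- E[sets == 2, ] + 5
  decS <- list(embedding = E, signs = dec$signs)
  num <- function(d) sum(d$signs * colSums(crossprod(mm$blocks[[mm$tested["t"]]],
                                                     d$embedding)^2))
  expect_equal(num(decS), num(dec), tolerance = 1e-8)
})

test_that("explained and residual traces decompose tr(Delta)", {
  tab <- rand_table(10, 40, seed = 3)
  sets <- rep(1:5, each = 2)
  set.seed(3)
  md <- matched_design(sets, list(t = rep(c(1, 0), 5), u = rnorm(10)))
  mm <- build_design(md)
  dec <- decompose_gower(gower_center(bray_curtis(tab)))
  Y <- dec$embedding; s <- dec$signs
  expl <- vapply(mm$blocks, function(B)
    sum(s * colSums(crossprod(B, Y)^2)), numeric(1))
  resid <- sum(s * colSums(Y^2)) - sum(expl)
  expect_equal(sum(expl) + resid, sum(s * colSums(Y^2)), tolerance = 1e-8)
  # and tr(Delta) equals the signed embedding total
  expect_equal(sum(diag(gower_center(bray_curtis(tab)))),
               sum(s * colSums(Y^2)), tolerance = 1e-8)
})

test_that("permanova_test finds a strong within-pair effect and stays exchangeable", {
  sim <- paired_sim(n_sets = 12, n_otus = 50, beta = 0.8, seed = 31)
  fit <- permanova_test(sim$counts, sim$metadata, "trait", n_perm = 999,
                        seed = 5)
  # minimal attainable p up to ties with the global sign-flip complement,
  # which yields the same statistic on pair designs
  expect_lte(unname(fit$p.value), 3 / 1000)
  expect_s3_class(fit, "permanova_fit")
  expect_output(print(fit), "PERMANOVA")
})

test_that("PERMANOVA with Euclidean distance on centered frequencies matches LDM", {
  sim <- paired_sim(n_sets = 4, n_otus = 30, beta = 0.3, seed = 17)
  f <- sim$counts / rowSums(sim$counts)
  D <- as.matrix(dist(center_columns(f)))
  pe <- permanova_test(sim$counts, sim$metadata, "trait", distance = D,
                       enumerate = TRUE, seed = 1)
  le <- ldm_test(sim$counts, sim$metadata, "trait", scales = "freq",
                 enumerate = TRUE, seed = 1, test_otus = FALSE)
  expect_equal(unname(pe$p.value), unname(le$global$p.value),
               tolerance = 1e-12)
})
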