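# Dirichlet-multinomial simulator for matched-set microbiome count data.
#
# Hierarchy: population composition pi_bar -> (optional set-level covariate
# modification) -> set mean pi_bar_i ~ Dir(pi_bar, theta1) -> sample baseline
# pi0_ij ~ Dir(pi_bar_i, theta2) -> trait effect -> (optional sample-level
# confounder, optional set x trait interaction) -> multinomial counts at
# Poisson read depth. theta1 captures between-set and theta2 within-set
# compositional heterogeneity. "Reducing by a factor beta" multiplies the
# affected frequencies by (1 - beta).

.run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Synthetic baseline composition
#'
#' A rank-ordered long-tailed composition used as the population mean of OTU
#' frequencies: normalized geometric decay with ratio `shape`. `shape = 1`
#' gives the uniform composition; the default 0.985 over several hundred
#' OTUs yields a realistic long tail with a few dominant taxa. Synthetic
#' stand-in for a composition estimated from real data; any user-supplied
#' probability vector may be used instead throughout the simulator.
#'
#' @param n_otus number of OTUs (>= 2).
#' @param shape geometric decay ratio in (0, 1].
#' @return strictly positive probability vector, decreasing, summing to 1.
#' @export
make_baseline_composition <- function(n_otus, shape = 0.985) {
  if (n_otus < 2L) stop("need at least two OTUs")
  if (shape <= 0 || shape > 1) stop("shape must lie in (0, 1]")
  v <- shape^(seq_len(n_otus) - 1L)
  v / sum(v)
}

#' Dirichlet concentration from mean and overdispersion
#'
#' Mean/overdispersion parameterization: `alpha_j = mean_j (1 - theta) /
#' theta`, so the total concentration is `(1 - theta) / theta` and the
#' marginal variance of component j is `mean_j (1 - mean_j) theta`.
#'
#' @param mean probability vector.
#' @param theta overdispersion in (0, 1).
#' @return concentration (alpha) vector.
#' @export
dirichlet_from_mean <- function(mean, theta) {
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  mean * (1 - theta) / theta
}

# one draw per row of the alpha matrix
.rdirichlet <- function(alpha) {
  alpha <- as.matrix(alpha)
  g <- matrix(stats::rgamma(length(alpha), shape = alpha),
              nrow(alpha), ncol(alpha))
  g / rowSums(g)
}

#' Simulation configuration
#'
#' Collects the parameters of the matched-set Dirichlet-multinomial
#' simulator. Defaults are the reference study conditions: overdispersion
#' `theta1 = 0.02` between sets and `theta2 = 0.007` within sets, read depth
#' Poisson with mean 10,000 floored at 500, covariate effect sizes
#' `beta_set = 0.2` and `beta_sam = 0.5`, 50 matched sets.
#'
#' @param n_sets number of matched sets.
#' @param m controls per set (scalar, or vector of length `n_sets` for mixed
#'   1:m designs); each set has 1 case and `m` controls for a binary trait.
#' @param trait_type `"binary"` (one case, m controls per set) or
#'   `"continuous"` (i.i.d. U`[0,1]` traits).
#' @param n_otus number of OTUs.
#' @param theta1,theta2 between-set / within-set Dirichlet overdispersion,
#'   each in (0, 1).
#' @param beta trait effect size in `[0, 1]` (0 = null).
#' @param beta_set,beta_sam,beta_int effect sizes of the set-level covariate,
#'   sample-level confounder, and set x trait interaction.
#' @param set_covariate,sample_confounder,interaction logical switches for
#'   the optional effects. The confounder is drawn Bernoulli with probability
#'   `0.2 - 0.1 * trait`, so it is associated with the trait; the interaction
#'   modification applies only when both the set covariate and the trait
#'   equal 1 (and implies the set covariate).
#' @param mechanism `"S1"` (half of the OTUs, excluding the three most
#'   abundant, are causal) or `"S2"` (the ten most abundant are causal).
#' @param depth_mean,depth_floor Poisson mean read depth and lower floor.
#' @param baseline optional user-supplied composition vector (overrides the
#'   geometric default); `shape` is the geometric ratio otherwise.
#' @param seed master seed; `causal_seed` seeds the causal-set substream so
#'   the same causal OTUs can be reused across replicates and scenarios.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_sets = 50L, m = 1L,
                       trait_type = c("binary", "continuous"),
                       n_otus = 856L, theta1 = 0.02, theta2 = 0.007,
                       beta = 0, beta_set = 0.2, beta_sam = 0.5,
                       beta_int = 0.5, set_covariate = FALSE,
                       sample_confounder = FALSE, interaction = FALSE,
                       mechanism = c("S1", "S2"), depth_mean = 10000,
                       depth_floor = 500, baseline = NULL, shape = 0.985,
                       seed = 1L, causal_seed = NULL) {
  trait_type <- match.arg(trait_type)
  mechanism <- match.arg(mechanism)
  stopifnot(theta1 > 0, theta1 < 1, theta2 > 0, theta2 < 1,
            beta >= 0, beta <= 1, depth_floor <= depth_mean)
  m <- as.integer(m)
  if (length(m) == 1L) m <- rep(m, n_sets)
  if (length(m) != n_sets) stop("m must have length 1 or n_sets")
  if (!is.null(baseline)) {
    if (abs(sum(baseline) - 1) > 1e-8 || any(baseline <= 0))
      stop("baseline must be a strictly positive probability vector")
    n_otus <- length(baseline)
  }
  if (interaction) set_covariate <- TRUE
  structure(list(n_sets = as.integer(n_sets), m = m,
                 trait_type = trait_type, n_otus = as.integer(n_otus),
                 theta1 = theta1, theta2 = theta2, beta = beta,
                 beta_set = beta_set, beta_sam = beta_sam,
                 beta_int = beta_int, set_covariate = set_covariate,
                 sample_confounder = sample_confounder,
                 interaction = interaction, mechanism = mechanism,
                 depth_mean = depth_mean, depth_floor = depth_floor,
                 baseline = baseline, shape = shape,
                 seed = as.integer(seed),
                 causal_seed = if (is.null(causal_seed)) as.integer(seed)
                               else as.integer(causal_seed)),
            class = "sim_config")
}

#' Assign trait values to matched-set samples
#'
#' Binary designs get exactly one case (trait 1) and `m_i` controls (trait 0)
#' per set; continuous traits are i.i.d. U`[0, 1]`.
#'
#' @param set_sizes integer vector of samples per set.
#' @param trait_type `"binary"` or `"continuous"`.
#' @return numeric per-sample trait vector (sets in order, case first within
#'   each binary set).
#' @export
assign_traits <- function(set_sizes, trait_type = c("binary", "continuous")) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "binary")
    unlist(lapply(set_sizes, function(s) c(1, rep(0, s - 1L))))
  else stats::runif(sum(set_sizes))
}

#' Draw the causal and covariate-associated OTU sets
#'
#' Mechanism S1 samples half of the OTUs (excluding the three most abundant)
#' as trait-causal; S2 takes the ten most abundant. Causal OTUs split into
#' equal decreased (-) and increased (+) subsets, and the increased subset
#' splits equally into additive (+a) and multiplicative (+m) halves.
#' Covariate- and confounder-associated sets are uniform samples of half the
#' OTUs split into -/+; interaction OTUs are a fresh uniform sample of half
#' the OTUs under S1 and abundance ranks 1-5 and 11-15 under S2.
#'
#' @param baseline composition used for abundance ranking.
#' @param mechanism `"S1"` or `"S2"`.
#' @param seed seed of the causal substream.
#' @return object of class `"causal_sets"`: integer index vectors
#'   `trait_minus`, `trait_plus_a`, `trait_plus_m`, `set_minus`, `set_plus`,
#'   `sam_minus`, `sam_plus`, `int_minus`, `int_plus`.
#' @export
assign_causal_sets <- function(baseline, mechanism = c("S1", "S2"),
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  J <- length(baseline)
  ord <- order(baseline, decreasing = TRUE)
  half <- function(x) {
    nm <- length(x) %/% 2L
    mi <- x[seq_len(nm)]
    list(minus = mi, plus = x[-seq_len(nm)])
  }
  .run_seeded(seed, {
    if (mechanism == "S1") {
      if (J < 8L) stop("S1 requires more OTUs")
      causal <- sample(ord[-(1:3)], J %/% 2L)
    } else {
      if (J < 10L) stop("S2 requires at least 10 OTUs")
      causal <- sample(ord[1:10])    # shuffled so the -/+ split is random
    }
    tr <- half(causal)
    pl <- half(tr$plus)
    set_ <- half(sample(J, J %/% 2L))
    sam_ <- half(sample(J, J %/% 2L))
    int_ <- if (mechanism == "S1") half(sample(J, J %/% 2L))
            else half(sample(ord[c(1:5, 11:15)]))
    structure(list(trait_minus = tr$minus, trait_plus_a = pl$minus,
                   trait_plus_m = pl$plus, set_minus = set_$minus,
                   set_plus = set_$plus, sam_minus = sam_$minus,
                   sam_plus = sam_$plus, int_minus = int_$minus,
                   int_plus = int_$plus, mechanism = mechanism),
              class = "causal_sets")
  })
}

# reduce OTUs in `minus` by factor beta (multiply by 1-beta) and hand the
# removed mass to `plus` in proportion to their current frequencies
.reduce_redistribute <- function(pi, minus, plus, beta) {
  M <- beta * sum(pi[minus])
  pi[minus] <- pi[minus] * (1 - beta)
  sp <- sum(pi[plus])
  if (M > 0 && sp <= 0) stop("no receiving OTUs with positive frequency")
  if (M > 0) pi[plus] <- pi[plus] + M * pi[plus] / sp
  pi
}

#' Trait effect on a composition
#'
#' Builds the trait-modified composition: OTUs in the decreased set are
#' multiplied by `(1 - beta)`; half of the removed mass is spread evenly over
#' the additive increased set and half over the multiplicative increased set
#' in proportion to baseline frequencies. The returned composition is the
#' mixture `(1 - x) pi0 + x pi_trait`, which applies verbatim to continuous
#' traits `x` in `[0, 1]`.
#'
#' @param pi0 baseline composition (sums to 1).
#' @param beta trait effect size in `[0, 1]`.
#' @param causal a [assign_causal_sets()] object.
#' @param x trait value in `[0, 1]`.
#' @return modified composition summing to 1.
#' @export
apply_trait_effect <- function(pi0, beta, causal, x) {
  if (beta < 0 || beta > 1 || x < 0 || x > 1)
    stop("beta and x must lie in [0, 1]")
  if (beta == 0 || x == 0) return(pi0)
  M <- beta * sum(pi0[causal$trait_minus])
  pit <- pi0
  pit[causal$trait_minus] <- pit[causal$trait_minus] * (1 - beta)
  if (M > 0) {
    if (!length(causal$trait_plus_a) || !length(causal$trait_plus_m))
      stop("empty increased-OTU subset with non-zero removed mass")
    pit[causal$trait_plus_a] <- pit[causal$trait_plus_a] +
      M / (2 * length(causal$trait_plus_a))
    sm <- sum(pi0[causal$trait_plus_m])
    if (sm <= 0) stop("multiplicative subset has zero total frequency")
    pit[causal$trait_plus_m] <- pit[causal$trait_plus_m] +
      (M / 2) * pi0[causal$trait_plus_m] / sm
  }
  (1 - x) * pi0 + x * pit
}

#' Set-level covariate effect on a set mean composition
#'
#' Reduces OTUs in the covariate-decreased set by `beta_set` and
#' redistributes all removed mass to the increased set proportionally to
#' current frequencies; the result is mixed with the original by the 0/1
#' covariate.
#'
#' @param mean_i set mean composition.
#' @param x_set 0/1 set-level covariate value.
#' @param beta_set effect size (default 0.2).
#' @param causal a [assign_causal_sets()] object.
#' @return modified composition.
#' @export
apply_set_covariate <- function(mean_i, x_set, beta_set = 0.2, causal) {
  if (x_set == 0) return(mean_i)
  mod <- .reduce_redistribute(mean_i, causal$set_minus, causal$set_plus,
                              beta_set)
  (1 - x_set) * mean_i + x_set * mod
}

#' Sample-level confounder effect on a composition
#'
#' @param pi sample composition (post trait effect).
#' @param x_sam 0/1 confounder value.
#' @param beta_sam effect size (default 0.5).
#' @param causal a [assign_causal_sets()] object.
#' @return modified composition.
#' @export
apply_sample_confounder <- function(pi, x_sam, beta_sam = 0.5, causal) {
  if (x_sam == 0) return(pi)
  mod <- .reduce_redistribute(pi, causal$sam_minus, causal$sam_plus, beta_sam)
  (1 - x_sam) * pi + x_sam * mod
}

#' Set x trait interaction effect on a composition
#'
#' Applies the reduce/redistribute modification (factor `beta_int`,
#' proportional redistribution) only when both the set covariate and the
#' trait equal 1.
#'
#' @param pi sample composition.
#' @param x_set,x_trait 0/1 indicator values.
#' @param beta_int interaction effect size.
#' @param causal a [assign_causal_sets()] object.
#' @return modified composition.
#' @export
apply_interaction <- function(pi, x_set, x_trait, beta_int, causal) {
  if (x_set != 1 || x_trait != 1 || beta_int == 0) return(pi)
  .reduce_redistribute(pi, causal$int_minus, causal$int_plus, beta_int)
}

#' Multinomial read counts at Poisson depth
#'
#' Total read count `N ~ Poisson(depth_mean)`, replaced by `depth_floor`
#' when below it; counts are `Multinomial(N, pi)`.
#'
#' @param pi composition vector.
#' @param depth_mean Poisson mean (default 10,000).
#' @param depth_floor minimum depth (default 500).
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return integer count vector.
#' @export
draw_counts <- function(pi, depth_mean = 10000, depth_floor = 500,
                        seed = NULL) {
  draw <- function() {
    N <- stats::rpois(1L, depth_mean)
    if (N < depth_floor) N <- depth_floor
    as.integer(stats::rmultinom(1L, N, pi))
  }
  if (is.null(seed)) draw() else .run_seeded(seed, draw())
}

#' Simulate a matched-set microbiome dataset
#'
#' Composes the full hierarchy (see [sim_config()]) and records the truth:
#' causal sets and all intermediate compositions.
#'
#' @param config a [sim_config()].
#' @param causal optional pre-drawn [assign_causal_sets()] object (reused
#'   across replicates so that all scenarios share causal OTUs); drawn from
#'   `config$causal_seed` when `NULL`.
#' @param seed optional override of `config$seed` for the data substream.
#' @return object of class `"mset_sim"`: `counts` (samples x OTUs integer
#'   matrix), `metadata` (data.frame with `sample_id`, `set_id`, `trait` and
#'   any `x_set`, `x_sam` columns), `truth` (causal sets, baseline, and the
#'   `pi_bar`, `pi0`, `pi` composition matrices).
#' @export
simulate_dataset <- function(config, causal = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  J <- cfg$n_otus
  baseline <- cfg$baseline %||% make_baseline_composition(J, cfg$shape)
  if (is.null(causal))
    causal <- assign_causal_sets(baseline, cfg$mechanism, cfg$causal_seed)
  sizes <- 1L + cfg$m
  n <- sum(sizes)
  set_of <- rep(seq_len(cfg$n_sets), sizes)
  .run_seeded(seed %||% cfg$seed, {
    trait <- assign_traits(sizes, cfg$trait_type)
    x_set <- if (cfg$set_covariate) stats::rbinom(cfg$n_sets, 1L, 0.5) else NULL
    pibar <- .rdirichlet(matrix(dirichlet_from_mean(baseline, cfg$theta1),
                                cfg$n_sets, J, byrow = TRUE))
    if (cfg$set_covariate)
      for (i in which(x_set == 1L))
        pibar[i, ] <- apply_set_covariate(pibar[i, ], 1L, cfg$beta_set, causal)
    alpha2 <- pibar[set_of, , drop = FALSE] * (1 - cfg$theta2) / cfg$theta2
    pi0 <- .rdirichlet(alpha2)
    x_sam <- if (cfg$sample_confounder)
      stats::rbinom(n, 1L, 0.2 - 0.1 * (cfg$trait_type == "binary") * trait)
    else NULL
    pim <- pi0
    for (i in seq_len(n)) {
      p <- apply_trait_effect(pi0[i, ], cfg$beta, causal, trait[i])
      if (cfg$sample_confounder)
        p <- apply_sample_confounder(p, x_sam[i], cfg$beta_sam, causal)
      if (cfg$interaction)
        p <- apply_interaction(p, x_set[set_of[i]], trait[i], cfg$beta_int,
                               causal)
      pim[i, ] <- p
    }
    counts <- matrix(0L, n, J,
                     dimnames = list(paste0("sample", seq_len(n)),
                                     paste0("otu", seq_len(J))))
    for (i in seq_len(n))
      counts[i, ] <- draw_counts(pim[i, ], cfg$depth_mean, cfg$depth_floor)
    meta <- data.frame(sample_id = rownames(counts), set_id = set_of,
                       trait = trait)
    if (cfg$set_covariate) meta$x_set <- x_set[set_of]
    if (cfg$sample_confounder) meta$x_sam <- x_sam
    structure(list(counts = counts, metadata = meta,
                   truth = list(causal = causal, baseline = baseline,
                                pi_bar = pibar, pi0 = pi0, pi = pim),
                   config = cfg),
              class = "mset_sim")
  })
}

#' @export
print.mset_sim <- function(x, ...) {
  cat("Simulated matched-set dataset:", nrow(x$counts), "samples x",
      ncol(x$counts), "OTUs;", x$config$n_sets, "sets;",
      x$config$trait_type, "trait, beta =", x$config$beta, "\n")
  invisible(x)
}

#' Scenario presets for the simulation studies
#'
#' Seven matched-set scenarios: (1) 50 matched pairs; (2) unbalanced, 25
#' pairs + 25 1:2 sets; (3) pairs with a sample-level confounder; (4) pairs
#' with a set-level covariate; (5) unbalanced with a set-level covariate;
#' (6) pairs with a continuous trait; (7) pairs with a set x trait
#' interaction (main effects beta = 0.5 and beta_set = 0.2 always active;
#' `beta_int` is the tested effect).
#'
#' @param scenario integer 1-7.
#' @param n_otus number of OTUs.
#' @param beta trait effect size (0 for null datasets); for scenario 7 this
#'   is ignored and the trait main effect is fixed at 0.5.
#' @param beta_int interaction effect size (scenario 7 only).
#' @param seed,causal_seed passed to [sim_config()].
#' @param ... further overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
sim_scenario <- function(scenario, n_otus = 856L, beta = 0, beta_int = 0,
                         seed = 1L, causal_seed = NULL, ...) {
  base <- switch(as.character(scenario),
    "1" = list(),
    "2" = list(m = rep(1:2, each = 25L)),
    "3" = list(sample_confounder = TRUE),
    "4" = list(set_covariate = TRUE),
    "5" = list(m = rep(1:2, each = 25L), set_covariate = TRUE),
    "6" = list(trait_type = "continuous"),
    "7" = list(interaction = TRUE, beta = 0.5, beta_int = beta_int),
    stop("scenario must be 1..7"))
  args <- c(base, list(n_otus = n_otus, seed = seed,
                       causal_seed = causal_seed), list(...))
  if (scenario != 7) args$beta <- beta
  do.call(sim_config, args)
}

#' 1:m design grids
#'
#' Controls-per-set vectors for the design comparisons: with a fixed total
#' of 90 samples (`m` = 1, 2, 3, 4, 5 gives 45 pairs, 30 1:2 sets, 22 1:3
#' sets plus one pair, 18 1:4 sets, 15 1:5 sets) or with the number of sets
#' fixed at 50.
#'
#' @param type `"fixed_total_90"` or `"fixed_sets_50"`.
#' @param m controls per set, 1-5.
#' @return integer vector of controls per set, one entry per set.
#' @export
design_grid <- function(type = c("fixed_total_90", "fixed_sets_50"), m) {
  type <- match.arg(type)
  stopifnot(m %in% 1:5)
  if (type == "fixed_sets_50") return(rep(as.integer(m), 50L))
  switch(m, rep(1L, 45L), rep(2L, 30L), c(rep(3L, 22L), 1L),
         rep(4L, 18L), rep(5L, 15L))
}

#' Method-of-moments Dirichlet overdispersion estimate
#'
#' Given rows of composition draws with known (or estimated) mean vector,
#' estimates theta from `Var(p_j) = mean_j (1 - mean_j) theta` pooled over
#' components: `theta_hat = sum_j s2_j / sum_j mean_j (1 - mean_j)`.
#'
#' @param P draws x components matrix of compositions.
#' @param mean optional known mean vector (column means used otherwise).
#' @return estimate of theta.
#' @export
mom_overdispersion <- function(P, mean = NULL) {
  P <- as.matrix(P)
  m <- mean %||% colMeans(P)
  s2 <- apply(P, 2L, stats::var)
  sum(s2) / sum(m * (1 - m))
}
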