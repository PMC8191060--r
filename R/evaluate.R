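# Replicate-level evaluation harness: type I error, power, OTU-level
# sensitivity and empirical FDR for any method/strategy combination.

#' Evaluation configuration
#'
#' Pairs a simulation scenario with an analysis method and strategy.
#' Strategies: `"proposed"` (set-ID indicators + sample-level confounders in
#' the nuisance block, restricted within-set permutation),
#' `"no_set_id"` (drop the indicators), `"free_permutation"` (unrestricted
#' permutation), `"no_confounder"` (drop the sample-level confounder from
#' the nuisance block). The default problem size (200 OTUs, B = 1000
#' permutations, 1000 replicates) is a scaled-down operating point chosen so
#' a full calibration runs in minutes on one CPU; all sizes are knobs.
#'
#' @param scenario scenario number 1-7 (see [sim_scenario()]).
#' @param method `"ldm"` or `"permanova"`.
#' @param strategy analysis strategy (above).
#' @param n_replicates simulation replicates.
#' @param n_otus OTUs per replicate.
#' @param n_perm permutations per test.
#' @param alpha nominal level of the global test.
#' @param nominal_fdr nominal FDR for OTU detection.
#' @param beta trait effect size (0 for calibration); `beta_int` the
#'   interaction effect for scenario 7.
#' @param test_otus compute per-replicate sensitivity and empirical FDR
#'   (LDM only; slower).
#' @param set_sizes optional controls-per-set vector overriding the
#'   scenario's design (see [design_grid()]); the string `"independent"`
#'   selects the 50+50 independent case-control design (pairs are simulated
#'   and one sample per pair is kept, analyzed unmatched with free
#'   permutation).
#' @param distance distance for the PERMANOVA method.
#' @param min_nonzero OTU non-zero filter applied before analysis.
#' @param mechanism causal mechanism `"S1"` or `"S2"`.
#' @param theta1,theta2 overdispersion overrides.
#' @param seed master seed; per-replicate seeds and the shared causal-set
#'   substream are derived from it, so results do not depend on execution
#'   order.
#' @return an object of class `"eval_config"`.
#' @export
eval_config <- function(scenario = 1, method = c("ldm", "permanova"),
                        strategy = c("proposed", "no_set_id",
                                     "free_permutation", "no_confounder"),
                        n_replicates = 1000L, n_otus = 200L,
                        n_perm = 1000L, alpha = 0.05, nominal_fdr = 0.10,
                        beta = 0, beta_int = 0, test_otus = FALSE,
                        set_sizes = NULL, distance = "bray",
                        min_nonzero = 5L, mechanism = "S1",
                        theta1 = 0.02, theta2 = 0.007, seed = 1L) {
  structure(list(scenario = scenario, method = match.arg(method),
                 strategy = match.arg(strategy),
                 n_replicates = as.integer(n_replicates),
                 n_otus = as.integer(n_otus), n_perm = as.integer(n_perm),
                 alpha = alpha, nominal_fdr = nominal_fdr, beta = beta,
                 beta_int = beta_int, test_otus = isTRUE(test_otus),
                 set_sizes = set_sizes, distance = distance,
                 min_nonzero = as.integer(min_nonzero),
                 mechanism = mechanism, theta1 = theta1, theta2 = theta2,
                 seed = as.integer(seed)),
            class = "eval_config")
}

# analyze one simulated dataset under a method/strategy; returns the global
# p-value plus optional sensitivity/FDP against the truth
.analyze_replicate <- function(sim, cfg, rep_seed, independent = FALSE) {
  counts <- sim$counts
  meta <- sim$metadata
  if (cfg$min_nonzero > 0L) counts <- filter_otus(counts, cfg$min_nonzero)
  adjust_id <- !(cfg$strategy == "no_set_id") && !independent
  permute <- if (cfg$strategy == "free_permutation" || independent)
    "free" else "within_set"
  conf <- NULL
  if (cfg$scenario == 3 && cfg$strategy != "no_confounder" &&
      "x_sam" %in% names(meta)) conf <- "x_sam"
  trait <- if (cfg$scenario == 7) c("trait", "trait:x_set") else "trait"
  tested <- if (cfg$scenario == 7) "trait:x_set" else "trait"
  if (cfg$method == "permanova") {
    fit <- permanova_test(counts, meta, trait = trait,
                          confounders = conf, distance = cfg$distance,
                          adjust_set_id = adjust_id, permute = permute,
                          n_perm = cfg$n_perm, seed = rep_seed)
    return(list(p = unname(fit$p.value[tested])))
  }
  fit <- ldm_test(counts, meta, trait = trait, confounders = conf,
                  adjust_set_id = adjust_id, permute = permute,
                  n_perm = cfg$n_perm, seed = rep_seed,
                  nominal_fdr = cfg$nominal_fdr,
                  test_otus = cfg$test_otus)
  out <- list(p = unname(fit$omnibus_p[tested]))
  if (cfg$test_otus) {
    truth <- sim$truth$causal
    causal_ids <- paste0("otu", c(truth$trait_minus, truth$trait_plus_a,
                                  truth$trait_plus_m))
    df <- fit$otu[[tested]]
    det <- df$otu[df$detected]
    tp <- sum(det %in% causal_ids)
    out$sensitivity <- tp / length(causal_ids)
    out$fdp <- if (length(det)) (length(det) - tp) / length(det) else 0
  }
  out
}

.run_replicates <- function(cfg) {
  seeds <- .run_seeded(cfg$seed, {
    list(reps = sample.int(.Machine$integer.max - 1L, cfg$n_replicates),
         causal = sample.int(.Machine$integer.max - 1L, 1L))
  })
  independent <- identical(cfg$set_sizes, "independent")
  m <- if (independent) rep(1L, 100L)
       else if (!is.null(cfg$set_sizes)) cfg$set_sizes
       else NULL
  scfg <- sim_scenario(cfg$scenario, n_otus = cfg$n_otus, beta = cfg$beta,
                       beta_int = cfg$beta_int, causal_seed = seeds$causal,
                       theta1 = cfg$theta1, theta2 = cfg$theta2)
  if (!is.null(m)) {
    scfg$m <- m
    scfg$n_sets <- length(m)
  }
  baseline <- make_baseline_composition(cfg$n_otus, scfg$shape)
  causal <- assign_causal_sets(baseline, scfg$mechanism, seeds$causal)
  p <- sens <- fdp <- rep(NA_real_, cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    sim <- simulate_dataset(scfg, causal = causal, seed = seeds$reps[r])
    if (independent) {
      # keep the case from the first 50 pairs, the control from the rest,
      # and analyze as 100 unmatched samples
      keep <- ifelse(sim$metadata$set_id <= 50L,
                     sim$metadata$trait == 1, sim$metadata$trait == 0)
      sim$counts <- sim$counts[keep, , drop = FALSE]
      sim$metadata <- sim$metadata[keep, , drop = FALSE]
      sim$metadata$set_id <- seq_len(nrow(sim$metadata))
    }
    res <- .analyze_replicate(sim, cfg, seeds$reps[r],
                              independent = independent)
    p[r] <- res$p
    if (!is.null(res$sensitivity)) { sens[r] <- res$sensitivity; fdp[r] <- res$fdp }
  }
  rate <- mean(p <= cfg$alpha)
  structure(list(rejection_rate = rate,
                 se = sqrt(rate * (1 - rate) / cfg$n_replicates),
                 sensitivity = if (cfg$test_otus) mean(sens) else NA_real_,
                 empirical_fdr = if (cfg$test_otus) mean(fdp) else NA_real_,
                 p.values = p, per_replicate = data.frame(
                   p = p, sensitivity = sens, fdp = fdp),
                 config = cfg),
            class = "eval_result")
}

#' Type I error of the global test
#'
#' Runs `n_replicates` null datasets (`beta = 0`; for scenario 7,
#' `beta_int = 0` with main effects active) and reports the fraction of
#' replicates with global p <= alpha, with its binomial standard error.
#'
#' @param cfg an [eval_config()] with a null effect size.
#' @return an `"eval_result"`.
#' @export
run_calibration <- function(cfg) {
  stopifnot(inherits(cfg, "eval_config"))
  if (cfg$scenario == 7) {
    if (cfg$beta_int != 0) stop("calibration for scenario 7 needs beta_int = 0")
  } else if (cfg$beta != 0) stop("calibration needs beta = 0")
  .run_replicates(cfg)
}

#' Power (and OTU-level sensitivity/FDR) of the test
#'
#' As [run_calibration()] but with a non-null effect; with `test_otus =
#' TRUE` (LDM) also reports mean sensitivity over truly causal OTUs and mean
#' empirical FDR (false-discovery proportion, 0/0 counted as 0) at the
#' nominal FDR.
#'
#' @param cfg an [eval_config()].
#' @return an `"eval_result"`.
#' @export
run_power <- function(cfg) {
  stopifnot(inherits(cfg, "eval_config"))
  .run_replicates(cfg)
}

#' Compare matched-set designs
#'
#' Runs [run_power()] for each design in `designs` (controls-per-set
#' vectors, or `"independent"`), sharing the causal-OTU substream across
#' designs via the common master seed.
#'
#' @param cfg base [eval_config()].
#' @param designs named list of designs.
#' @return named list of `"eval_result"` objects.
#' @export
compare_designs <- function(cfg, designs) {
  stopifnot(inherits(cfg, "eval_config"))
  out <- lapply(designs, function(d) {
    ci <- cfg
    ci$set_sizes <- d
    .run_replicates(ci)
  })
  names(out) <- names(designs)
  out
}

#' @export
print.eval_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Scenario %s | %s | %s: rejection rate %.4f (SE %.4f) over %d replicates\n",
    cfg$scenario, cfg$method, cfg$strategy, x$rejection_rate, x$se,
    cfg$n_replicates))
  if (!is.na(x$sensitivity))
    cat(sprintf("  mean sensitivity %.3f, empirical FDR %.3f (nominal %.2f)\n",
                x$sensitivity, x$empirical_fdr, cfg$nominal_fdr))
  invisible(x)
}
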