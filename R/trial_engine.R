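#' Deterministic seed derivation
#'
#' Mixes a master seed with stream identifiers into a 31-bit seed via a
#' multiplicative-congruential hash, so that each (trial, stream) pair gets
#' its own reproducible RNG stream. In particular the patient stream
#' (covariates and outcome uniforms) depends only on the trial seed, not on
#' the design, so competing designs are compared on common patient data.
#'
#' @param ... Integer components (master seed first, then stream ids).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
mix_seed <- function(...) {
  ids <- c(...)
  x <- 0
  for (v in ids) {
    x <- (x * 69069 + (as.double(v) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(x %% 2147483646 + 1)
}

.designs <- c("TRAD", "RAR", "CARA1", "CARA2", "BACARA")

#' Trial configuration
#'
#' @param scenario Scenario object (see [scenario_table()]) or a scenario id.
#' @param design One of `"TRAD"`, `"RAR"`, `"CARA1"`, `"CARA2"`, `"BACARA"`
#'   (case-insensitive).
#' @param cohort_sizes Cohort sizes `n_1..n_K`; analyses occur after each
#'   cohort, the last being the final analysis.
#' @param monitoring A [monitoring_config()].
#' @param mcmc List with `iterations` and `burn_in` for posterior sampling.
#' @param seed Integer master seed for the trial.
#' @return List of class `trial_config`.
#' @export
trial_config <- function(scenario, design = "BACARA",
                         cohort_sizes = c(70, 70, 70),
                         monitoring = monitoring_config(),
                         mcmc = list(iterations = 10000, burn_in = 5000),
                         seed = 1L) {
  if (is.numeric(scenario) && length(scenario) == 1) {
    scenario <- get_scenario(scenario)
  }
  design <- toupper(design)
  stopifnot(design %in% .designs, length(cohort_sizes) >= 2,
            all(cohort_sizes >= 1),
            inherits(monitoring, "monitoring_config"))
  structure(list(scenario = scenario, design = design,
                 cohort_sizes = as.integer(cohort_sizes),
                 monitoring = monitoring, mcmc = mcmc,
                 seed = as.integer(seed)),
            class = "trial_config")
}

# Map each patient profile to its subgroup row index.
.profile_index <- function(profiles, subgroups) {
  keys <- apply(subgroups, 1, paste, collapse = "")
  match(apply(profiles, 1, paste, collapse = ""), keys)
}

#' Randomize one cohort
#'
#' Assigns each patient to the experimental arm A by an independent Bernoulli
#' draw with that patient's allocation probability (no blocking or urn
#' balancing), using the current RNG state.
#'
#' @param prob_A Per-patient allocation probability to A (scalar or vector).
#' @param n Cohort size (defaults to `length(prob_A)`).
#' @return Integer vector of arm indicators (1 = A, 0 = B).
#' @export
randomize_cohort <- function(prob_A, n = length(prob_A)) {
  prob_A <- rep_len(prob_A, n)
  stopifnot(all(prob_A >= 0), all(prob_A <= 1))
  as.integer(stats::runif(n) < prob_A)
}

#' Run one adaptive group sequential trial
#'
#' Executes a complete trial under the configured design: cohort 1 is
#' randomized 1:1 for every design; after each cohort's outcomes are in, the
#' stage analysis runs (the Bayesian subgroup-averaged test for BaCARA, the
#' O'Brien-Fleming two-proportion test for the comparators). If the trial
#' continues, the design's allocation rule is refreshed from all accumulated
#' data and applied patient-by-patient to the next cohort. BaCARA performs a
#' single posterior fit per stage, reused for monitoring and allocation.
#'
#' @param config A [trial_config()].
#' @return Object of class `trial_result`: verdict, stopping stage,
#'   `rejected` flag, enrollment and per-arm counts, total failures,
#'   per-(subgroup, arm) allocation counts, the allocation probabilities
#'   applied per cohort, the per-stage decisions, accumulated records, and a
#'   count of degenerate (fallback) fits.
#' @export
run_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  scen <- config$scenario
  params <- scen$params
  dist <- scen$covariate_dist
  d <- length(dist)
  K <- length(config$cohort_sizes)
  N <- sum(config$cohort_sizes)
  design <- config$design
  mon <- config$monitoring
  subgroups <- subgroup_profiles(d)
  nsub <- nrow(subgroups)

  # independent streams: patients (design-invariant), assignments, MCMC
  seed_patients <- mix_seed(config$seed, 104729)
  seed_assign <- mix_seed(config$seed, 224737)
  seed_mcmc <- mix_seed(config$seed, 350377)

  set.seed(seed_patients)
  all_profiles <- generate_patients(N, dist)
  all_u <- stats::runif(N)

  if (design != "BACARA") {
    info <- cumsum(config$cohort_sizes) / N
    # two-sided chi-square test at overall level alpha: one-sided spending
    # at alpha / 2 per tail
    bounds <- obf_boundaries(mon$alpha / 2, info)
  }

  records <- NULL
  cohort_weights <- vector("list", K)
  alloc_prob_trace <- matrix(NA_real_, nrow = K, ncol = nsub,
                             dimnames = list(NULL,
                               apply(subgroups, 1, paste, collapse = "")))
  decisions <- vector("list", K)
  sub_prob <- rep(0.5, nsub)       # per-subgroup allocation prob, stage >= 2
  n_degenerate <- 0L
  verdict <- NA_character_
  stop_stage <- K

  offset <- 0L
  for (k in seq_len(K)) {
    nk <- config$cohort_sizes[k]
    idx <- offset + seq_len(nk)
    offset <- offset + nk
    profiles <- all_profiles[idx, , drop = FALSE]
    sub_idx <- .profile_index(profiles, subgroups)

    p_alloc <- if (k == 1) rep(prob_trad(), nk) else sub_prob[sub_idx]
    alloc_prob_trace[k, ] <- if (k == 1) rep(0.5, nsub) else sub_prob
    set.seed(mix_seed(seed_assign, k))
    arm <- randomize_cohort(p_alloc)
    y <- generate_outcomes(params, arm, profiles, u = all_u[idx])

    cohort <- data.frame(profiles, arm = arm, y = y, cohort = k)
    records <- rbind(records, cohort)
    cohort_weights[[k]] <- tabulate(sub_idx, nbins = nsub) / nk

    final <- (k == K)
    if (design == "BACARA") {
      mle <- fit_probit_mle(records)
      if (mle$degenerate) n_degenerate <- n_degenerate + 1L
      post <- sample_posterior(records, prior_spec(mle),
                               iterations = config$mcmc$iterations,
                               burn_in = config$mcmc$burn_in,
                               seed = mix_seed(seed_mcmc, k))
      tk <- test_statistic_draws(post, config$cohort_sizes[seq_len(k)],
                                 cohort_weights[seq_len(k)], subgroups)
      dec <- bayes_decision(tk, mon, k, K)
    } else {
      dec <- comparator_test(records, bounds[k], final = final)
    }
    decisions[[k]] <- dec
    if (dec$verdict != "CONTINUE") {
      verdict <- dec$verdict
      stop_stage <- k
      break
    }

    # refresh the allocation rule for the next cohort
    if (k < K) {
      if (design == "RAR") {
        qa <- mean(records$y[records$arm == 1] == 0)
        qb <- mean(records$y[records$arm == 0] == 0)
        if (is.nan(qa)) qa <- 0.5
        if (is.nan(qb)) qb <- 0.5
        sub_prob <- rep(prob_rar(qa, qb), nsub)
      } else if (design == "CARA1" || design == "CARA2") {
        mle <- fit_probit_mle(records)
        if (mle$degenerate) n_degenerate <- n_degenerate + 1L
        post <- sample_posterior(records, prior_spec(mle),
                                 iterations = config$mcmc$iterations,
                                 burn_in = config$mcmc$burn_in,
                                 seed = mix_seed(seed_mcmc, k))
      }
      if (design == "CARA1" || design == "BACARA") {
        sub_prob <- vapply(seq_len(nsub), function(i) {
          prob_cara1(posterior_prob_benefit(post, subgroups[i, ]))
        }, numeric(1))
      } else if (design == "CARA2") {
        sub_prob <- vapply(seq_len(nsub), function(i) {
          r <- posterior_mean_rates(post, subgroups[i, ])
          prob_cara2(r["pA"], r["pB"])
        }, numeric(1))
      }
      # TRAD keeps 0.5
    }
  }

  n_enrolled <- nrow(records)
  sub_idx_all <- .profile_index(
    as.matrix(records[, paste0("x", seq_len(d)), drop = FALSE]), subgroups)
  subgroup_alloc <- matrix(0L, nrow = nsub, ncol = 2,
                           dimnames = list(
                             apply(subgroups, 1, paste, collapse = ""),
                             c("A", "B")))
  for (i in seq_len(n_enrolled)) {
    col <- if (records$arm[i] == 1) 1L else 2L
    subgroup_alloc[sub_idx_all[i], col] <-
      subgroup_alloc[sub_idx_all[i], col] + 1L
  }

  structure(list(
    verdict = verdict,
    rejected = verdict %in% c("STOP_SUPERIOR", "FINAL_SUPERIOR"),
    stop_stage = stop_stage,
    n_enrolled = n_enrolled,
    nA = sum(records$arm == 1),
    nB = sum(records$arm == 0),
    failures = sum(records$y),
    subgroup_alloc = subgroup_alloc,
    alloc_prob_trace = alloc_prob_trace[seq_len(stop_stage), , drop = FALSE],
    decisions = decisions[seq_len(stop_stage)],
    records = records,
    n_degenerate_fits = n_degenerate,
    design = design,
    scenario_id = scen$id,
    seed = config$seed
  ), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("%s trial (scenario %s): %s at stage %d\n", x$design,
              ifelse(is.null(x$scenario_id), "?", x$scenario_id),
              x$verdict, x$stop_stage))
  cat(sprintf("  enrolled %d (A: %d, B: %d), failures %d\n",
              x$n_enrolled, x$nA, x$nB, x$failures))
  invisible(x)
}
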