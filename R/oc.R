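#' Operating characteristics over replicated trials
#'
#' Runs `n_reps` independent trials of one (scenario, design) pair and
#' aggregates: rejection probability, mean difference in per-arm sample
#' sizes, mean number of failures, per-(subgroup, arm) allocation fractions
#' (per-trial subgroup share within each arm, `count(s, g) / n_g`, then mean
#' and SD across trials), and
#' early-stopping fractions by stage. Per-replicate seeds are derived from
#' the master seed, so results are reproducible and independent of execution
#' order, and the patient streams are shared across designs run with the
#' same master seed.
#'
#' @param scenario Scenario object or id.
#' @param design Design name (see [trial_config()]).
#' @param n_reps Number of replicated trials.
#' @param seed Master seed.
#' @param cohort_sizes,monitoring,mcmc Passed to [trial_config()].
#' @return Object of class `oc_summary` with the aggregate fields and a
#'   per-trial data frame `trials`.
#' @export
operating_characteristics <- function(scenario, design, n_reps = 1000,
                                      seed = 1L,
                                      cohort_sizes = c(70, 70, 70),
                                      monitoring = monitoring_config(),
                                      mcmc = list(iterations = 10000,
                                                  burn_in = 5000)) {
  stopifnot(n_reps >= 1)
  if (is.numeric(scenario) && length(scenario) == 1) {
    scenario <- get_scenario(scenario)
  }
  d <- length(scenario$covariate_dist)
  subgroups <- subgroup_profiles(d)
  nsub <- nrow(subgroups)
  sub_names <- apply(subgroups, 1, paste, collapse = "")
  K <- length(cohort_sizes)

  frac_A <- matrix(NA_real_, n_reps, nsub)
  frac_B <- matrix(NA_real_, n_reps, nsub)
  trials <- data.frame(rep = seq_len(n_reps), rejected = NA,
                       stop_stage = NA_integer_, n_enrolled = NA_integer_,
                       nA = NA_integer_, nB = NA_integer_,
                       failures = NA_integer_, verdict = NA_character_,
                       seed = NA_integer_)
  for (r in seq_len(n_reps)) {
    trial_seed <- mix_seed(seed, r)
    res <- run_trial(trial_config(scenario, design,
                                  cohort_sizes = cohort_sizes,
                                  monitoring = monitoring, mcmc = mcmc,
                                  seed = trial_seed))
    trials$rejected[r] <- res$rejected
    trials$stop_stage[r] <- res$stop_stage
    trials$n_enrolled[r] <- res$n_enrolled
    trials$nA[r] <- res$nA
    trials$nB[r] <- res$nB
    trials$failures[r] <- res$failures
    trials$verdict[r] <- res$verdict
    trials$seed[r] <- trial_seed
    frac_A[r, ] <- res$subgroup_alloc[, "A"] / max(res$nA, 1)
    frac_B[r, ] <- res$subgroup_alloc[, "B"] / max(res$nB, 1)
  }
  alloc <- data.frame(
    subgroup = rep(sub_names, 2),
    arm = rep(c("A", "B"), each = nsub),
    mean = c(colMeans(frac_A), colMeans(frac_B)),
    sd = c(apply(frac_A, 2, stats::sd), apply(frac_B, 2, stats::sd))
  )
  stop_frac <- vapply(seq_len(K), function(k) mean(trials$stop_stage == k),
                      numeric(1))
  structure(list(
    scenario_id = scenario$id,
    design = toupper(design),
    n_reps = n_reps,
    seed = seed,
    rejection_prob = mean(trials$rejected),
    mean_alloc_diff = mean(trials$nA - trials$nB),
    mean_failures = mean(trials$failures),
    subgroup_alloc = alloc,
    stop_fractions = stop_frac,
    trials = trials
  ), class = "oc_summary")
}

#' @export
print.oc_summary <- function(x, ...) {
  cat(sprintf("Operating characteristics: scenario %s, %s, %d trials\n",
              ifelse(is.null(x$scenario_id), "?", x$scenario_id), x$design,
              x$n_reps))
  cat(sprintf("  rejection probability: %.3f\n", x$rejection_prob))
  cat(sprintf("  mean nA - nB: %.3f\n", x$mean_alloc_diff))
  cat(sprintf("  mean failures: %.2f\n", x$mean_failures))
  invisible(x)
}

#' Calibrate the Bayesian monitoring cutoffs
#'
#' Simulation-based calibration of `(eps1, eps2, eps3)`: starting from
#' `eps1 = eps3 = 1 - alpha` and `eps2 = 1 - beta`, the cutoffs are adjusted
#' coordinate-wise -- superiority cutoffs up when the worst null-scenario
#' type I error exceeds the target (and down when below it), the futility
#' cutoff up when power falls short (and down when above target) -- with a
#' halving step schedule, until both error rates sit inside their tolerance
#' bands or the iteration budget is spent. Common random numbers (a fixed
#' seed schedule) make the search deterministic.
#'
#' @param eval_fn Function taking `(eps1, eps2, eps3)` and returning
#'   `list(type1 = max type I error over the null scenarios, power = power
#'   on the reference alternative)`. If `NULL`, one is built from
#'   [operating_characteristics()] over `null_scenarios` and `alt_scenario`.
#' @param null_scenarios,alt_scenario Scenario ids used by the default
#'   `eval_fn`.
#' @param alpha,beta Target type I and type II error rates.
#' @param n_reps Replicates per evaluation (default eval only).
#' @param seed Master seed for the common-random-number schedule.
#' @param step_init Initial adjustment step.
#' @param tol_alpha,tol_power Tolerance bands around the targets.
#' @param max_iter Iteration cap; on exhaustion the best cutoffs found are
#'   returned with `converged = FALSE`.
#' @param mcmc MCMC settings for the default eval.
#' @return Object of class `calibration_result`: the cutoffs, achieved
#'   rates, `converged` flag and the full iteration `trace`.
#' @export
calibrate_cutoffs <- function(eval_fn = NULL, null_scenarios = 1:9,
                              alt_scenario = 10, alpha = 0.05, beta = 0.2,
                              n_reps = 500, seed = 1L, step_init = 0.01,
                              tol_alpha = 0.01, tol_power = 0.02,
                              max_iter = 20,
                              mcmc = list(iterations = 2000,
                                          burn_in = 1000)) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1)
  if (is.null(eval_fn)) {
    eval_fn <- function(eps1, eps2, eps3) {
      mon <- monitoring_config(eps1 = eps1, eps2 = eps2, eps3 = eps3,
                               alpha = alpha)
      t1 <- max(vapply(null_scenarios, function(s) {
        operating_characteristics(s, "BACARA", n_reps = n_reps,
                                  seed = mix_seed(seed, s),
                                  monitoring = mon,
                                  mcmc = mcmc)$rejection_prob
      }, numeric(1)))
      pw <- operating_characteristics(alt_scenario, "BACARA",
                                      n_reps = n_reps,
                                      seed = mix_seed(seed, 1000 + alt_scenario),
                                      monitoring = mon,
                                      mcmc = mcmc)$rejection_prob
      list(type1 = t1, power = pw)
    }
  }
  clamp <- function(x) min(max(x, 0.5), 1 - 1e-4)
  eps1 <- clamp(1 - alpha)
  eps3 <- clamp(1 - alpha)
  eps2 <- clamp(1 - beta)
  step1 <- step_init
  step2 <- step_init
  dir1_prev <- 0
  dir2_prev <- 0
  trace <- NULL
  best <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    rates <- eval_fn(eps1, eps2, eps3)
    row <- data.frame(iter = it, eps1 = eps1, eps2 = eps2, eps3 = eps3,
                      type1 = rates$type1, power = rates$power)
    trace <- rbind(trace, row)
    ok1 <- rates$type1 <= alpha + tol_alpha
    ok2 <- rates$power >= 1 - beta - tol_power
    score <- max(0, rates$type1 - (alpha + tol_alpha)) +
      max(0, (1 - beta - tol_power) - rates$power)
    if (is.null(best) || score < best$score) {
      best <- list(eps1 = eps1, eps2 = eps2, eps3 = eps3, score = score,
                   type1 = rates$type1, power = rates$power)
    }
    if (ok1 && ok2) {
      converged <- TRUE
      best <- list(eps1 = eps1, eps2 = eps2, eps3 = eps3, score = 0,
                   type1 = rates$type1, power = rates$power)
      break
    }
    # type I too high -> raise superiority cutoffs; too low -> lower them
    dir1 <- if (rates$type1 > alpha + tol_alpha) 1
            else if (rates$type1 < alpha - tol_alpha) -1 else 0
    # power too low -> raise futility cutoff; too high -> lower it
    dir2 <- if (rates$power < 1 - beta - tol_power) 1
            else if (rates$power > 1 - beta + tol_power) -1 else 0
    if (dir1 != 0 && dir1_prev != 0 && dir1 != dir1_prev) step1 <- step1 / 2
    if (dir2 != 0 && dir2_prev != 0 && dir2 != dir2_prev) step2 <- step2 / 2
    eps1 <- clamp(eps1 + dir1 * step1)
    eps3 <- clamp(eps3 + dir1 * step1)
    eps2 <- clamp(eps2 + dir2 * step2)
    dir1_prev <- dir1
    dir2_prev <- dir2
  }
  structure(list(eps1 = best$eps1, eps2 = best$eps2, eps3 = best$eps3,
                 type1 = best$type1, power = best$power,
                 converged = converged, trace = trace),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibrated cutoffs: eps1 = %.3f, eps2 = %.3f, eps3 = %.3f\n",
              x$eps1, x$eps2, x$eps3))
  cat(sprintf("  achieved type I %.3f, power %.3f (%s)\n", x$type1, x$power,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Arrange operating-characteristic summaries into report tables
#'
#' Produces the three standard report shapes: rejection probabilities
#' (scenario by design), per-(subgroup, arm) allocation fraction mean/SD
#' (long format), and the remaining operating characteristics (mean
#' `nA - nB` and mean failures).
#'
#' @param summaries List of `oc_summary` objects.
#' @return List with data frames `rejection`, `allocation` and `ops`.
#' @export
summarize_to_tables <- function(summaries) {
  if (length(summaries) == 0) {
    return(list(
      rejection = data.frame(scenario = integer(), design = character(),
                             rejection_prob = numeric()),
      allocation = data.frame(scenario = integer(), design = character(),
                              subgroup = character(), arm = character(),
                              mean = numeric(), sd = numeric()),
      ops = data.frame(scenario = integer(), design = character(),
                       mean_alloc_diff = numeric(),
                       mean_failures = numeric())
    ))
  }
  rejection <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(scenario = s$scenario_id, design = s$design,
               rejection_prob = s$rejection_prob)
  }))
  allocation <- do.call(rbind, lapply(summaries, function(s) {
    cbind(data.frame(scenario = s$scenario_id, design = s$design),
          s$subgroup_alloc)
  }))
  ops <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(scenario = s$scenario_id, design = s$design,
               mean_alloc_diff = s$mean_alloc_diff,
               mean_failures = s$mean_failures)
  }))
  rownames(rejection) <- rownames(allocation) <- rownames(ops) <- NULL
  list(rejection = rejection, allocation = allocation, ops = ops)
}

#' Write report tables to delimited files
#'
#' @param tables Result of [summarize_to_tables()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_oc_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("rejection.csv", "allocation.csv", "ops.csv"))
  utils::write.csv(tables$rejection, paths[1], row.names = FALSE)
  utils::write.csv(tables$allocation, paths[2], row.names = FALSE)
  utils::write.csv(tables$ops, paths[3], row.names = FALSE)
  invisible(paths)
}
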