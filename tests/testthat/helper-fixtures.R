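# Shared fixtures: simulated datasets and hand-built posterior objects.

# Simulated records from a scenario with 1:1 randomization.
simulate_records <- function(scenario_id, n, seed) {
  scen <- get_scenario(scenario_id)
  set.seed(seed)
  profiles <- generate_patients(n, scen$covariate_dist)
  arm <- stats::rbinom(n, 1, 0.5)
  y <- generate_outcomes(scen$params, arm, profiles)
  data.frame(profiles, arm = arm, y = y, cohort = 1L)
}

# A posterior_draws object with prescribed draws (one theta per row).
fake_posterior <- function(draws, d = (ncol(draws) / 2) - 1) {
  colnames(draws) <- c(paste0("beta", 0:d), paste0("gamma", 0:d))
  structure(list(draws = draws, d = d, iterations = nrow(draws),
                 burn_in = 0, seed = NULL),
            class = "posterior_draws")
}

reduced_mcmc <- list(iterations = 2000, burn_in = 1000)

# Posterior mean by brute-force quadrature on a coarse grid (d = 1 only:
# four coefficients). Independent oracle for the Gibbs sampler.
grid_posterior_mean <- function(rec, prior, half_width = 3, step = 0.3) {
  X <- probit_design(matrix(rec$x1, ncol = 1), rec$arm)
  pts <- lapply(prior$mean,
                function(m) seq(m - half_width, m + half_width, by = step))
  grid <- as.matrix(expand.grid(pts))
  pm <- pnorm(grid %*% t(X))
  pm <- pmin(pmax(pm, 1e-12), 1 - 1e-12)
  ll <- drop(log(pm) %*% rec$y + log(1 - pm) %*% (1 - rec$y))
  lprior <- -0.5 * colSums((t(grid) - prior$mean)^2 / prior$variance_diag)
  w <- exp(ll + lprior - max(ll + lprior))
  drop(crossprod(grid, w)) / sum(w)
}

# Fixed 20-observation, single-covariate dataset for sampler-vs-grid checks.
# The seed is chosen so the MLE is interior (no quasi-separation): the
# posterior is then compact and a coarse quadrature grid covers it.
tiny_probit_dataset <- function() {
  set.seed(4)
  profiles <- matrix(rbinom(20, 1, 0.5), ncol = 1,
                     dimnames = list(NULL, "x1"))
  arm <- rbinom(20, 1, 0.5)
  params <- list(beta = c(-0.3, 0.4), gamma = c(-0.4, 0.2))
  y <- generate_outcomes(params, arm, profiles)
  data.frame(x1 = profiles[, 1], arm = arm, y = y, cohort = 1L)
}
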