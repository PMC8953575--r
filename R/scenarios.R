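#' Subgroup covariate profiles
#'
#' Enumerates all `2^d` binary covariate profiles defining the patient
#' subgroups. For `d = 2` the rows are ordered `(1,1), (1,0), (0,1), (0,0)`,
#' the convention used throughout the package's subgroup-level outputs.
#'
#' @param d Number of binary covariates.
#' @return Integer matrix with `2^d` rows and `d` columns.
#' @export
subgroup_profiles <- function(d = 2) {
  stopifnot(d >= 1)
  g <- expand.grid(rep(list(c(1L, 0L)), d))
  m <- as.matrix(g)[, d:1, drop = FALSE]
  dimnames(m) <- list(NULL, paste0("x", seq_len(d)))
  m
}

#' Probit response probability
#'
#' Event probability under the probit regression model
#' `Pr(Y = 1 | G, x) = pnorm(xt' beta + G * xt' gamma)` with
#' `xt = (1, x)` the intercept-augmented covariate vector. `beta` holds the
#' intercept and covariate main (prognostic) effects; `gamma` holds the
#' treatment main effect and treatment-covariate interaction (predictive)
#' effects.
#'
#' @param params List with numeric vectors `beta` and `gamma`, each of
#'   length `d + 1`.
#' @param arm Treatment indicator: 1 for the experimental arm A, 0 for the
#'   control arm B.
#' @param profile Binary covariate vector of length `d`, or a matrix with one
#'   profile per row.
#' @return Event probability (vector if `profile` is a matrix).
#' @export
response_probability <- function(params, arm, profile) {
  stopifnot(is.list(params), length(params$beta) == length(params$gamma),
            all(is.finite(params$beta)), all(is.finite(params$gamma)),
            arm %in% c(0, 1))
  if (!is.matrix(profile)) profile <- matrix(profile, nrow = 1)
  if (ncol(profile) != length(params$beta) - 1L)
    stop("profile length must equal length(beta) - 1")
  xt <- cbind(1, profile)
  lp <- drop(xt %*% params$beta) + arm * drop(xt %*% params$gamma)
  stats::pnorm(lp)
}

# Parameter rows of the twenty shipped simulation scenarios (d = 2).
.scenario_params <- function() {
  m <- matrix(c(
     0,     0,    0,     0,     0,    0,
    -0.5,   0.5,  0,     0,     0,    0,
    -0.5,   1,    0,     0,     0,    0,
    -1,     0,    0.5,   0,     0,    0,
    -1,     0,    2,     0,     0,    0,
    -0.5,   0.5,  0.5,   0,     0,    0,
    -0.5,   1,    1,     0,     0,    0,
    -0.5,  -0.5,  0.5,   0,     0,    0,
    -0.5,  -1,    1,     0,     0,    0,
     0,     0,    0,    -0.5,   0,    0,
    -0.5,   0.5,  0,    -0.5,   0,    0,
    -0.5,  -0.2,  0,    -0.5,   0,    0,
    -0.5,   0,    0,    -0.5,  -0.5,  0,
    -0.5,   0,    0,    -0.5,   0.5,  0,
    -0.5,   0.5,  0,    -0.5,  -0.5,  0,
    -1,     0,    0.5,  -0.5,   0,    0,
    -1,     0,    2,    -0.5,   0,    0,
    -1,     0,    2,    -0.5,   0,    0.5,
     0.5,   0.5, -0.5,  -0.5,   0.5, -0.5,
     0.5,   0.5, -0.5,  -0.65,  0.5,  0.5
  ), nrow = 20, byrow = TRUE)
  colnames(m) <- c("beta0", "beta1", "beta2", "gamma0", "gamma1", "gamma2")
  m
}

#' The twenty shipped simulation scenarios
#'
#' Returns the list of data-generating scenarios used in the package's
#' simulation study: two independent Bernoulli(0.5) covariates and probit
#' coefficients `(beta, gamma)` per scenario. Scenarios 1-9 are null
#' (`gamma = 0`, no treatment effect anywhere); scenarios 10-20 carry a
#' treatment effect, in several cases modified by predictive covariates.
#'
#' @return List of 20 scenario objects, each a list with elements `id`,
#'   `params` (list `beta`, `gamma`) and `covariate_dist` (per-covariate
#'   Bernoulli success probabilities).
#' @seealso [get_scenario()], [true_effect_table()]
#' @export
scenario_table <- function() {
  m <- .scenario_params()
  lapply(seq_len(nrow(m)), function(i) {
    list(id = i,
         params = list(beta = unname(m[i, 1:3]), gamma = unname(m[i, 4:6])),
         covariate_dist = c(0.5, 0.5))
  })
}

#' Fetch a single scenario by id
#'
#' @param id Scenario id, 1-20.
#' @return A scenario object (see [scenario_table()]).
#' @export
get_scenario <- function(id) {
  stopifnot(length(id) == 1, id %in% 1:20)
  scenario_table()[[id]]
}

#' Generate patient covariate profiles
#'
#' Draws each binary covariate independently from its Bernoulli success
#' probability, using the current RNG state.
#'
#' @param n Number of patients.
#' @param covariate_dist Vector of per-covariate Bernoulli probabilities.
#' @return Integer matrix with `n` rows and `length(covariate_dist)` columns.
#' @export
generate_patients <- function(n, covariate_dist = c(0.5, 0.5)) {
  stopifnot(n >= 1, all(covariate_dist >= 0), all(covariate_dist <= 1))
  d <- length(covariate_dist)
  m <- matrix(0L, nrow = n, ncol = d, dimnames = list(NULL, paste0("x", 1:d)))
  for (j in seq_len(d)) m[, j] <- stats::rbinom(n, 1L, covariate_dist[j])
  m
}

#' Generate binary outcomes from the probit model
#'
#' Draws `Y ~ Bernoulli(p)` with `p` from [response_probability()]. `Y = 1` is
#' an event (failure). If `u` is supplied, outcomes are thresholded against
#' those uniforms (`Y = 1` iff `u < p`), which lets different designs be
#' compared on a common patient stream.
#'
#' @param params Scenario regression parameters (list `beta`, `gamma`).
#' @param arm Treatment indicator vector (0/1), recycled to the number of
#'   profiles.
#' @param profiles Matrix of covariate profiles, one patient per row.
#' @param u Optional uniform deviates of length `nrow(profiles)`.
#' @return Integer vector of outcomes.
#' @export
generate_outcomes <- function(params, arm, profiles, u = NULL) {
  if (!is.matrix(profiles)) profiles <- matrix(profiles, nrow = 1)
  n <- nrow(profiles)
  arm <- rep_len(arm, n)
  xt <- cbind(1, profiles)
  p <- stats::pnorm(drop(xt %*% params$beta) + arm * drop(xt %*% params$gamma))
  if (is.null(u)) u <- stats::runif(n)
  as.integer(u < p)
}

#' Analytic per-subgroup and overall event rates of a scenario
#'
#' Computes `pA(x)` and `pB(x)` for every covariate profile directly from the
#' probit model, plus prevalence-weighted overall rates. With independent
#' Bernoulli(0.5) covariates all four subgroups have weight 0.25; weights are
#' recomputed from `covariate_dist` in general.
#'
#' @param scenario A scenario object (see [scenario_table()]).
#' @return Data frame with one row per subgroup plus an `overall` row, and
#'   columns for the profile, prevalence `weight`, `pA` and `pB`.
#' @export
true_effect_table <- function(scenario) {
  params <- scenario$params
  dist <- scenario$covariate_dist
  d <- length(dist)
  prof <- subgroup_profiles(d)
  w <- apply(prof, 1, function(x) prod(ifelse(x == 1, dist, 1 - dist)))
  pA <- response_probability(params, 1, prof)
  pB <- response_probability(params, 0, prof)
  out <- data.frame(
    subgroup = c(apply(prof, 1, paste, collapse = ""), "overall"),
    weight = c(w, 1),
    pA = c(pA, sum(w * pA)),
    pB = c(pB, sum(w * pB))
  )
  rownames(out) <- NULL
  out
}
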