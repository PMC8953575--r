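#' Monitoring configuration
#'
#' Collects the design parameters of both sequential tests: the margins
#' `delta1` (superiority) and `delta2` (futility), the calibrated posterior
#' probability cutoffs `eps1` (interim superiority), `eps2` (interim
#' futility), `eps3` (final superiority), and the one-sided type I error
#' target `alpha` of the comparator group sequential test.
#'
#' @param delta1,delta2 Margins on the treatment-effect scale (event-rate
#'   difference A minus B); the defaults are 0.
#' @param eps1,eps2,eps3 Probability cutoffs in (0, 1); the defaults are the
#'   calibrated values 0.995, 0.75, 0.98.
#' @param alpha One-sided level of the comparator test.
#' @return List of class `monitoring_config`.
#' @export
monitoring_config <- function(delta1 = 0, delta2 = 0, eps1 = 0.995,
                              eps2 = 0.75, eps3 = 0.98, alpha = 0.05) {
  stopifnot(eps1 > 0, eps1 < 1, eps2 > 0, eps2 < 1, eps3 > 0, eps3 < 1,
            alpha > 0, alpha < 0.5)
  structure(list(delta1 = delta1, delta2 = delta2, eps1 = eps1, eps2 = eps2,
                 eps3 = eps3, alpha = alpha),
            class = "monitoring_config")
}

#' Subgroup-averaged treatment effect
#'
#' The prevalence-weighted average, over a cohort's subgroups, of the
#' difference in event probability between the arms:
#' `sum_i w_i * (pA(x_i) - pB(x_i))` with `pA`, `pB` from the probit model at
#' `theta`. Weights are the cohort's empirical subgroup prevalences.
#'
#' @param theta Regression parameters (list `beta`, `gamma`).
#' @param weights Non-negative subgroup weights summing to 1, aligned with
#'   the rows of `profiles`.
#' @param profiles Subgroup profile matrix (default all profiles for the
#'   implied `d`).
#' @return Value in `[-1, 1]`; negative favors the experimental arm A.
#' @export
delta_k <- function(theta, weights, profiles = subgroup_profiles(length(theta$beta) - 1)) {
  stopifnot(length(weights) == nrow(profiles), all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8)
  pA <- response_probability(theta, 1, profiles)
  pB <- response_probability(theta, 0, profiles)
  sum(weights * (pA - pB))
}

#' Posterior draws of the cumulative sequential test statistic
#'
#' For each posterior draw of the coefficients, computes the cohort-size
#' weighted average `T_k = sum_j n_j * Delta_j / sum_j n_j` of the
#' subgroup-averaged treatment effects of the `k` accumulated cohorts, each
#' `Delta_j` using cohort `j`'s own empirical subgroup weights. All `Delta_j`
#' are evaluated under the current posterior (conditioning on all accumulated
#' data).
#'
#' @param posterior A `posterior_draws` object.
#' @param cohort_sizes Positive sizes `n_1..n_k`.
#' @param cohort_weights List of `k` subgroup weight vectors, each aligned
#'   with `profiles`.
#' @param profiles Subgroup profile matrix.
#' @return Numeric vector, one `T_k` value per posterior draw.
#' @export
test_statistic_draws <- function(posterior, cohort_sizes, cohort_weights,
                                 profiles = subgroup_profiles(posterior$d)) {
  stopifnot(inherits(posterior, "posterior_draws"),
            length(cohort_sizes) == length(cohort_weights),
            all(cohort_sizes > 0))
  k <- posterior$d + 1L
  B <- posterior$draws[, 1:k, drop = FALSE]
  G <- posterior$draws[, (k + 1):(2 * k), drop = FALSE]
  xt <- t(cbind(1, profiles))                     # (d+1) x I
  lpB <- B %*% xt                                 # draws x I
  diffs <- stats::pnorm(lpB + G %*% xt) - stats::pnorm(lpB)
  # Delta_j is linear in the weights, so the size-weighted average of the
  # per-cohort Deltas equals one Delta at the size-averaged weights.
  W <- do.call(cbind, cohort_weights)             # I x k
  wbar <- drop(W %*% cohort_sizes) / sum(cohort_sizes)
  drop(diffs %*% wbar)
}

#' Bayesian sequential decision rule
#'
#' At interim analyses (`stage < n_stages`) the trial stops for superiority
#' if `Pr(T_k < delta1 | data) > eps1`, otherwise stops for futility if
#' `Pr(T_k > delta2 | data) > eps2`, otherwise continues (superiority is
#' checked first). At the final analysis, A is declared superior iff
#' `Pr(T_K < delta1 | data) > eps3`.
#'
#' @param tk_draws Posterior draws of the test statistic.
#' @param config A [monitoring_config()].
#' @param stage Current analysis index `k`.
#' @param n_stages Total number of analyses `K`.
#' @return List of class `bacara_decision` with `verdict` (one of
#'   `CONTINUE`, `STOP_SUPERIOR`, `STOP_FUTILE`, `FINAL_SUPERIOR`,
#'   `FINAL_NOT_SUPERIOR`), `stage`, and the posterior tail probabilities
#'   `p_superior`, `p_futile`.
#' @export
bayes_decision <- function(tk_draws, config, stage, n_stages) {
  stopifnot(length(tk_draws) > 0, stage >= 1, stage <= n_stages)
  p_sup <- mean(tk_draws < config$delta1)
  p_fut <- mean(tk_draws > config$delta2)
  if (stage < n_stages) {
    verdict <- if (p_sup > config$eps1) "STOP_SUPERIOR"
               else if (p_fut > config$eps2) "STOP_FUTILE"
               else "CONTINUE"
  } else {
    verdict <- if (p_sup > config$eps3) "FINAL_SUPERIOR"
               else "FINAL_NOT_SUPERIOR"
  }
  structure(list(verdict = verdict, stage = stage, p_superior = p_sup,
                 p_futile = p_fut),
            class = "bacara_decision")
}

# O'Brien-Fleming-type alpha spending function (Lan-DeMets form) for
# one-sided alpha: f(t) = 2 * (1 - pnorm(qnorm(1 - alpha/2) / sqrt(t))),
# which satisfies f(1) = alpha exactly.
obf_spending <- function(t, alpha) {
  2 * (1 - stats::pnorm(stats::qnorm(1 - alpha / 2) / sqrt(t)))
}

#' Group sequential boundaries under O'Brien-Fleming alpha spending
#'
#' Critical z-values at each analysis such that the cumulative probability of
#' crossing under the null equals the Lan-DeMets O'Brien-Fleming spending
#' function at the information fractions. Crossing probabilities are computed
#' by the standard recursive numerical integration of the joint normal
#' density of the sequential z-statistics (grid quadrature).
#'
#' @param alpha One-sided type I error, in (0, 0.5).
#' @param info_fractions Increasing information fractions in (0, 1], ending
#'   at 1.
#' @return Numeric vector of critical values, one per analysis, decreasing.
#' @export
obf_boundaries <- function(alpha = 0.05, info_fractions = c(1/3, 2/3, 1)) {
  stopifnot(alpha > 0, alpha < 0.5, length(info_fractions) >= 1,
            all(diff(info_fractions) > 0), all(info_fractions > 0),
            abs(info_fractions[length(info_fractions)] - 1) < 1e-12)
  key <- paste0(format(alpha, digits = 12), "|",
                paste(format(info_fractions, digits = 12), collapse = ","))
  cached <- .bacara_cache[[key]]
  if (!is.null(cached)) return(cached)
  spend <- obf_spending(info_fractions, alpha)
  incr <- diff(c(0, spend))
  K <- length(info_fractions)
  hstep <- 0.01
  z <- seq(-8.6, 8.6, by = hstep)
  wts <- rep(hstep, length(z))
  wts[c(1, length(z))] <- hstep / 2                 # trapezoid
  # subdensity of Z_1 on the grid
  h <- stats::dnorm(z)
  bounds <- numeric(K)
  bounds[1] <- stats::qnorm(1 - incr[1])
  for (j in seq_len(K)[-1]) {
    cont <- z < bounds[j - 1]
    hw <- h * wts
    hw[!cont] <- 0
    tprev <- info_fractions[j - 1]
    tj <- info_fractions[j]
    cc <- sqrt(tprev / tj)
    dd <- sqrt(1 - tprev / tj)
    # h_j(z) = int h_{j-1}(u) * dnorm((z - c*u)/d)/d du over the
    # continuation region
    Kmat <- stats::dnorm(outer(z, z * cc, "-") / dd) / dd
    h <- drop(Kmat %*% hw)
    # solve for bound: tail mass above it equals the spending increment
    tail_mass <- rev(cumsum(rev(h * wts)))
    idx <- which(tail_mass <= incr[j])[1]
    if (is.na(idx) || idx == 1) {
      bounds[j] <- z[1]
    } else {
      # linear interpolation between grid points
      x1 <- z[idx - 1]; x2 <- z[idx]
      y1 <- tail_mass[idx - 1]; y2 <- tail_mass[idx]
      bounds[j] <- x1 + (y1 - incr[j]) / (y1 - y2) * (x2 - x1)
    }
  }
  .bacara_cache[[key]] <- bounds
  bounds
}

.bacara_cache <- new.env(parent = emptyenv())

#' Conventional chi-square group sequential test
#'
#' The comparator test at analysis `k`: the pooled-variance two-proportion
#' z-statistic (signed so that a lower event rate on the experimental arm A
#' is positive), whose square is the usual chi-square statistic. The test
#' rejects when `|z|` exceeds the alpha-spending boundary -- the chi-square
#' test is two-sided, so with overall level `alpha` the boundaries are
#' computed from one-sided spending at `alpha / 2` (see [obf_boundaries()]).
#' Comparator designs stop on rejection only (no futility stopping).
#'
#' @param records Accumulated patient records (columns `arm`, `y`).
#' @param boundary Critical value for `|z|` at this analysis.
#' @param final Logical: is this the final analysis?
#' @return List of class `bacara_decision` with `verdict`, signed `z` and a
#'   `degenerate` flag (statistic undefined: empty arm or constant outcomes).
#' @export
comparator_test <- function(records, boundary, final = FALSE) {
  nA <- sum(records$arm == 1)
  nB <- sum(records$arm == 0)
  degenerate <- FALSE
  z <- 0
  if (nA == 0 || nB == 0) {
    degenerate <- TRUE
  } else {
    pA <- sum(records$y[records$arm == 1]) / nA
    pB <- sum(records$y[records$arm == 0]) / nB
    pp <- (sum(records$y)) / (nA + nB)
    if (pp <= 0 || pp >= 1) {
      degenerate <- TRUE
    } else {
      z <- (pB - pA) / sqrt(pp * (1 - pp) * (1 / nA + 1 / nB))
    }
  }
  reject <- !degenerate && abs(z) > boundary
  verdict <- if (reject) {
    if (final) "FINAL_SUPERIOR" else "STOP_SUPERIOR"
  } else {
    if (final) "FINAL_NOT_SUPERIOR" else "CONTINUE"
  }
  structure(list(verdict = verdict, z = z, degenerate = degenerate),
            class = "bacara_decision")
}
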