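#' Fixed equal randomization probability
#'
#' @return Allocation probability to the experimental arm A: always 0.5.
#' @export
prob_trad <- function() 0.5

#' Rosenberger-style response-adaptive allocation probability
#'
#' Failure-minimizing square-root rule on the per-arm success (non-event)
#' proportions: `sqrt(qA) / (sqrt(qA) + sqrt(qB))`. Proportions are clipped to
#' `clip` before the rule to guard against absorbing allocation and 0/0 with
#' small cohorts; the clipping does not affect asymptotic behavior.
#'
#' @param success_rate_A,success_rate_B Observed per-arm success proportions
#'   (`Pr(Y = 0)`), pooled over all accumulated cohorts.
#' @param clip Two-sided clipping bounds applied to each proportion.
#' @return Allocation probability to arm A.
#' @export
prob_rar <- function(success_rate_A, success_rate_B, clip = c(0.05, 0.95)) {
  stopifnot(success_rate_A >= 0, success_rate_A <= 1,
            success_rate_B >= 0, success_rate_B <= 1)
  if (success_rate_A == 0 && success_rate_B == 0) return(0.5)
  qa <- min(max(success_rate_A, clip[1]), clip[2])
  qb <- min(max(success_rate_B, clip[1]), clip[2])
  sqrt(qa) / (sqrt(qa) + sqrt(qb))
}

#' Personalized allocation from the posterior benefit probability
#'
#' The first personalized (CARA) rule: with `p` the posterior probability
#' that a patient with this covariate profile benefits from A,
#' the allocation probability to A is `p / (p + (1 - p))`. The denominator is
#' identically 1, so the rule equals `p`; it is implemented as written so the
#' algebraic identity is a tested property rather than a silent
#' simplification.
#'
#' @param p_benefit Posterior benefit probability (see
#'   [posterior_prob_benefit()]).
#' @return Allocation probability to arm A.
#' @export
prob_cara1 <- function(p_benefit) {
  stopifnot(p_benefit >= 0, p_benefit <= 1)
  p_benefit / (p_benefit + (1 - p_benefit))
}

#' Personalized allocation from estimated per-arm event rates
#'
#' The second personalized (CARA) rule: allocation to each arm proportional
#' to its estimated non-event probability,
#' `(1 - pA) / ((1 - pA) + (1 - pB))`, with the rates taken as plug-in
#' posterior-mean estimates for the patient's covariate profile.
#'
#' @param pA_hat,pB_hat Estimated event rates under A and B (see
#'   [posterior_mean_rates()]).
#' @return Allocation probability to arm A.
#' @export
prob_cara2 <- function(pA_hat, pB_hat) {
  stopifnot(pA_hat >= 0, pA_hat <= 1, pB_hat >= 0, pB_hat <= 1)
  den <- (1 - pA_hat) + (1 - pB_hat)
  if (den == 0) return(0.5)
  (1 - pA_hat) / den
}
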