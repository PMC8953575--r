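---
title: "Personalized response-adaptive group sequential trials with bacara"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized response-adaptive group sequential trials with bacara}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacara)
```

## The problem

In a comparative two-arm trial with a binary adverse endpoint (an "event":
say, diagnosis of advanced disease under one of two screening modalities),
patients differ in measured risk factors, and the two interventions may work
differently in different covariate subgroups. Covariate-adjusted
response-adaptive randomization (CARA) uses the accumulating outcome data to
randomize each new patient with a probability tailored to their own
covariates, steering more patients toward whichever arm currently looks
better *for patients like them*. That is ethically attractive, but it
interferes with the usual frequentist test: when a covariate has a strong
prognostic effect, outcome-dependent allocation correlates arm membership
with patient risk and a conventional group sequential test can grossly
inflate the type I error rate.

`bacara` simulates this whole landscape. It implements five designs on a
common patient stream — fixed 1:1 randomization (`TRAD`), overall
response-adaptive randomization (`RAR`), two personalized rules (`CARA1`,
`CARA2`) monitored by a conventional chi-square group sequential test, and
the Bayesian design `BACARA`, which combines the personalized allocation of
`CARA1` with a subgroup-averaged Bayesian test whose cutoffs are calibrated
to restore error control — and estimates their operating characteristics
over replicated trials.

## Outcome model

Each patient carries $d$ binary covariates $x$ (the shipped scenarios use
$d = 2$, drawn independently Bernoulli(0.5)) and is assigned treatment $G$
(1 = experimental arm A, 0 = control B). With $\tilde x = (1, x^\top)^\top$,
the event indicator follows a probit regression

$$\Pr(Y = 1 \mid G, x) \;=\; \Phi\!\left(\tilde x^\top \beta
  + G\,\tilde x^\top \gamma\right),$$

where $\beta$ holds the intercept and prognostic (main) effects, and
$\gamma$ the treatment main effect and predictive (interaction) effects.
`scenario_table()` exposes twenty parameter sets spanning pure nulls,
prognostic-only nulls, and alternatives with prognostic and/or predictive
structure; `true_effect_table()` evaluates the implied per-subgroup and
overall event rates analytically, so the generator can always be checked
against closed forms.

## Trial engine

A trial enrolls up to $N = 210$ patients in $K = 3$ cohorts of 70 (all
configurable). Cohort 1 is always randomized 1:1 — it is the burn-in that
gives the regression something to fit. After each cohort's outcomes are
observed, the stage analysis runs; if the trial continues, the design's
allocation rule is refreshed from all accumulated data, frozen, and applied
patient-by-patient to the next cohort as independent Bernoulli draws (no urn
or blocking — the binomial assignment variability is part of what the
operating characteristics measure).

The allocation rules are:

* `TRAD`: $\pi_A = 0.5$ throughout.
* `RAR`: Rosenberger-style failure-minimizing rule
  $\pi_A = \sqrt{q_A}/(\sqrt{q_A} + \sqrt{q_B})$ on the pooled per-arm
  success proportions $q_g = \widehat{\Pr}(Y = 0 \mid G = g)$. The
  proportions are clipped to $[0.05, 0.95]$ first; this guards the $0/0$
  and absorbing-allocation corners reachable with 70-patient cohorts and
  does not affect the rule's asymptotics.
* `CARA1` (and `BACARA`): $\pi_{k,A}(x) = p_{k-1}(x) / \{p_{k-1}(x) +
  (1 - p_{k-1}(x))\}$, where $p_{k-1}(x) = \Pr(p_A(x) < p_B(x) \mid
  D_{k-1})$ is the posterior probability that a patient with covariates $x$
  benefits from A. The denominator is identically 1, so the rule equals
  $p_{k-1}(x)$; it is coded as written and the identity is asserted by a
  test, so any "simplifying" refactor is caught.
* `CARA2`: $\pi_{k,A}(x) = (1 - \hat p_A(x))/\{(1 - \hat p_A(x)) +
  (1 - \hat p_B(x))\}$ with plug-in rates at the posterior mean of the
  coefficients.

$p_{k-1}(x)$ is computed by draw counting: the fraction of posterior draws
with $\tilde x^\top \gamma < 0$ (the probit link is strictly increasing, so
$p_A(x) < p_B(x) \iff \tilde x^\top\gamma < 0$). Draws with the contrast
exactly zero — a measure-zero event — count as *not* benefiting, making the
inequality strict and the degenerate all-null posterior allocate at
probability zero rather than one.

## Posterior inference

The probit coefficients get independent normal priors centered at the
maximum-likelihood estimate of the accumulated data with common variance 4 —
informative enough to stabilize a 70-patient, 6-parameter fit, vague enough
not to dominate it. The prior is re-centered at every interim from all data
accumulated so far. When the MLE is unusable (perfect separation, an empty
arm, constant outcomes, runaway coefficients), the center falls back to a
ridge-penalized probit estimate (L2 penalty 1.0) and the fit is flagged; a
simulation never aborts mid-replicate.

Sampling uses Albert–Chib truncated-normal data augmentation, implemented in
C++: latent utilities $z_i \sim N(x_i^\top\theta, 1)$ truncated by the
observed outcome, then $\theta$ from its exact multivariate-normal full
conditional (whose precision $X^\top X + \Sigma_0^{-1}$ is constant and
Cholesky-factored once per chain). One-sided truncated normals use naive
rejection near the bulk and Robert's translated-exponential rejection in the
tail, both driven by R's RNG so `set.seed()` makes entire chains
reproducible. Defaults are 10,000 iterations with 5,000 burn-in; the
simulation studies in the test suite run reduced 2,000/1,000 chains, which
leaves posterior summaries accurate to well under the Monte Carlo noise of
the trial replications themselves. The sampler is validated against
brute-force grid quadrature of the exact posterior on a small
single-covariate dataset.

## Monitoring

### The Bayesian subgroup-averaged test

Because allocation depends on covariates, patients within an arm are not
exchangeable and a pooled two-proportion comparison is biased. The `BACARA`
test therefore averages the treatment contrast *within* subgroups first. For
cohort $k$ with observed subgroup prevalences $w_{ki}$,

$$\Delta_k(\theta) = \sum_i w_{ki}\,\{p_A(x_i) - p_B(x_i)\},
\qquad
T_k = \frac{\sum_{j\le k} n_j \Delta_j}{\sum_{j \le k} n_j}.$$

$\Pr(x)$ in $\Delta_k$ is taken as the empirical subgroup prevalence within
cohort $k$ — each $\Delta_k$ is a summary of its own cohort — and every
$\Delta_j$, $j = 1..k$, is evaluated under the *current* posterior
$\Pr(\theta \mid D_k)$, since the stage-$k$ decision conditions on all
accumulated data. Since $\Delta$ is linear in the weights, $T_k$ per draw
equals a single $\Delta$ at the cohort-size-weighted average of the weight
vectors; the code exploits this and a test pins the identity.

With margins $\delta_1 = \delta_2 = 0$ and cutoffs
$(\epsilon_1, \epsilon_2, \epsilon_3)$, an interim stops for superiority if
$\Pr(T_k < \delta_1 \mid D_k) > \epsilon_1$, else for futility if
$\Pr(T_k > \delta_2 \mid D_k) > \epsilon_2$ (superiority is checked first;
the ordering is fixed for determinism). The final analysis declares A
superior iff $\Pr(T_K < \delta_1 \mid D_K) > \epsilon_3$. The shipped
defaults $(0.995, 0.75, 0.98)$ are the calibrated values for the
$N = 210$, $K = 3$ setup at one-sided $\alpha = 0.05$ and power 0.8. One
posterior fit per stage serves both the monitoring decision and the next
cohort's allocation.

### The comparator chi-square test

The four comparator designs use the conventional group sequential test: the
pooled-variance two-proportion statistic, whose square is the chi-square
statistic, against O'Brien–Fleming-type alpha-spending boundaries at
information fractions $(1/3, 2/3, 1)$. We implement this as the two-sided
chi-square test at overall level 0.05 — rejection when $|z|$ exceeds the
boundary, with the Lan–DeMets OBF spending function
$f(t) = 2 - 2\Phi(\Phi^{-1}(1 - \alpha/2)/\sqrt t)$ applied at $\alpha/2$
per tail, giving boundaries $\approx (3.71, 2.51, 2.00)$. A one-sided
construction at $\alpha = 0.05$ (final boundary $\approx 1.70$) is also
expressible via `obf_boundaries()`, but the two-sided chi-square is what a
"conventional group sequential chi-square test" means and is the variant
whose null level, power and expected-failure profile line up with the
reference operating characteristics the acceptance suite checks.
Comparators stop early on rejection only; there is no futility boundary, so
their single rejection probability aggregates cleanly across stages.

Boundaries are solved by the standard recursive numerical integration of the
sequential normal density (trapezoid grid on $[-8.6, 8.6]$, step 0.01 —
crossing probabilities accurate to about $10^{-6}$), memoized per
$(\alpha, \text{fractions})$. An independent Monte Carlo simulation of the
joint sequential path serves as the oracle in the test suite.

## Calibration

`calibrate_cutoffs()` implements the simulation-based search: start at
$\epsilon_1 = \epsilon_3 = 1 - \alpha$ and $\epsilon_2 = 1 - \beta$; raise
the superiority cutoffs while the worst null-scenario type I error exceeds
target (lower them when below), raise the futility cutoff while power falls
short (lower it when above); halve a coordinate's step when its direction
reverses; stop inside the tolerance band ($\alpha \pm 0.01$, power within
0.02) or at the iteration cap, returning the trace and a convergence flag.
Common random numbers (a fixed per-evaluation seed schedule) make the search
deterministic. The published cutoffs are validated by their achieved error
rates, not by re-deriving the cutoff values, whose search path depends on
unstated replication counts and step sizes.

## Randomness architecture

Every trial derives three independent streams from its seed via a
multiplicative hash (`mix_seed`): patients (covariates and the outcome
uniforms, thresholded as $Y = 1 \iff u < \Pr(Y=1 \mid G, x)$), assignments,
and MCMC. The patient stream does not depend on the design, so competing
designs face identical patients and identical potential outcomes — the
cross-design contrasts in failures and allocation are paired comparisons.
Replicates are seeded independently from the master seed, so aggregation is
order-invariant and safe to parallelize.

## What the generator does and does not emulate

The generator *is* the study conditions: independent Bernoulli(0.5) binary
covariates, probit outcomes, cohorts of 70 with outcomes fully observed
before the next cohort enrolls. It does not model delayed or missing
responses, staggered enrollment, continuous covariates (and their
dichotomization), covariate drift over the trial, or dropout. Passing tests
therefore certify the designs' behavior under clean cohort-wise follow-up,
not robustness to those real-trial features.

## Problem sizes and known limitations

The test suite runs 1,000-replicate studies for the fast fixed-randomization
design and 500-replicate studies with 2,000/1,000 MCMC chains for the
adaptive designs; the acceptance script uses 1,000 replicates throughout.
At these sizes a rejection probability carries a Monte Carlo standard error
of about 0.01–0.02, which is the resolution at which the reproduced
operating characteristics should be read.

Known limitations: the reproduced type I inflation of `CARA1` under a
strongly prognostic covariate is somewhat larger (by roughly 0.1 in
rejection probability) than the reference value, and its allocation
probabilities correspondingly more dispersed — the reference computation of
the posterior benefit probability is not fully specified, and the
draw-counting estimator used here is one faithful reading. The inflation
phenomenon itself, its direction, and the restoration of error control by
the subgroup-averaged test are all reproduced. Multi-arm extensions,
covariate selection during burn-in, and safety-endpoint monitoring are out
of scope.

## A minimal session

```{r example, eval = FALSE}
library(bacara)

# one BaCARA trial under a pure treatment effect
res <- run_trial(trial_config(10, "BACARA", seed = 1))
res

# operating characteristics of the fixed design under the global null
oc <- operating_characteristics(1, "TRAD", n_reps = 1000, seed = 1)
oc

# report tables across designs
tabs <- summarize_to_tables(list(oc))
tabs$rejection
```
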