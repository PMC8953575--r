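test_that("subgroup-averaged effect is zero under the null and analytic otherwise", {
  w <- rep(0.25, 4)
  for (i in 1:9) expect_equal(delta_k(get_scenario(i)$params, w), 0)

  expect_equal(delta_k(get_scenario(10)$params, w), pnorm(-0.5) - 0.5)

  # brute force over the four profiles of scenario 20
  d20 <- mean(c(pnorm(0.85) - pnorm(0.5),
                pnorm(0.85) - pnorm(1.0),
                pnorm(-0.15) - pnorm(0),
                pnorm(-0.15) - pnorm(0.5)))
  expect_equal(delta_k(get_scenario(20)$params, w), d20)
})

test_that("subgroup-averaged effect is linear in the weights", {
  th <- get_scenario(19)$params
  w1 <- c(0.4, 0.3, 0.2, 0.1)
  w2 <- c(0.1, 0.1, 0.4, 0.4)
  lam <- 0.3
  mix <- lam * w1 + (1 - lam) * w2
  expect_equal(delta_k(th, mix),
               lam * delta_k(th, w1) + (1 - lam) * delta_k(th, w2))
})

test_that("cumulative statistic draws reduce correctly", {
  set.seed(31)
  draws <- cbind(matrix(rnorm(300, sd = 0.3), 100, 3),
                 matrix(rnorm(300, sd = 0.3), 100, 3))
  post <- fake_posterior(draws)
  w <- c(0.25, 0.25, 0.25, 0.25)

  # single cohort: T equals Delta draw by draw
  t1 <- test_statistic_draws(post, 70, list(w))
  d1 <- apply(draws, 1, function(th) {
    delta_k(list(beta = th[1:3], gamma = th[4:6]), w)
  })
  expect_equal(t1, d1)

  # identical weights across cohorts: T equals the single-cohort Delta
  t2 <- test_statistic_draws(post, c(70, 70), list(w, w))
  expect_equal(t2, d1)

  # merging cohorts with shared weights leaves T unchanged
  t3 <- test_statistic_draws(post, c(140), list(w))
  expect_equal(t3, t2)

  # unequal weights: size-weighted average of the per-cohort Deltas
  w2 <- c(0.4, 0.1, 0.3, 0.2)
  tk <- test_statistic_draws(post, c(70, 30), list(w, w2))
  d2 <- apply(draws, 1, function(th) {
    delta_k(list(beta = th[1:3], gamma = th[4:6]), w2)
  })
  expect_equal(tk, (70 * d1 + 30 * d2) / 100)
})

test_that("Bayesian decision rule applies the cutoffs in order", {
  cfg <- monitoring_config()
  expect_equal(bayes_decision(rep(-0.3, 100), cfg, 1, 3)$verdict,
               "STOP_SUPERIOR")
  expect_equal(bayes_decision(rep(0.3, 100), cfg, 2, 3)$verdict,
               "STOP_FUTILE")
  half <- c(rep(-0.1, 50), rep(0.1, 50))
  expect_equal(bayes_decision(half, cfg, 1, 3)$verdict, "CONTINUE")
  # final analysis uses eps3
  expect_equal(bayes_decision(rep(-0.3, 100), cfg, 3, 3)$verdict,
               "FINAL_SUPERIOR")
  expect_equal(bayes_decision(half, cfg, 3, 3)$verdict, "FINAL_NOT_SUPERIOR")
})

test_that("raising the superiority cutoff can only withhold interim stops", {
  set.seed(32)
  for (r in 1:20) {
    tk <- rnorm(200, mean = runif(1, -0.3, 0.1), sd = 0.1)
    lo <- bayes_decision(tk, monitoring_config(eps1 = 0.90), 1, 3)$verdict
    hi <- bayes_decision(tk, monitoring_config(eps1 = 0.99), 1, 3)$verdict
    if (hi == "STOP_SUPERIOR") expect_equal(lo, "STOP_SUPERIOR")
  }
})

test_that("alpha spending boundaries have the right shape", {
  expect_equal(obf_boundaries(0.05, 1), qnorm(0.95), tolerance = 1e-8)

  b <- obf_boundaries(0.05, c(1/3, 2/3, 1))
  expect_true(all(diff(b) < 0))
  expect_gt(b[3], qnorm(0.95))

  # spending function conservation: increments sum exactly to alpha
  sp <- 2 * (1 - pnorm(qnorm(1 - 0.05 / 2) / sqrt(c(1/3, 2/3, 1))))
  expect_lt(abs(sum(diff(c(0, sp))) - 0.05), 1e-6)

  expect_error(obf_boundaries(0.05, c(2/3, 1/3, 1)))
  expect_error(obf_boundaries(0.05, c(1/3, 2/3)))
})

test_that("boundary crossing probabilities match a Monte Carlo oracle", {
  info <- c(1/3, 2/3, 1)
  alpha <- 0.025
  b <- obf_boundaries(alpha, info)
  sp <- 2 * (1 - pnorm(qnorm(1 - alpha / 2) / sqrt(info)))
  incr <- diff(c(0, sp))

  set.seed(33)
  n <- 4e5
  z1 <- rnorm(n)
  z2 <- sqrt(1/2) * z1 + sqrt(1/2) * rnorm(n)
  z3 <- sqrt(2/3) * z2 + sqrt(1/3) * rnorm(n)
  c1 <- z1 > b[1]
  c2 <- !c1 & z2 > b[2]
  c3 <- !c1 & !c2 & z3 > b[3]
  for (j in 1:3) {
    phat <- mean(list(c1, c2, c3)[[j]])
    se <- sqrt(incr[j] * (1 - incr[j]) / n)
    expect_lt(abs(phat - incr[j]), 4 * se + 1e-5)
  }
  tot <- mean(c1 | c2 | c3)
  expect_lt(abs(tot - alpha), 4 * sqrt(alpha * (1 - alpha) / n))
})

test_that("comparator test computes the pooled two-proportion statistic", {
  mk <- function(eA, nA, eB, nB) {
    data.frame(arm = c(rep(1, nA), rep(0, nB)),
               y = c(rep(1, eA), rep(0, nA - eA), rep(1, eB), rep(0, nB - eB)))
  }
  eq <- comparator_test(mk(15, 70, 15, 70), boundary = 2)
  expect_equal(eq$z, 0)
  expect_equal(eq$verdict, "CONTINUE")

  r <- comparator_test(mk(10, 70, 30, 70), boundary = 2.5)
  pp <- 40 / 140
  z_hand <- (30/70 - 10/70) / sqrt(pp * (1 - pp) * (2 / 70))
  expect_equal(r$z, z_hand)
  expect_equal(r$verdict, "STOP_SUPERIOR")

  never <- comparator_test(mk(10, 70, 30, 70), boundary = Inf, final = TRUE)
  expect_equal(never$verdict, "FINAL_NOT_SUPERIOR")

  onearm <- comparator_test(data.frame(arm = rep(1, 10), y = rbinom(10, 1, 0.5)),
                            boundary = 2)
  expect_true(onearm$degenerate)
  expect_equal(onearm$verdict, "CONTINUE")
})
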