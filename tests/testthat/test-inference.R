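test_that("probit MLE recovers generating coefficients at large n", {
  rec <- simulate_records(10, 20000, seed = 42)
  fit <- fit_probit_mle(rec)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$gamma[1] - (-0.5)), 0.1)
  expect_true(all(abs(fit$beta) < 0.1))
  expect_true(all(abs(fit$gamma[2:3]) < 0.1))

  rec1 <- simulate_records(1, 20000, seed = 43)
  fit1 <- fit_probit_mle(rec1)
  expect_true(all(abs(c(fit1$beta, fit1$gamma)) < 0.1))
})

test_that("degenerate data falls back to a finite penalized fit", {
  rec <- simulate_records(1, 40, seed = 1)
  rec$y <- 0L
  fit <- fit_probit_mle(rec)
  expect_true(fit$degenerate)
  expect_true(all(is.finite(c(fit$beta, fit$gamma))))

  rec2 <- simulate_records(1, 40, seed = 2)
  rec2$arm <- 1L
  fit2 <- fit_probit_mle(rec2)
  expect_true(fit2$degenerate)
  expect_true(all(is.finite(c(fit2$beta, fit2$gamma))))
})

test_that("posterior sampling validates its iteration counts", {
  rec <- simulate_records(1, 30, seed = 3)
  prior <- prior_spec(list(beta = c(0, 0, 0), gamma = c(0, 0, 0)))
  expect_error(sample_posterior(rec, prior, iterations = 100, burn_in = 100),
               "exceed")
})

test_that("a near-degenerate prior pins the posterior at its mean", {
  rec <- simulate_records(1, 30, seed = 3)
  center <- c(0.3, -0.2, 0.1, -0.4, 0.2, 0)
  prior <- list(mean = center, variance_diag = rep(1e-6, 6))
  post <- sample_posterior(rec, prior, iterations = 600, burn_in = 100,
                           seed = 5)
  expect_lt(max(abs(sweep(post$draws, 2, center))), 0.01)
})

test_that("posterior is reproducible given the seed", {
  rec <- simulate_records(5, 60, seed = 4)
  prior <- prior_spec(fit_probit_mle(rec))
  p1 <- sample_posterior(rec, prior, 500, 200, seed = 99)
  p2 <- sample_posterior(rec, prior, 500, 200, seed = 99)
  expect_identical(p1$draws, p2$draws)
})

test_that("posterior means recover the truth on abundant data", {
  rec <- simulate_records(19, 20000, seed = 44)
  prior <- prior_spec(fit_probit_mle(rec))
  post <- sample_posterior(rec, prior, 3000, 1000, seed = 6)
  truth <- unlist(get_scenario(19)$params)
  expect_true(all(abs(colMeans(post$draws) - truth) < 0.1))
})

test_that("posterior means on null data concentrate near zero", {
  rec <- simulate_records(1, 20000, seed = 45)
  prior <- prior_spec(fit_probit_mle(rec))
  post <- sample_posterior(rec, prior, 2000, 1000, seed = 7)
  expect_true(all(abs(colMeans(post$draws)) < 0.1))
})

test_that("Gibbs sampler agrees with grid integration on a small dataset", {
  # d = 1: four coefficients, posterior computable by brute-force quadrature
  rec <- tiny_probit_dataset()
  prior <- prior_spec(fit_probit_mle(rec))
  grid_mean <- grid_posterior_mean(rec, prior)
  post <- sample_posterior(rec, prior, 12000, 2000, seed = 12)
  expect_true(all(abs(colMeans(post$draws) - grid_mean) < 0.05))
})

test_that("larger prior variance pulls the posterior mean toward the MLE", {
  rec <- simulate_records(10, 150, seed = 46)
  mle <- fit_probit_mle(rec)
  theta_mle <- c(mle$beta, mle$gamma)
  center <- theta_mle + 0.8          # prior mean deliberately offset
  dists <- vapply(c(0.01, 1, 100), function(v) {
    prior <- list(mean = center, variance_diag = rep(v, 6))
    post <- sample_posterior(rec, prior, 6000, 2000, seed = 13)
    sqrt(sum((colMeans(post$draws) - theta_mle)^2))
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
})

test_that("posterior benefit probability counts draws with negative contrast", {
  # sign forced: every draw has gamma0 = -1
  d1 <- cbind(matrix(rnorm(300), 100, 3), -1, 0, 0)
  post <- fake_posterior(d1)
  for (prof in list(c(0, 0), c(1, 0), c(1, 1))) {
    expect_equal(posterior_prob_benefit(post, prof), 1)
  }

  # exact ties count as not benefiting
  d0 <- cbind(matrix(rnorm(300), 100, 3), 0, 0, 0)
  expect_equal(posterior_prob_benefit(fake_posterior(d0), c(1, 1)), 0)

  # direct count: 60 draws at gamma0 = -1, 40 at +1
  d <- cbind(matrix(rnorm(300), 100, 3), c(rep(-1, 60), rep(1, 40)), 0, 0)
  expect_equal(posterior_prob_benefit(fake_posterior(d), c(0, 1)), 0.6)
})

test_that("posterior benefit probability ignores draw order", {
  set.seed(14)
  d <- cbind(matrix(rnorm(400), 100, 4), rnorm(100), rnorm(100))
  post <- fake_posterior(d[, 1:6])
  perm <- fake_posterior(d[sample(100), 1:6])
  expect_equal(posterior_prob_benefit(post, c(1, 0)),
               posterior_prob_benefit(perm, c(1, 0)))
})

test_that("plug-in rates use the posterior mean of the coefficients", {
  at0 <- fake_posterior(matrix(0, 10, 6))
  expect_equal(unname(posterior_mean_rates(at0, c(0, 0))), c(0.5, 0.5))

  sc10 <- get_scenario(10)
  at10 <- fake_posterior(matrix(rep(c(sc10$params$beta, sc10$params$gamma),
                                    each = 10), 10, 6))
  r <- posterior_mean_rates(at10, c(0, 0))
  expect_equal(unname(r), c(pnorm(-0.5), 0.5))

  # mean of parameters, not of probabilities
  two <- fake_posterior(rbind(c(-1, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0)))
  expect_equal(unname(posterior_mean_rates(two, c(0, 0))["pB"]), 0.5)
})
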