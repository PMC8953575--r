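#' Design matrix of the probit regression
#'
#' Builds `[1, x, G, G*x]` so that the coefficient vector is
#' `theta = (beta, gamma)`.
#'
#' @param profiles Covariate matrix, one patient per row.
#' @param arm Treatment indicator vector (0/1).
#' @return Numeric matrix with `2 * (d + 1)` columns.
#' @export
probit_design <- function(profiles, arm) {
  if (!is.matrix(profiles)) profiles <- matrix(profiles, nrow = length(arm))
  d <- ncol(profiles)
  X <- cbind(1, profiles, arm, arm * profiles)
  colnames(X) <- c(paste0("beta", 0:d), paste0("gamma", 0:d))
  X
}

# Ridge-penalized probit fit, the fallback when the unpenalized MLE is
# unusable (separation, empty cells, single-arm data). L2 penalty keeps the
# estimate finite under any data configuration.
.ridge_probit <- function(X, y, lambda = 1.0) {
  negll <- function(theta) {
    p <- stats::pnorm(drop(X %*% theta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p)) + 0.5 * lambda * sum(theta^2)
  }
  grad <- function(theta) {
    lp <- drop(X %*% theta)
    p <- pmin(pmax(stats::pnorm(lp), 1e-12), 1 - 1e-12)
    w <- stats::dnorm(lp) * (p - y) / (p * (1 - p))
    drop(crossprod(X, w)) + lambda * theta
  }
  fit <- stats::optim(rep(0, ncol(X)), negll, grad, method = "BFGS",
                      control = list(maxit = 500))
  fit$par
}

#' Maximum-likelihood probit fit
#'
#' Fits the probit regression of outcome on covariates, treatment and their
#' interactions by maximum likelihood. When the MLE is degenerate --
#' non-convergence, perfect separation, single-arm data, constant outcomes or
#' runaway coefficients -- a ridge-penalized estimate (L2 penalty 1) is
#' returned instead and flagged, so a running simulation never aborts.
#'
#' @param records Data frame of patient records with covariate columns
#'   `x1..xd`, and columns `arm`, `y`.
#' @return List with `beta`, `gamma` and logical `degenerate`.
#' @export
fit_probit_mle <- function(records) {
  stopifnot(nrow(records) > 0)
  d <- sum(grepl("^x[0-9]+$", names(records)))
  profiles <- as.matrix(records[, paste0("x", seq_len(d)), drop = FALSE])
  X <- probit_design(profiles, records$arm)
  y <- records$y
  p <- ncol(X)
  degenerate <- length(unique(records$arm)) < 2 || length(unique(y)) < 2
  theta <- NULL
  if (!degenerate) {
    warned <- FALSE
    fit <- tryCatch(
      withCallingHandlers(
        stats::glm.fit(X, y, family = stats::binomial(link = "probit")),
        warning = function(w) {
          warned <<- TRUE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged && !warned &&
        all(is.finite(fit$coefficients)) &&
        max(abs(fit$coefficients)) < 10) {
      theta <- fit$coefficients
    } else {
      degenerate <- TRUE
    }
  }
  if (is.null(theta)) theta <- .ridge_probit(X, y)
  k <- p / 2
  list(beta = unname(theta[1:k]), gamma = unname(theta[(k + 1):p]),
       degenerate = degenerate)
}

#' Normal prior specification for the probit coefficients
#'
#' Independent normal priors centered at a fitted estimate (by default the
#' MLE of the accumulated data) with common diagonal variance 4: informative
#' enough to stabilize small-sample posteriors without dominating them.
#'
#' @param center List with `beta` and `gamma` (e.g. from [fit_probit_mle()]),
#'   or a numeric vector of length `2 * (d + 1)`.
#' @param variance Common prior variance for every coefficient.
#' @return List with `mean` and `variance_diag`.
#' @export
prior_spec <- function(center, variance = 4) {
  mean <- if (is.list(center)) c(center$beta, center$gamma) else center
  stopifnot(all(is.finite(mean)), variance > 0)
  list(mean = unname(mean), variance_diag = rep(variance, length(mean)))
}

#' Posterior sampling for the probit model
#'
#' Gibbs sampling by truncated-normal data augmentation (Albert-Chib): latent
#' normal utilities are drawn conditional on the outcomes, then the
#' coefficient vector from its exact multivariate-normal full conditional
#' under the independent normal prior.
#'
#' @param records Patient records (see [fit_probit_mle()]).
#' @param prior Prior from [prior_spec()].
#' @param iterations Total Gibbs iterations.
#' @param burn_in Initial iterations discarded.
#' @param seed Optional integer seed; when supplied the chain is fully
#'   reproducible.
#' @return Object of class `posterior_draws`: list with `draws` (matrix,
#'   one row per retained draw), `d`, `iterations`, `burn_in`, `seed`.
#' @export
sample_posterior <- function(records, prior, iterations = 10000,
                             burn_in = 5000, seed = NULL) {
  if (iterations <= burn_in || burn_in < 0)
    stop("iterations must exceed burn_in")
  d <- sum(grepl("^x[0-9]+$", names(records)))
  profiles <- as.matrix(records[, paste0("x", seq_len(d)), drop = FALSE])
  X <- probit_design(profiles, records$arm)
  stopifnot(length(prior$mean) == ncol(X), all(prior$variance_diag > 0))
  if (!is.null(seed)) set.seed(seed)
  draws <- gibbs_probit_cpp(X, as.integer(records$y), prior$mean,
                            prior$variance_diag, as.integer(iterations),
                            as.integer(burn_in))
  colnames(draws) <- colnames(X)
  structure(list(draws = draws, d = d, iterations = iterations,
                 burn_in = burn_in, seed = seed),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", nrow(x$draws), "retained (of", x$iterations,
      "iterations,", x$burn_in, "burn-in)\n")
  print(round(colMeans(x$draws), 3))
  invisible(x)
}

#' Posterior probability of individual treatment benefit
#'
#' For a patient with covariates `x`, the posterior probability that the
#' experimental arm lowers the event probability, i.e.
#' `Pr(pA(x) < pB(x) | data)`. Since the probit link is strictly increasing
#' this is the posterior mass of `xt' gamma < 0`; draws with the contrast
#' exactly zero count as not benefiting (strict inequality).
#'
#' @param posterior A `posterior_draws` object.
#' @param profile Binary covariate vector of length `d`.
#' @return Probability in `[0, 1]`.
#' @export
posterior_prob_benefit <- function(posterior, profile) {
  stopifnot(inherits(posterior, "posterior_draws"),
            length(profile) == posterior$d)
  k <- posterior$d + 1L
  g <- posterior$draws[, (k + 1):(2 * k), drop = FALSE]
  xt <- c(1, profile)
  mean(drop(g %*% xt) < 0)
}

#' Plug-in posterior-mean event rates
#'
#' Event rates for both arms at a covariate profile, evaluated at the
#' coordinate-wise posterior mean of the coefficients (a plug-in estimate,
#' not the posterior mean of the probabilities).
#'
#' @inheritParams posterior_prob_benefit
#' @return Named numeric vector `c(pA, pB)`.
#' @export
posterior_mean_rates <- function(posterior, profile) {
  stopifnot(inherits(posterior, "posterior_draws"),
            length(profile) == posterior$d)
  theta <- colMeans(posterior$draws)
  k <- posterior$d + 1L
  xt <- c(1, profile)
  b <- sum(xt * theta[1:k])
  g <- sum(xt * theta[(k + 1):(2 * k)])
  c(pA = stats::pnorm(b + g), pB = stats::pnorm(b))
}
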