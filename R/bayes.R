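# Numerically stable log(1 + exp(eta)).
log1pexp <- function(eta) {
  out <- eta
  lo <- eta <= 18
  out[lo] <- log1p(exp(eta[lo]))
  hi <- eta > 18 & eta <= 33
  out[hi] <- eta[hi] + exp(-eta[hi])
  out
}

# Normal approximation to the bounded-uniform-prior posterior: mean at the
# (clamped) MLE, covariance from the inverse observed information.  Aliased
# or separated coordinates get a diffuse fallback variance, and standard
# deviations are capped at 5 so that flat (separated) directions stay on the
# scale of the bounded prior support rather than exploding.
.posterior_moments <- function(X, y, bound) {
  f <- .fit_glm(X, y)
  mu <- f$coefficients
  mu[is.na(mu)] <- 0
  mu <- pmin(pmax(mu, -bound + 1e-6), bound - 1e-6)
  V <- f$vcov
  bad <- !is.finite(diag(V)) | diag(V) <= 0
  V[!is.finite(V)] <- 0
  diag(V)[bad] <- 4
  s <- pmin(1, 5 / sqrt(diag(V)))
  V <- V * outer(s, s)
  ev <- eigen(V, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-8)
  list(mu = mu, V = ev$vectors %*% (lam * t(ev$vectors)),
       L = ev$vectors %*% diag(sqrt(lam), ncol(X)))
}

# Laplace mode: multivariate-normal draws at the posterior moments, clipped
# to the prior support.
.laplace_posterior <- function(X, y, bound, draws) {
  m <- .posterior_moments(X, y, bound)
  d <- MASS::mvrnorm(draws, m$mu, m$V)
  d <- pmin(pmax(d, -bound + 1e-9), bound - 1e-9)
  colnames(d) <- colnames(X)
  list(draws = d, accept_rate = NA_real_)
}

# Random-walk Metropolis under independent U(-bound, bound) priors, with a
# Laplace-shaped proposal whose global scale adapts during burn-in towards
# a 25-45% acceptance rate.
.metropolis_posterior <- function(X, y, bound, iter, burnin, draws) {
  p <- ncol(X)
  m <- .posterior_moments(X, y, bound)
  loglik <- function(th) {
    eta <- drop(X %*% th)
    sum(y * eta) - sum(log1pexp(eta))
  }
  th <- m$mu
  ll <- loglik(th)
  scale <- 2.38 / sqrt(p)
  keep <- matrix(NA_real_, iter - burnin, p)
  acc <- 0L; acc_win <- 0L
  for (it in seq_len(iter)) {
    prop <- th + scale * drop(m$L %*% stats::rnorm(p))
    if (all(abs(prop) < bound)) {
      llp <- loglik(prop)
      if (log(runif(1)) < llp - ll) {
        th <- prop; ll <- llp; acc <- acc + 1L; acc_win <- acc_win + 1L
      }
    }
    if (it <= burnin && it %% 50 == 0) {
      rate <- acc_win / 50
      if (rate < 0.1) scale <- scale * 0.5
      else if (rate < 0.25) scale <- scale * 0.85
      else if (rate > 0.45) scale <- scale * 1.2
      acc_win <- 0L
    }
    if (it > burnin) keep[it - burnin, ] <- th
  }
  idx <- if (nrow(keep) > draws)
    round(seq(1, nrow(keep), length.out = draws)) else seq_len(nrow(keep))
  d <- keep[idx, , drop = FALSE]
  colnames(d) <- colnames(X)
  list(draws = d, accept_rate = acc / iter)
}

#' Fit the Bayesian interim model
#'
#' Bayesian version of the logistic analysis model, with independent uniform
#' priors on (−`prior_bound`, `prior_bound`) for every coefficient.  Two
#' computation modes are available: a Laplace approximation (normal
#' approximation at the maximum-likelihood estimate, draws truncated to the
#' prior support) and random-walk Metropolis sampling with an adaptively
#' scaled Laplace-shaped proposal.  The fit powers the interim allocation
#' updates of Bayesian adaptive randomisation; the final analysis of every
#' trial remains frequentist.
#'
#' @inheritParams fit_outcome_model
#' @param prior_bound Half-width of the uniform prior support.
#' @param method `"laplace"` or `"mcmc"`.
#' @param draws Number of posterior draws returned.
#' @param iter,burnin Metropolis chain length and burn-in.
#' @param seed Optional seed.
#' @return An object of class `umbrella_posterior` holding a `draws` matrix
#'   (one column per analysis-model coefficient) and the acceptance rate
#'   (for MCMC).
#' @examples
#' des <- trial_design()
#' tr <- run_trial(des, get_scenario("scenario1"), strategy_er(), seed = 1)
#' post <- fit_bayes(tr$patients, draws = 200, seed = 1)
#' range(post$draws)
#' @export
fit_bayes <- function(patients, K = NULL, prior_bound = 10,
                      method = c("laplace", "mcmc"), draws = 1000,
                      iter = 4000, burnin = 1000, seed = NULL) {
  method <- match.arg(method)
  if (nrow(patients) == 0) abort_config("At least one patient record is required.")
  if (!is.null(seed)) set.seed(seed)
  K <- K %||% sum(grepl("^b[0-9]+$", names(patients)))
  profiles <- as.matrix(patients[paste0("b", seq_len(K))])
  X <- build_model_matrix(patients$arm, profiles, K)
  y <- patients$response
  res <- if (method == "laplace") .laplace_posterior(X, y, prior_bound, draws)
         else .metropolis_posterior(X, y, prior_bound, iter, burnin, draws)
  structure(
    list(draws = res$draws, method = method, accept_rate = res$accept_rate,
         prior_bound = prior_bound, K = K, n = nrow(patients)),
    class = "umbrella_posterior"
  )
}

#' @export
print.umbrella_posterior <- function(x, ...) {
  cat("<umbrella_posterior> ", x$method, ", ", nrow(x$draws), " draws, ",
      x$n, " patients, prior U(-", x$prior_bound, ", ", x$prior_bound, ")\n",
      sep = "")
  if (is.finite(x$accept_rate))
    cat("  Metropolis acceptance rate:", round(x$accept_rate, 3), "\n")
  invisible(x)
}

#' @export
tidy.umbrella_posterior <- function(x, ...) {
  tibble(term = colnames(x$draws),
         estimate = colMeans(x$draws),
         std.error = apply(x$draws, 2, stats::sd))
}

# Linear-predictor coefficient vector for (arm, profile) in analysis-model
# coordinates (delta_kk structurally absent).
.arm_coef_vector <- function(K, arm, profile) {
  terms <- analysis_terms(K)
  v <- setNames(numeric(length(terms)), terms)
  v["alpha"] <- 1
  v[paste0("gamma", seq_len(K))] <- profile
  if (arm > 0) {
    v[paste0("beta", arm)] <- 1
    for (l in setdiff(seq_len(K), arm))
      v[paste0("delta", arm, "_", l)] <- profile[l]
  }
  v
}

#' Posterior probability of being the best arm
#'
#' For each posterior draw, identifies which of the candidate experimental
#' arms maximises the response probability for the given biomarker profile
#' (the response probability is monotone in the linear predictor, so arms
#' are compared on the linear predictor).  Ties within a draw are split
#' equally.  Returns the per-arm win frequencies.
#'
#' @param posterior An `umbrella_posterior`.
#' @param profile 0/1 biomarker vector.
#' @param arms Integer vector of candidate experimental arms (length >= 2).
#' @return Named probability vector over `arms`, summing to 1.
#' @export
posterior_prob_best <- function(posterior, profile, arms) {
  if (length(arms) < 2)
    abort_contract("`posterior_prob_best()` needs at least two candidate arms.")
  K <- posterior$K
  C <- vapply(arms, function(a) .arm_coef_vector(K, a, profile),
              numeric(ncol(posterior$draws)))
  eta <- posterior$draws %*% C
  mx <- apply(eta, 1, max)
  w <- (eta >= mx - 1e-12) * 1
  w <- w / rowSums(w)
  setNames(colMeans(w), paste0("T", arms))
}
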