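# Large balanced synthetic dataset from known coefficients with a zero
# interaction diagonal (the analysis model is then correctly specified).
balanced_dataset <- function(n, alpha = qlogis(0.25),
                             beta = c(0.4, -0.2, 0, 0.3),
                             gamma = c(0.2, 0, -0.3, 0.1),
                             delta = NULL, seed = 1) {
  set.seed(seed)
  K <- 4
  if (is.null(delta)) {
    delta <- matrix(0.15, K, K); diag(delta) <- 0
  }
  profiles <- matrix(rbinom(n * K, 1, 0.5), n,
                     dimnames = list(NULL, paste0("b", 1:K)))
  arms <- sample(0:K, n, replace = TRUE)
  sc <- scenario_spec(alpha, beta, gamma, delta)
  p <- response_probability(sc, arms, profiles)
  dplyr::bind_cols(tibble::tibble(arm = arms, response = rbinom(n, 1, p)),
                   tibble::as_tibble(profiles))
}

test_that("the analysis model has the expected free parameters", {
  expect_equal(n_free_parameters(4), 21L)
  X <- build_model_matrix(c(0, 1, 4), matrix(c(0, 0, 0, 0,
                                               1, 1, 0, 0,
                                               0, 0, 0, 1), 3, 4, byrow = TRUE))
  expect_equal(ncol(X), 21)
  expect_equal(colnames(X)[1:5], c("alpha", "beta1", "beta2", "beta3", "beta4"))
  # diagonal interactions are structurally absent
  expect_false(any(grepl("^delta1_1$|^delta2_2$|^delta3_3$|^delta4_4$",
                         colnames(X))))
  # patient 2: on T1, positive for B1 and B2 -> delta1_2 active
  expect_equal(unname(X[2, "delta1_2"]), 1)
})

test_that("maximum likelihood recovers known coefficients on balanced data", {
  d <- balanced_dataset(2e4, seed = 10)
  fit <- fit_outcome_model(d)
  expect_true(fit$converged)
  expect_false(fit$separation)
  truth <- c(qlogis(0.25), 0.4, -0.2, 0, 0.3, 0.2, 0, -0.3, 0.1)
  est <- fit$coefficients[1:9]
  expect_true(all(abs(est - truth) < 3 * fit$se[1:9]))
})

test_that("degenerate data yields a flagged fit, never an exception", {
  d <- balanced_dataset(300, seed = 11)
  d$response <- 0L
  fit <- fit_outcome_model(d)
  expect_s3_class(fit, "umbrella_fit")
  expect_true(fit$separation)
  tests <- test_hypotheses(fit)
  expect_false(any(tests$reject))
  expect_true(all(tests$flagged))
})

test_that("twenty one-sided hypotheses are tested per trial", {
  d <- balanced_dataset(2000, seed = 12)
  fit <- fit_outcome_model(d)
  tests <- test_hypotheses(fit, level = 0.05)
  expect_equal(nrow(tests), 20)
  expect_equal(nrow(dplyr::distinct(tests, treatment, biomarker)), 20)
  # the linked test (l = k) coincides with the biomarker-negative test
  for (k in 1:4) {
    a <- dplyr::filter(tests, treatment == k, biomarker == 0)
    b <- dplyr::filter(tests, treatment == k, biomarker == k)
    expect_equal(a$statistic, b$statistic)
  }
  # rejection region matches the one-sided p-value inversion
  expect_equal(tests$reject,
               !tests$flagged & tests$p_value < 0.05)
  expect_equal(tests$p_value, pnorm(tests$statistic, lower.tail = FALSE))
  # delta-method estimate equals the coefficient sum
  r <- dplyr::filter(tests, treatment == 1, biomarker == 2)
  expect_equal(r$estimate,
               unname(fit$coefficients["beta1"] + fit$coefficients["delta1_2"]))
})

test_that("tidy and glance expose the fit in broom style", {
  d <- balanced_dataset(1500, seed = 13)
  fit <- fit_outcome_model(d)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 21)
  g <- glance(fit)
  expect_equal(g$n, 1500)
  expect_true(g$converged)
})

test_that("posterior draws honour the uniform prior bounds", {
  d <- balanced_dataset(500, seed = 14)
  post_l <- fit_bayes(d, method = "laplace", draws = 400, seed = 1)
  expect_true(all(abs(post_l$draws) < 10))
  post_m <- fit_bayes(d, method = "mcmc", draws = 300, iter = 1500,
                      burnin = 500, seed = 2)
  expect_true(all(abs(post_m$draws) < 10))
  expect_true(post_m$accept_rate > 0.1 && post_m$accept_rate < 0.7)
  expect_error(fit_bayes(d[0, ]), class = "umbrellasim_config_error")
})

test_that("the posterior agrees with maximum likelihood on large balanced data", {
  d <- balanced_dataset(4000, seed = 15)
  fit <- fit_outcome_model(d)
  post <- fit_bayes(d, method = "mcmc", draws = 1000, iter = 4000,
                    burnin = 1000, seed = 3)
  pm <- colMeans(post$draws)
  psd <- apply(post$draws, 2, sd)
  expect_true(all(abs(pm - fit$coefficients) < 3 * psd))
})

test_that("Laplace and Metropolis best-arm probabilities agree closely", {
  tr <- run_trial(default_design, get_scenario("scenario2"), strategy_er(),
                  seed = 77)
  pl <- fit_bayes(tr$patients, method = "laplace", draws = 5000, seed = 4)
  pmcmc <- fit_bayes(tr$patients, method = "mcmc", draws = 4000, iter = 20000,
                     burnin = 4000, seed = 5)
  for (pr in list(c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 0, 0))) {
    arms <- setdiff(eligible_arms(pr, 4), 0)
    a <- posterior_prob_best(pl, pr, arms)
    b <- posterior_prob_best(pmcmc, pr, arms)
    expect_lt(max(abs(a - b)), 0.05)
  }
})

test_that("best-arm win frequencies count draws, splitting ties", {
  # arm 1 better in 600 of 1000 draws
  d <- zero_draws(n = 1000)
  d[, "beta1"] <- c(rep(1, 600), rep(-1, 400))
  d[, "beta2"] <- 0
  post <- fake_posterior(d)
  expect_equal(unname(posterior_prob_best(post, c(1, 1, 0, 0), c(1, 2))),
               c(0.6, 0.4))
  # dominance
  post2 <- fake_posterior(zero_draws(n = 50, overrides = list(beta1 = 4)))
  expect_equal(unname(posterior_prob_best(post2, c(1, 1, 0, 0), c(1, 2))),
               c(1, 0))
  # exchangeable posterior: ties split equally
  post3 <- fake_posterior(zero_draws(n = 50))
  expect_equal(unname(posterior_prob_best(post3, c(1, 1, 1, 0), c(1, 2, 3))),
               rep(1 / 3, 3))
})
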