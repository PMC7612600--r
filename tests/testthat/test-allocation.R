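test_that("single-biomarker patients are split 50:50 with the linked arm", {
  expect_equal(single_biomarker_probs(c(0, 1, 0, 0)),
               c(T0 = 0.5, T1 = 0, T2 = 0.5, T3 = 0, T4 = 0))
  expect_equal(single_biomarker_probs(c(1, 0, 0, 0)),
               c(T0 = 0.5, T1 = 0.5, T2 = 0, T3 = 0, T4 = 0))
  expect_error(single_biomarker_probs(c(1, 1, 0, 0)),
               class = "umbrellasim_contract_error")
})

test_that("equal randomisation is uniform over eligible arms", {
  expect_equal(unname(er_probs(c(0, 1, 2), K = 4)),
               c(1, 1, 1, 0, 0) / 3)
  expect_equal(unname(er_probs(0:4, K = 4)), rep(0.2, 5))
  expect_equal(unname(er_probs(c(0, 1), K = 4)), c(0.5, 0.5, 0, 0, 0))
  expect_error(er_probs(integer(0), K = 4),
               class = "umbrellasim_contract_error")
})

test_that("fixed-control randomisation gives theta to control and splits the rest", {
  expect_equal(unname(rfac_probs(c(0, 1, 2), theta = 0.3, K = 4)),
               c(0.3, 0.35, 0.35, 0, 0))
  expect_equal(unname(rfac_probs(0:4, theta = 0.2, K = 4)), rep(0.2, 5))
  expect_error(rfac_probs(c(0, 1), theta = 1.0, K = 4),
               class = "umbrellasim_config_error")
})

test_that("hierarchy randomisation follows the marginalised two-stage rule", {
  expect_equal(hierarchy_probs(c(1, 1, 0, 0), rho = 0.9),
               c(T0 = 0.5, T1 = 0.45, T2 = 0.05, T3 = 0, T4 = 0))
  p <- hierarchy_probs(c(0, 1, 1, 1), rho = 0.75)
  expect_equal(unname(p),
               c(0.75 / 2 + 0.25 / 3, 0, 0.375, 0.25 / 3, 0.25 / 3))
  # complete belief degenerates to the top-ranked positive arm
  expect_equal(hierarchy_probs(c(1, 0, 1, 0), rho = 1),
               c(T0 = 0.5, T1 = 0.5, T2 = 0, T3 = 0, T4 = 0))
  expect_error(hierarchy_probs(c(1, 0, 0, 0), rho = 0.9),
               class = "umbrellasim_contract_error")
  # rho = 0.5 with two positives is symmetric in the two arms
  p5 <- hierarchy_probs(c(0, 1, 0, 1), rho = 0.5)
  expect_equal(p5[["T2"]], p5[["T4"]])
  # a non-identity ordering promotes the higher-ranked biomarker
  p_ord <- hierarchy_probs(c(1, 1, 0, 0), rho = 0.9, order = c(2, 1, 3, 4))
  expect_equal(p_ord[["T2"]], 0.45)
})

test_that("constrained randomisation prioritises the lagging arm", {
  cnt <- c(10, 12, 0, 5, 0)
  expect_equal(cr_probs(c(1, 0, 1, 0), cnt, phi = 0.75),
               c(T0 = 0.5, T1 = 0.125, T2 = 0, T3 = 0.375, T4 = 0))
  expect_equal(cr_probs(c(1, 0, 1, 0), cnt, phi = 1),
               c(T0 = 0.5, T1 = 0, T2 = 0, T3 = 0.5, T4 = 0))
  expect_equal(cr_probs(c(1, 0, 1, 0), c(10, 7, 0, 7, 0), phi = 0.75),
               c(T0 = 0.5, T1 = 0.25, T2 = 0, T3 = 0.25, T4 = 0))
  expect_error(cr_probs(c(1, 0, 0, 0), cnt, phi = 0.75),
               class = "umbrellasim_contract_error")
})

test_that("arm-balance constrained randomisation targets the least-accrued arm", {
  p <- cr_probs(c(1, 1, 0, 0), c(10, 2, 9, 0, 0), phi = 0.9,
                mode = "arm_balance")
  expect_equal(p[["T1"]], 0.9)
  expect_equal(p[["T0"]], 0.05)
  expect_equal(p[["T2"]], 0.05)
})

test_that("adaptive randomisation starts equal and then follows the posterior", {
  des <- default_design
  bar <- strategy_bar()
  # before the first interim: equal randomisation for every profile
  expect_equal(bar_probs(c(1, 1, 0, 0), NULL, stage = 0, bar, des),
               er_probs(c(0, 1, 2), K = 4))
  # single-biomarker patients stay on the 50:50 rule at every stage
  post <- fake_posterior(zero_draws(overrides = list(beta1 = 5)))
  expect_equal(bar_probs(c(0, 1, 0, 0), post, stage = 3, bar, des),
               single_biomarker_probs(c(0, 1, 0, 0)))
  # a point-mass posterior sends all experimental mass to the winning arm
  expect_equal(bar_probs(c(1, 1, 0, 0), post, stage = 1, bar, des),
               c(T0 = 1 / 3, T1 = 2 / 3, T2 = 0, T3 = 0, T4 = 0))
  # degenerate posterior falls back to equal randomisation with a warning
  bar0 <- strategy_bar(tuning_power = 1)
  degen <- fake_posterior(zero_draws(overrides = list(beta1 = NaN)))
  expect_warning(
    p <- bar_probs(c(1, 1, 0, 0), degen, stage = 1, bar0, des),
    class = "umbrellasim_bar_fallback")
  expect_equal(p, er_probs(c(0, 1, 2), K = 4))
  expect_warning(
    p2 <- bar_probs(c(1, 1, 0, 0), NULL, stage = 2, bar0, des),
    class = "umbrellasim_bar_fallback")
  expect_equal(p2, er_probs(c(0, 1, 2), K = 4))
})

test_that("drawn arms follow the allocation distribution", {
  set.seed(1)
  expect_equal(draw_arm(c(T0 = 1, T1 = 0, T2 = 0, T3 = 0, T4 = 0)), 0L)
  draws <- replicate(1e4, draw_arm(c(T0 = 0.5, T1 = 0.5, T2 = 0, T3 = 0, T4 = 0)))
  expect_lt(abs(mean(draws == 1) - 0.5), 3 * sqrt(0.25 / 1e4))
  set.seed(42); a <- draw_arm(c(T0 = 0.3, T1 = 0.7, T2 = 0, T3 = 0, T4 = 0))
  set.seed(42); b <- draw_arm(c(T0 = 0.3, T1 = 0.7, T2 = 0, T3 = 0, T4 = 0))
  expect_identical(a, b)
  expect_error(draw_arm(c(T0 = 0.7, T1 = 0.7)),
               class = "umbrellasim_contract_error")
})

test_that("every strategy yields a valid distribution supported on eligible arms", {
  des <- default_design
  pm <- umbrellasim:::profile_matrix(4)
  post <- fake_posterior(zero_draws(n = 50, overrides = list(beta2 = 1)))
  set.seed(99)
  for (nm in names(all_strategies())) {
    strat <- all_strategies()[[nm]]
    for (r in seq_len(nrow(pm))) {
      pr <- pm[r, ]
      counts <- c(sample(0:20, 1), sample(0:20, 4, replace = TRUE))
      p <- allocation_probs(strat, pr, des, counts = counts,
                            posterior = post, stage = 2)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-12)
      elig <- eligible_arms(pr, 4, des$negative_policy)
      expect_true(all((which(p > 0) - 1L) %in% elig),
                  label = paste(nm, "support for profile", r))
    }
  }
})

test_that("all strategies coincide for single-biomarker patients", {
  des <- default_design
  post <- fake_posterior(zero_draws(n = 20, overrides = list(beta1 = 3)))
  singles <- diag(4)
  for (r in 1:4) {
    pr <- singles[r, ]
    expected <- single_biomarker_probs(pr)
    for (strat in all_strategies()) {
      p <- allocation_probs(strat, pr, des, counts = c(5, 4, 3, 2, 1),
                            posterior = post, stage = 3)
      expect_equal(p, expected, label = strat$name)
    }
  }
})

test_that("equal-count constrained randomisation mirrors the rho = 0.5 hierarchy", {
  p <- cr_probs(c(1, 1, 0, 0), c(0, 0, 0, 0, 0), phi = 0.75)
  expect_equal(p, c(T0 = 0.5, T1 = 0.25, T2 = 0.25, T3 = 0, T4 = 0))
})
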