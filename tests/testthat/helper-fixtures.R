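# Shared fixtures: the default four-biomarker design, a small fast design
# for loop-heavy checks, and a posterior object with known draws.

default_design <- trial_design()

small_design <- trial_design(n_max = 80, interims = c(30, 55))

null_scenario <- get_scenario("scenario1")

# Scenario with a single linked interaction of chosen size.
linked_scenario <- function(d11 = 2.1, K = 4, alpha = qlogis(0.2)) {
  delta <- matrix(0, K, K)
  delta[1, 1] <- d11
  scenario_spec(alpha, rep(0, K), rep(0, K), delta,
                label = "linked interaction", name = "linked")
}

# Posterior stub with draws supplied directly, for oracle checks.
fake_posterior <- function(draws, K = 4) {
  structure(list(draws = draws, method = "stub", accept_rate = NA_real_,
                 prior_bound = 10, K = K, n = nrow(draws)),
            class = "umbrella_posterior")
}

# Draw matrix with every coefficient zero except named overrides.
zero_draws <- function(n = 100, K = 4, overrides = list()) {
  terms <- umbrellasim:::analysis_terms(K)
  d <- matrix(0, n, length(terms), dimnames = list(NULL, terms))
  for (nm in names(overrides)) d[, nm] <- overrides[[nm]]
  d
}

all_strategies <- function() {
  list(ER = strategy_er(),
       RFAC = strategy_rfac(theta = 0.25),
       HIER = strategy_hier(rho = 0.75),
       CR = strategy_cr(phi = 0.75),
       BAR = strategy_bar(draws = 100))
}
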