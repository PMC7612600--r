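# Allocation probability matrix over all 2^K profiles for strategies whose
# distribution depends on the profile only (ER, RFAC, HIER).  Lets whole
# trials be simulated without a per-patient loop.
.profile_prob_matrix <- function(strategy, design) {
  pm <- profile_matrix(design$K)
  t(apply(pm, 1, function(pr) .strategy_probs(strategy, pr, design)))
}

#' Simulate a single umbrella trial
#'
#' Enrols `n_max` patients one at a time: samples a biomarker profile,
#' computes the allocation distribution under the strategy (using current
#' accrual counts for constrained randomisation and the latest interim
#' posterior for Bayesian adaptive randomisation), draws the arm, and
#' samples the binary response immediately.  For Bayesian adaptive
#' randomisation the Bayesian model is refitted each time enrolment crosses
#' an interim threshold; the other strategies perform no interim analysis.
#' The final analysis is always the frequentist fit plus the `K(K + 1)`
#' one-sided Wald tests.
#'
#' @param design A [trial_design()].
#' @param scenario A [scenario_spec()].
#' @param strategy An [allocation_strategies] object.
#' @param seed Optional integer seed; a fixed seed reproduces the trial
#'   exactly.
#' @param analyze Fit the analysis model and run the hypothesis tests
#'   (disable for allocation-only studies).
#' @param detail Keep the per-patient tibble (disable inside large
#'   replication loops).
#' @return An object of class `umbrella_trial` with elements `patients`
#'   (tibble: patient, biomarker indicators, stage, arm, true_p, response,
#'   on_best, multi_eligible), `fit`, `tests`, `arm_counts`,
#'   `response_counts`, `prop_experimental`, `prop_best`, `stage_best`,
#'   `n_interim_fits` and `flags`.
#' @examples
#' tr <- run_trial(trial_design(), get_scenario("scenario2"),
#'                 strategy_er(), seed = 42)
#' tr$arm_counts
#' dplyr::filter(tr$tests, reject)
#' @export
run_trial <- function(design, scenario, strategy, seed = NULL,
                      analyze = TRUE, detail = TRUE) {
  if (!inherits(design, "trial_design")) abort_config("`design` must be a trial_design.")
  if (!inherits(scenario, "scenario_spec")) abort_config("`scenario` must be a scenario_spec.")
  if (!inherits(strategy, "allocation_strategy")) abort_config("`strategy` must be an allocation_strategy.")
  if (scenario$K != design$K) abort_config("Scenario and design disagree on K.")
  if (!is.null(seed)) set.seed(seed)
  K <- design$K
  N <- design$n_max
  profiles <- .sample_profile_matrix(N, design$prevalences)
  pid <- profile_id(profiles)
  stage_vec <- findInterval(seq_len(N) - 1L, design$interims)
  n_fits <- 0L
  bar_fallbacks <- 0L

  if (!strategy$state_dependent) {
    P <- .profile_prob_matrix(strategy, design)
    cum <- t(apply(P, 1, cumsum))
    u <- runif(N)
    arms <- as.integer(rowSums(u > cum[pid, , drop = FALSE]))
    true_p <- response_probability(scenario, arms, profiles)
    y <- sample_response(true_p)
  } else {
    counts <- integer(K + 1)
    arms <- integer(N)
    y <- integer(N)
    true_p <- numeric(N)
    posterior <- NULL
    cur_stage <- 0L
    cache <- vector("list", 2^K)
    is_bar <- inherits(strategy, "strategy_bar")
    for (i in seq_len(N)) {
      if (is_bar && stage_vec[i] > cur_stage) {
        idx <- seq_len(i - 1L)
        posterior <- tryCatch(
          fit_bayes(tibble(arm = arms[idx], response = y[idx]) |>
                      dplyr::bind_cols(as_tibble(profiles[idx, , drop = FALSE])),
                    K = K, prior_bound = strategy$prior_bound,
                    method = strategy$method, draws = strategy$draws,
                    iter = strategy$iter, burnin = strategy$burnin),
          error = function(e) NULL)
        n_fits <- n_fits + 1L
        cur_stage <- stage_vec[i]
        cache <- vector("list", 2^K)
      }
      pr <- profiles[i, ]
      if (is_bar) {
        p <- cache[[pid[i]]]
        if (is.null(p)) {
          p <- withCallingHandlers(
            .strategy_probs(strategy, pr, design, posterior = posterior,
                            stage = cur_stage),
            umbrellasim_bar_fallback = function(w) {
              bar_fallbacks <<- bar_fallbacks + 1L
              rlang::cnd_muffle(w)
            })
          cache[[pid[i]]] <- p
        }
      } else {
        p <- .strategy_probs(strategy, pr, design, counts = counts)
      }
      a <- sample.int(K + 1L, 1L, prob = p) - 1L
      arms[i] <- a
      counts[a + 1L] <- counts[a + 1L] + 1L
      true_p[i] <- response_probability(scenario, a, matrix(pr, nrow = 1))
      y[i] <- rbinom(1L, 1L, true_p[i])
    }
  }

  pm <- profile_matrix(K)
  bas <- best_arm_sets(scenario, design)
  Bmat <- matrix(FALSE, nrow(pm), K + 1)
  for (r in seq_len(nrow(pm)))
    if (bas[[r]]$informative) Bmat[r, bas[[r]]$set + 1] <- TRUE
  on_best <- Bmat[cbind(pid, arms + 1L)]
  any_informative <- any(vapply(bas, `[[`, logical(1), "informative"))
  me_profile <- vapply(seq_len(nrow(pm)), function(r) {
    length(eligible_arms(pm[r, ], K, design$negative_policy)) >= 3
  }, logical(1))
  multi_eligible <- me_profile[pid]

  arm_counts <- setNames(tabulate(arms + 1L, K + 1L), arm_names(K))
  response_counts <- setNames(
    vapply(0:K, function(a) sum(y[arms == a]), numeric(1)), arm_names(K))

  n_stages <- length(design$interims)
  stage_best <- vapply(0:n_stages, function(s) {
    sel <- multi_eligible & stage_vec == s
    if (!any(sel) || !any_informative) NA_real_ else mean(on_best[sel])
  }, numeric(1))
  names(stage_best) <- paste0("stage", 0:n_stages)

  fit <- NULL
  tests <- NULL
  if (analyze) {
    X <- build_model_matrix(arms, profiles, K)
    fit <- .fit_glm(X, y)
    fit$K <- K
    class(fit) <- "umbrella_fit"
    tests <- test_hypotheses(fit, design$test_level)
  }

  patients <- NULL
  if (detail) {
    patients <- dplyr::bind_cols(
      tibble(patient = seq_len(N)),
      as_tibble(profiles),
      tibble(stage = stage_vec, arm = arms, true_p = true_p, response = y,
             on_best = on_best, multi_eligible = multi_eligible))
  }

  structure(
    list(patients = patients, fit = fit, tests = tests,
         arm_counts = arm_counts, response_counts = response_counts,
         prop_experimental = mean(arms > 0),
         prop_best = if (any_informative) mean(on_best) else NA_real_,
         stage_best = stage_best,
         n_interim_fits = n_fits,
         flags = list(
           separation = if (analyze) fit$separation else NA,
           converged = if (analyze) fit$converged else NA,
           rank_deficient = if (analyze) fit$rank_deficient else NA,
           bar_fallbacks = bar_fallbacks),
         design = design, scenario = scenario, strategy = strategy,
         seed = seed),
    class = "umbrella_trial")
}

#' @export
print.umbrella_trial <- function(x, ...) {
  cat("<umbrella_trial> ", x$strategy$name, " / ", x$scenario$name, ", N = ",
      sum(x$arm_counts), "\n", sep = "")
  print(x$arm_counts)
  cat("  proportion on experimental arms:", round(x$prop_experimental, 3), "\n")
  if (!is.null(x$tests))
    cat("  hypotheses rejected:", sum(x$tests$reject), "of", nrow(x$tests), "\n")
  invisible(x)
}

#' Replicate a trial and aggregate operating characteristics
#'
#' Runs `reps` independent trials (replicate `r` is seeded deterministically
#' from `(seed, r)`, so results are reproducible under any execution order)
#' and aggregates the operating characteristics of the design: per-hypothesis
#' rejection rates (power where the null is false under the generating
#' scenario, type I error where it is true), allocation and response
#' summaries per arm, the proportion of patients on experimental arms and on
#' their best available arm, and bias/MSE of the configured estimand.
#'
#' The default estimand is the linked-subgroup effect estimate for
#' treatment 1 in the biomarker-1 population: the analysis model's
#' `beta_1` (its `delta_11` is structurally zero), compared against the
#' generating value `beta_1 + delta_11`.  Replicates whose fit was flagged
#' (separation or non-convergence) are excluded from bias/MSE.
#'
#' @inheritParams run_trial
#' @param reps Number of replicate trials.
#' @param seed Base seed.
#' @param estimand Length-2 integer vector `c(k, l)` selecting the
#'   hypothesis estimate tracked for bias/MSE.
#' @return An object of class `umbrella_study`; see [tidy.umbrella_study()]
#'   and [glance.umbrella_study()].
#' @examples
#' st <- run_study(trial_design(), get_scenario("scenario1"), strategy_er(),
#'                 reps = 20, seed = 1)
#' glance(st)
#' @export
run_study <- function(design, scenario, strategy, reps = 1000, seed = 1,
                      estimand = c(1, 1), analyze = TRUE) {
  if (reps < 1) abort_config("`reps` must be at least 1.")
  K <- design$K
  H <- K * (K + 1)
  reject <- matrix(NA, reps, H)
  flagged_any <- logical(reps)
  est <- rep(NA_real_, reps)
  prop_exp <- numeric(reps)
  prop_best <- rep(NA_real_, reps)
  arm_counts <- matrix(0, reps, K + 1)
  resp_counts <- matrix(0, reps, K + 1)
  stage_best <- matrix(NA_real_, reps, length(design$interims) + 1)
  bar_fallbacks <- 0L

  for (r in seq_len(reps)) {
    tr <- run_trial(design, scenario, strategy, seed = derive_seed(seed, r),
                    analyze = analyze, detail = FALSE)
    if (analyze) {
      reject[r, ] <- tr$tests$reject
      flagged_any[r] <- tr$fit$separation || !tr$fit$converged
      row <- which(tr$tests$treatment == estimand[1] &
                     tr$tests$biomarker == estimand[2])
      if (!tr$tests$flagged[row]) est[r] <- tr$tests$estimate[row]
    }
    prop_exp[r] <- tr$prop_experimental
    prop_best[r] <- tr$prop_best
    arm_counts[r, ] <- tr$arm_counts
    resp_counts[r, ] <- tr$response_counts
    stage_best[r, ] <- tr$stage_best
    bar_fallbacks <- bar_fallbacks + tr$flags$bar_fallbacks
  }

  truth <- hypothesis_truth(scenario)
  rejections <- NULL
  bias <- mse <- NA_real_
  n_est <- 0L
  if (analyze) {
    rate <- colMeans(reject)
    rejections <- dplyr::mutate(truth,
      rate = rate,
      mc_se = sqrt(rate * (1 - rate) / reps))
    true_val <- scenario$beta[estimand[1]] +
      if (estimand[2] > 0) scenario$delta[estimand[1], estimand[2]] else 0
    ok <- !is.na(est)
    n_est <- sum(ok)
    if (n_est > 0) {
      bias <- mean(est[ok] - true_val)
      mse <- mean((est[ok] - true_val)^2)
    }
  }

  allocation <- tibble(
    arm = arm_names(K),
    mean_n = colMeans(arm_counts),
    mean_responses = colMeans(resp_counts),
    response_rate = colMeans(resp_counts) / pmax(colMeans(arm_counts), 1e-12))

  summary <- tibble(
    strategy = strategy$name, scenario = scenario$name,
    reps = reps, seed = seed,
    prop_experimental = mean(prop_exp),
    prop_experimental_se = stats::sd(prop_exp) / sqrt(reps),
    prop_experimental_min = min(prop_exp),
    prop_experimental_max = max(prop_exp),
    prop_best = if (all(is.na(prop_best))) NA_real_ else mean(prop_best, na.rm = TRUE),
    exp_accrual_range = mean(apply(arm_counts[, -1, drop = FALSE], 1,
                                   function(z) max(z) - min(z))),
    bias = bias, mse = mse, estimand_n = n_est,
    flagged = sum(flagged_any), bar_fallbacks = bar_fallbacks)

  structure(
    list(rejections = rejections, allocation = allocation, summary = summary,
         stage_best = tibble(
           stage = 0:length(design$interims),
           prop_best_multi = colMeans(stage_best, na.rm = TRUE),
           n_reps = colSums(!is.na(stage_best))),
         estimand = estimand,
         design = design, scenario = scenario, strategy = strategy),
    class = "umbrella_study")
}

#' @export
print.umbrella_study <- function(x, ...) {
  cat("<umbrella_study> ", x$strategy$name, " / ", x$scenario$name, ", ",
      x$summary$reps, " replicates\n", sep = "")
  cat("  proportion on experimental arms:",
      sprintf("%.1f%% (%.1f-%.1f)", 100 * x$summary$prop_experimental,
              100 * x$summary$prop_experimental_min,
              100 * x$summary$prop_experimental_max), "\n")
  if (!is.null(x$rejections)) {
    key <- dplyr::filter(x$rejections, .data$treatment == 1,
                         .data$biomarker %in% 1:2)
    cat("  rejection rate H0(1,1):", sprintf("%.2f%%", 100 * key$rate[1]),
        " H0(1,2):", sprintf("%.2f%%", 100 * key$rate[2]), "\n")
  }
  invisible(x)
}

#' Tidy per-hypothesis rates of a study
#'
#' @param x An `umbrella_study`.
#' @param ... Unused.
#' @return A tibble with one row per hypothesis: treatment, biomarker
#'   population, the true generating effect, whether the null holds,
#'   the Monte-Carlo rejection rate and its standard error.
#' @export
tidy.umbrella_study <- function(x, ...) {
  if (is.null(x$rejections))
    return(tibble(treatment = integer(), biomarker = integer(),
                  true_effect = numeric(), h0_true = logical(),
                  rate = numeric(), mc_se = numeric()))
  x$rejections
}

#' One-row summary of a study
#'
#' @inheritParams tidy.umbrella_study
#' @return A one-row tibble with allocation proportions, bias/MSE of the
#'   estimand, and bookkeeping counts.
#' @export
glance.umbrella_study <- function(x, ...) x$summary

#' Rejection rate of one hypothesis
#'
#' @param study An `umbrella_study`.
#' @param treatment,biomarker Hypothesis indices (`biomarker = 0` is the
#'   biomarker-negative population).
#' @return Scalar Monte-Carlo rejection rate.
#' @export
rejection_rate <- function(study, treatment = 1, biomarker = 1) {
  r <- dplyr::filter(study$rejections, .data$treatment == !!treatment,
                     .data$biomarker == !!biomarker)
  r$rate
}

#' Expected proportion of patients on experimental arms
#'
#' Exact expectation over the `2^K` biomarker profiles (weighted by
#' [profile_probability()]) of the probability mass a strategy places on
#' experimental arms.  Available in closed form for equal randomisation and
#' fixed-control-probability randomisation only; the state-dependent and
#' adaptive strategies have no profile-wise closed form and raise an error.
#'
#' @param strategy A `strategy_er()` or `strategy_rfac()` object.
#' @param design A [trial_design()].
#' @return Expected experimental-arm proportion (0-1 scale).
#' @examples
#' expected_exp_proportion(strategy_er(), trial_design()) # 0.639167
#' @export
expected_exp_proportion <- function(strategy, design = trial_design()) {
  if (!inherits(strategy, c("strategy_er", "strategy_rfac")))
    abort(paste0("Closed-form experimental proportion is unsupported for `",
                 strategy$name, "`."),
          class = "umbrellasim_unsupported_error")
  pm <- profile_matrix(design$K)
  w <- profile_probability(pm, design$prevalences)
  pe <- apply(pm, 1, function(pr) {
    1 - .strategy_probs(strategy, pr, design)[1]
  })
  sum(w * pe)
}

#' Power sweep over sample size or biomarker prevalence
#'
#' Re-estimates the rejection rate of the linked hypothesis `H0(1, 1)` for
#' each strategy over a grid of either maximum sample sizes or biomarker-1
#' prevalences, holding everything else at the supplied design.
#'
#' @param design Base [trial_design()].
#' @param scenario Generating [scenario_spec()].
#' @param strategies Named list of [allocation_strategies] objects.
#' @param axis `"n_max"` or `"prevalence1"`.
#' @param values Grid of axis values.
#' @param reps Replicates per grid point and strategy.
#' @param seed Base seed.
#' @return A tibble of class `umbrella_sweep`: axis, value, strategy, power,
#'   mc_se.
#' @examples
#' \donttest{
#' sw <- sweep_power(trial_design(), get_scenario("scenario2"),
#'                   list(ER = strategy_er()), axis = "n_max",
#'                   values = c(200, 400), reps = 50, seed = 1)
#' autoplot(sw)
#' }
#' @export
sweep_power <- function(design, scenario, strategies,
                        axis = c("n_max", "prevalence1"), values,
                        reps = 500, seed = 1) {
  axis <- match.arg(axis)
  if (is.null(names(strategies)))
    names(strategies) <- vapply(strategies, `[[`, character(1), "name")
  grid <- tidyr::expand_grid(value = values, strategy = names(strategies))
  rows <- purrr::pmap(
    dplyr::mutate(grid, idx = dplyr::row_number()),
    function(value, strategy, idx) {
      des <- design
      if (axis == "n_max") {
        interims <- des$interims[des$interims < value]
        des <- trial_design(des$K, des$prevalences, value, interims,
                            des$test_level, des$negative_policy)
      } else {
        prev <- des$prevalences
        prev[1] <- value
        des <- trial_design(des$K, prev, des$n_max, des$interims,
                            des$test_level, des$negative_policy)
      }
      st <- run_study(des, scenario, strategies[[strategy]], reps = reps,
                      seed = derive_seed(seed, idx * 100003))
      r <- dplyr::filter(st$rejections, .data$treatment == 1, .data$biomarker == 1)
      tibble(axis = axis, value = value, strategy = strategy,
             power = r$rate, mc_se = r$mc_se)
    })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("umbrella_sweep", class(out))
  out
}
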