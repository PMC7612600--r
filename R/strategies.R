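new_strategy <- function(name, subclass, state_dependent, adaptive, params) {
  structure(
    c(list(name = name), params,
      list(state_dependent = state_dependent, adaptive = adaptive)),
    class = c(subclass, "allocation_strategy")
  )
}

#' Allocation strategies for multi-eligible patients
#'
#' Constructors for the five treatment-allocation strategies compared by the
#' simulator.  Patients positive for exactly one biomarker are randomised
#' 50:50 between control and the linked treatment under every strategy (the
#' only exception being `strategy_rfac(scope = "all_patients")`, which applies
#' the fixed control probability to everyone).  The strategies differ in how
#' they treat patients eligible for two or more experimental arms:
#'
#' * `strategy_er()` — equal randomisation: uniform over all eligible arms
#'   (control included).
#' * `strategy_rfac()` — fixed control probability: control receives `theta`,
#'   the remainder is split equally across eligible experimental arms.  With
#'   `scope = "multi_and_negative"` (default) the rule applies only to
#'   multi-eligible patients; `"all_patients"` applies it to every patient,
#'   which makes the expected experimental share exactly `1 - theta`.
#' * `strategy_hier()` — biomarker hierarchy: with belief probability `rho`
#'   the patient is randomised 50:50 between control and the arm linked to
#'   their highest-ranked positive biomarker; with probability `1 - rho` they
#'   are randomised equally between control and the remaining eligible
#'   experimental arms.  `rho = 1` is complete belief in the hierarchy.
#'   All-negative patients are treated as positive for every biomarker
#'   (`negative = "hierarchy"`) or randomised uniformly (`negative = "er"`).
#' * `strategy_cr()` — constrained randomisation: with probability `phi` the
#'   currently least-accrued eligible experimental arm is randomised 1:1
#'   against control; with probability `1 - phi` one of the other eligible
#'   experimental arms (chosen uniformly) is.  Ties on minimal accrual break
#'   uniformly.  `mode = "arm_balance"` instead sends mass `phi` directly to
#'   the least-accrued arm among all eligible arms including control, which
#'   actively balances per-arm accrual and pushes the experimental share
#'   towards `1 - 1/(K + 1)`.
#' * `strategy_bar()` — Bayesian adaptive randomisation: starts as equal
#'   randomisation, then after each interim analysis gives control a share of
#'   `1/(m + 1)` (for `m` eligible experimental arms) and splits the
#'   experimental mass proportionally to the posterior probability that each
#'   arm maximises the patient's response probability, raised to
#'   `tuning_power`.  The interim posterior is a Bayesian logistic regression
#'   with independent uniform priors on (−`prior_bound`, `prior_bound`),
#'   fitted either by Laplace approximation (`method = "laplace"`, fast) or
#'   random-walk Metropolis (`method = "mcmc"`).
#'
#' @param theta Control-allocation probability, strictly in (0, 1).
#' @param scope Which patients the fixed-control rule applies to.
#' @param rho Hierarchy belief probability in \[0.5, 1\].
#' @param order Permutation of `1:K` giving the biomarker importance ranking
#'   (most important first); `NULL` means the identity ordering.
#' @param negative All-negative patient handling for the hierarchy rule.
#' @param phi Lagging-arm priority probability in \[0.5, 1\].
#' @param mode Constrained-randomisation variant, see above.
#' @param control_share Control probability for adaptive patients; `NULL`
#'   (default) uses `1/(m + 1)`, otherwise a fixed probability in (0, 1).
#' @param tuning_power Non-negative exponent applied to posterior best-arm
#'   probabilities before renormalisation (0 recovers equal experimental
#'   shares, larger values are greedier).
#' @param adaptive_scope `"multi_eligible"` adapts every patient with at
#'   least two eligible experimental arms (all-negative patients included);
#'   `"multi_positive"` restricts adaptation to multi-positive patients.
#' @param method Posterior computation mode for interim fits.
#' @param draws Number of posterior draws used for best-arm probabilities.
#' @param iter,burnin Metropolis chain length and burn-in (`method = "mcmc"`).
#' @param prior_bound Half-width of the uniform prior support.
#'
#' @return An object of class `allocation_strategy`.
#' @examples
#' strategy_er()
#' strategy_rfac(theta = 0.2, scope = "all_patients")
#' strategy_hier(rho = 0.9)
#' @name allocation_strategies
NULL

#' @rdname allocation_strategies
#' @export
strategy_er <- function() {
  new_strategy("ER", "strategy_er", FALSE, FALSE, list())
}

#' @rdname allocation_strategies
#' @export
strategy_rfac <- function(theta = 0.2,
                          scope = c("multi_and_negative", "all_patients")) {
  scope <- match.arg(scope)
  if (length(theta) != 1L || !is.finite(theta) || theta <= 0 || theta >= 1)
    abort_config("`theta` must lie strictly in (0, 1).")
  new_strategy("RFAC", "strategy_rfac", FALSE, FALSE,
               list(theta = theta, scope = scope))
}

#' @rdname allocation_strategies
#' @export
strategy_hier <- function(rho = 0.9, order = NULL,
                          negative = c("hierarchy", "er")) {
  negative <- match.arg(negative)
  if (length(rho) != 1L || !is.finite(rho) || rho < 0.5 || rho > 1)
    abort_config("`rho` must lie in [0.5, 1].")
  if (!is.null(order) && !setequal(order, seq_along(order)))
    abort_config("`order` must be a permutation of 1:K.")
  new_strategy("HIER", "strategy_hier", FALSE, FALSE,
               list(rho = rho, order = order, negative = negative))
}

#' @rdname allocation_strategies
#' @export
strategy_cr <- function(phi = 0.75, mode = c("control_paired", "arm_balance")) {
  mode <- match.arg(mode)
  if (length(phi) != 1L || !is.finite(phi) || phi < 0.5 || phi > 1)
    abort_config("`phi` must lie in [0.5, 1].")
  new_strategy("CR", "strategy_cr", TRUE, FALSE,
               list(phi = phi, mode = mode))
}

#' @rdname allocation_strategies
#' @export
strategy_bar <- function(control_share = NULL, tuning_power = 1,
                         adaptive_scope = c("multi_eligible", "multi_positive"),
                         method = c("laplace", "mcmc"), draws = 1000,
                         iter = 4000, burnin = 1000, prior_bound = 10) {
  adaptive_scope <- match.arg(adaptive_scope)
  method <- match.arg(method)
  if (!is.null(control_share) &&
      (control_share <= 0 || control_share >= 1))
    abort_config("`control_share` must lie strictly in (0, 1) or be NULL.")
  if (tuning_power < 0) abort_config("`tuning_power` must be non-negative.")
  new_strategy("BAR", "strategy_bar", TRUE, TRUE,
               list(control_share = control_share,
                    tuning_power = tuning_power,
                    adaptive_scope = adaptive_scope,
                    method = method, draws = as.integer(draws),
                    iter = as.integer(iter), burnin = as.integer(burnin),
                    prior_bound = prior_bound))
}

#' @export
print.allocation_strategy <- function(x, ...) {
  pars <- switch(x$name,
    RFAC = paste0("theta = ", x$theta, ", scope = ", x$scope),
    HIER = paste0("rho = ", x$rho, ", negative = ", x$negative),
    CR   = paste0("phi = ", x$phi, ", mode = ", x$mode),
    BAR  = paste0("method = ", x$method, ", tuning_power = ", x$tuning_power),
    ""
  )
  cat("<allocation_strategy> ", x$name,
      if (nzchar(pars)) paste0(" (", pars, ")"), "\n", sep = "")
  invisible(x)
}

.zero_probs <- function(K) setNames(numeric(K + 1), arm_names(K))

#' Allocation rule for single-biomarker patients
#'
#' Patients positive for exactly one biomarker are randomised equally between
#' control and the linked experimental arm; this rule is shared by all
#' strategies.
#'
#' @param profile 0/1 biomarker vector with exactly one positive entry.
#' @param K Number of experimental arms.
#' @return Named probability vector over arms `T0 ... TK`.
#' @examples
#' single_biomarker_probs(c(0, 1, 0, 0))
#' @export
single_biomarker_probs <- function(profile, K = length(profile)) {
  if (sum(profile) != 1L)
    abort_contract("`profile` must have exactly one positive biomarker.")
  p <- .zero_probs(K)
  p[1] <- 0.5
  p[which(profile == 1) + 1] <- 0.5
  p
}

#' Equal-randomisation probabilities
#'
#' Uniform distribution over the patient's eligible arms (control included).
#'
#' @param eligible Integer vector of eligible arm indices (must contain 0).
#' @param K Number of experimental arms.
#' @return Named probability vector over arms `T0 ... TK`.
#' @examples
#' er_probs(c(0, 1, 2), K = 4)
#' @export
er_probs <- function(eligible, K) {
  if (length(eligible) == 0 || !0 %in% eligible)
    abort_contract("`eligible` must be non-empty and contain the control arm 0.")
  p <- .zero_probs(K)
  p[eligible + 1] <- 1 / length(eligible)
  p
}

#' Fixed-control-probability randomisation
#'
#' Control receives probability `theta`; the remaining mass is split equally
#' across the eligible experimental arms.
#'
#' @inheritParams er_probs
#' @param theta Control probability, strictly in (0, 1).
#' @return Named probability vector over arms `T0 ... TK`.
#' @examples
#' rfac_probs(c(0, 1, 2), theta = 0.3, K = 4)
#' @export
rfac_probs <- function(eligible, theta, K) {
  if (theta <= 0 || theta >= 1)
    abort_config("`theta` must lie strictly in (0, 1).")
  ex <- setdiff(eligible, 0L)
  if (length(ex) == 0)
    abort_contract("At least one experimental arm must be eligible.")
  p <- .zero_probs(K)
  p[1] <- theta
  p[ex + 1] <- (1 - theta) / length(ex)
  p
}

#' Biomarker-hierarchy randomisation
#'
#' Marginal allocation distribution of the two-stage hierarchy rule for a
#' multi-positive patient: with belief probability `rho`, 50:50 between
#' control and the arm linked to the highest-ranked positive biomarker; with
#' probability `1 - rho`, equal randomisation between control and the
#' remaining eligible experimental arms.
#'
#' @param profile 0/1 biomarker vector with at least two positive entries
#'   (or all-negative when `negative = "hierarchy"`).
#' @param rho Belief probability in \[0.5, 1\].
#' @param order Permutation of `1:K`, most important biomarker first.
#' @param negative All-negative handling (treated as positive for all, or
#'   plain equal randomisation).
#' @return Named probability vector over arms `T0 ... TK`.
#' @examples
#' hierarchy_probs(c(1, 1, 0, 0), rho = 0.9) # T0 0.5, T1 0.45, T2 0.05
#' @export
hierarchy_probs <- function(profile, rho, order = NULL,
                            negative = c("hierarchy", "er")) {
  negative <- match.arg(negative)
  K <- length(profile)
  order <- order %||% seq_len(K)
  if (rho < 0.5 || rho > 1) abort_config("`rho` must lie in [0.5, 1].")
  npos <- sum(profile)
  if (npos == 1L)
    abort_contract("Single-positive patients use `single_biomarker_probs()`.")
  if (npos == 0L) {
    if (negative == "er") return(er_probs(0:K, K))
    profile <- rep(1L, K)
  }
  pos <- which(profile == 1)
  ranked <- order[order %in% pos]
  top <- ranked[1]
  rest <- ranked[-1]
  p <- .zero_probs(K)
  p[1] <- rho / 2 + (1 - rho) / (length(rest) + 1)
  p[top + 1] <- rho / 2
  p[rest + 1] <- (1 - rho) / (length(rest) + 1)
  p
}

#' Constrained randomisation towards under-accrued arms
#'
#' @param profile 0/1 biomarker vector (multi-eligible: at least two eligible
#'   experimental arms, all-negative patients qualify under the `all_arms`
#'   policy).
#' @param counts Named or plain numeric vector of current per-arm accruals
#'   `n_0 ... n_K`.
#' @param phi Priority probability for the least-accrued arm, in \[0.5, 1\].
#' @param mode `"control_paired"` (1:1 with control after the branch choice)
#'   or `"arm_balance"` (mass `phi` straight to the least-accrued arm among
#'   all eligible arms including control).
#' @param negative_policy Eligibility policy for all-negative patients.
#' @return Named probability vector over arms `T0 ... TK`.
#' @examples
#' cr_probs(c(1, 0, 1, 0), counts = c(10, 12, 0, 5, 0), phi = 0.75)
#' @export
cr_probs <- function(profile, counts, phi = 0.75,
                     mode = c("control_paired", "arm_balance"),
                     negative_policy = "all_arms") {
  mode <- match.arg(mode)
  K <- length(profile)
  if (length(counts) != K + 1)
    abort_contract("`counts` must cover all K + 1 arms.")
  if (phi < 0.5 || phi > 1) abort_config("`phi` must lie in [0.5, 1].")
  elig <- eligible_arms(profile, K, negative_policy)
  ex <- setdiff(elig, 0L)
  if (length(ex) < 2)
    abort_contract("Constrained randomisation needs >= 2 eligible experimental arms.")
  # P(arm selected) = phi * 1[arm minimal]/|M| + (1-phi)/(|M|(|A|-1)) *
  #   (|M| - 1[arm minimal]), marginalising the uniform tie-break over the
  #   minimal set M and the uniform choice among the other arms.
  branch_probs <- function(arms, n_arms) {
    in_min <- n_arms == min(n_arms)
    nM <- sum(in_min)
    sel <- (1 - phi) * (nM - in_min) / (nM * (length(arms) - 1))
    sel[in_min] <- sel[in_min] + phi / nM
    sel
  }
  p <- .zero_probs(K)
  if (mode == "control_paired") {
    p[1] <- 0.5
    p[ex + 1] <- 0.5 * branch_probs(ex, counts[ex + 1])
  } else {
    p[elig + 1] <- branch_probs(elig, counts[elig + 1])
  }
  p
}

#' Bayesian adaptive randomisation probabilities
#'
#' Before the first interim (`stage = 0`) every patient is allocated by equal
#' randomisation.  Single-biomarker patients stay on the 50:50 rule at every
#' stage.  From the first interim on, adaptive-scope patients receive a
#' control share of `1/(m + 1)` (or the configured fixed share) and the
#' experimental mass is split proportionally to each arm's posterior
#' probability of maximising the patient's response probability, raised to
#' the strategy's tuning power.  A degenerate posterior (all best-arm
#' probabilities zero, or no posterior available) falls back to equal
#' randomisation with a warning.
#'
#' @param profile 0/1 biomarker vector.
#' @param posterior An `umbrella_posterior` from [fit_bayes()], or `NULL`.
#' @param stage Interim index (0 before the first interim analysis).
#' @param strategy A `strategy_bar()` object holding the tuning parameters.
#' @param design A [trial_design()].
#' @return Named probability vector over arms `T0 ... TK`.
#' @export
bar_probs <- function(profile, posterior, stage,
                      strategy = strategy_bar(), design = trial_design()) {
  K <- design$K
  npos <- sum(profile)
  elig <- eligible_arms(profile, K, design$negative_policy)
  if (length(elig) == 1L) { p <- .zero_probs(K); p[1] <- 1; return(p) }
  if (npos == 1L) return(single_biomarker_probs(profile, K))
  ex <- setdiff(elig, 0L)
  adaptive <- length(ex) >= 2 &&
    (strategy$adaptive_scope == "multi_eligible" || npos >= 2)
  if (stage < 1 || !adaptive) return(er_probs(elig, K))
  fallback <- function(msg) {
    warn(msg, class = "umbrellasim_bar_fallback")
    er_probs(elig, K)
  }
  if (is.null(posterior)) return(fallback("No posterior available; falling back to equal randomisation."))
  pb <- posterior_prob_best(posterior, profile, ex)
  w <- pb^strategy$tuning_power
  if (any(!is.finite(w)) || !any(w > 0))
    return(fallback("Degenerate posterior best-arm probabilities; falling back to equal randomisation."))
  cs <- strategy$control_share %||% (1 / (length(ex) + 1))
  p <- .zero_probs(K)
  p[1] <- cs
  p[ex + 1] <- (1 - cs) * w / sum(w)
  p
}

# Central dispatcher used by the engine: returns the allocation distribution
# for one patient under any strategy, given the current trial state.
.strategy_probs <- function(strategy, profile, design,
                            counts = NULL, posterior = NULL, stage = 0L) {
  K <- design$K
  npos <- sum(profile)
  elig <- eligible_arms(profile, K, design$negative_policy)
  if (length(elig) == 1L) { p <- .zero_probs(K); p[1] <- 1; return(p) }
  if (inherits(strategy, "strategy_bar"))
    return(bar_probs(profile, posterior, stage, strategy, design))
  if (npos == 1L &&
      !(inherits(strategy, "strategy_rfac") && strategy$scope == "all_patients"))
    return(single_biomarker_probs(profile, K))
  if (inherits(strategy, "strategy_er")) return(er_probs(elig, K))
  if (inherits(strategy, "strategy_rfac"))
    return(rfac_probs(elig, strategy$theta, K))
  if (inherits(strategy, "strategy_hier"))
    return(hierarchy_probs(profile, strategy$rho, strategy$order %||% seq_len(K),
                           strategy$negative))
  if (inherits(strategy, "strategy_cr"))
    return(cr_probs(profile, counts, strategy$phi, strategy$mode,
                    design$negative_policy))
  abort_config(paste0("Unknown strategy `", strategy$name, "`."))
}

#' Allocation probabilities for one patient
#'
#' High-level entry point dispatching to the rule of the given strategy,
#' using the current accrual state (constrained randomisation) and interim
#' posterior (Bayesian adaptive randomisation) where relevant.
#'
#' @param strategy An [allocation_strategies] object.
#' @param profile 0/1 biomarker vector.
#' @param design A [trial_design()].
#' @param counts Per-arm accrual counts `n_0 ... n_K` (required for
#'   constrained randomisation).
#' @param posterior Interim posterior (Bayesian adaptive randomisation).
#' @param stage Interim index of the arriving patient.
#' @return Named probability vector over arms `T0 ... TK`.
#' @examples
#' allocation_probs(strategy_er(), c(1, 1, 0, 0), trial_design())
#' @export
allocation_probs <- function(strategy, profile, design,
                             counts = NULL, posterior = NULL, stage = 0L) {
  if (!inherits(strategy, "allocation_strategy"))
    abort_config("`strategy` must be an allocation_strategy object.")
  .strategy_probs(strategy, profile, design, counts, posterior, stage)
}

#' Draw an arm from an allocation distribution
#'
#' @param probs Named probability vector over arms `T0 ... TK`, summing to 1.
#' @return The drawn arm index (0 = control).
#' @examples
#' set.seed(1)
#' draw_arm(c(T0 = 0.5, T1 = 0.5, T2 = 0, T3 = 0, T4 = 0))
#' @export
draw_arm <- function(probs) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    abort_contract("`probs` must be non-negative and sum to 1.")
  sample.int(length(probs), 1L, prob = probs) - 1L
}
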