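#' Calibrate an effect size to a target power
#'
#' Bisection search for the value of one free coefficient of the generating
#' model that gives a target Monte-Carlo power for a chosen hypothesis under
#' a chosen allocation strategy.  Power is a monotone function of the free
#' coefficient, so the search brackets the target between `interval[1]`
#' (which must give power below target) and `interval[2]` (above target) and
#' halves the bracket until the Monte-Carlo estimate at the midpoint is
#' within `tol_se` standard errors of the target or `max_iter` halvings have
#' been performed.
#'
#' @param design A [trial_design()].
#' @param strategy An [allocation_strategies] object.
#' @param template A [scenario_spec()] providing all fixed coefficients.
#' @param coef `"delta"` (free coefficient is `delta[k, l]`) or `"beta"`
#'   (free coefficient is `beta[k]`).
#' @param k,l Indices of the free coefficient and of the tested hypothesis
#'   `H0(k, l)`.
#' @param target_power Target power in (0.5, 0.99).
#' @param reps Monte-Carlo replicates per power evaluation.
#' @param seed Base seed.
#' @param interval Search interval for the free coefficient.
#' @param tol_se Stop when `|power - target|` is below this many Monte-Carlo
#'   standard errors.
#' @param max_iter Maximum bisection steps.
#' @return A list with `value` (calibrated coefficient), `power` (achieved
#'   Monte-Carlo power), `mc_se`, and `trace` (a tibble of evaluations).
#' @examples
#' \donttest{
#' calibrate_effect(trial_design(), strategy_er(),
#'                  get_scenario("scenario1"), k = 1, l = 1,
#'                  target_power = 0.8, reps = 200, seed = 1)
#' }
#' @export
calibrate_effect <- function(design, strategy, template,
                             coef = c("delta", "beta"), k = 1, l = 1,
                             target_power = 0.8, reps = 500, seed = 1,
                             interval = c(0, 4), tol_se = 1, max_iter = 10) {
  coef <- match.arg(coef)
  if (target_power <= 0.5 || target_power >= 0.99)
    abort_config("`target_power` must lie in (0.5, 0.99).")
  make_scenario <- function(v) {
    beta <- template$beta
    delta <- template$delta
    if (coef == "delta") delta[k, l] <- v else beta[k] <- v
    scenario_spec(template$alpha, beta, template$gamma, delta,
                  label = template$label, name = template$name)
  }
  eval_power <- function(v, s) {
    st <- run_study(design, make_scenario(v), strategy, reps = reps, seed = s)
    rejection_rate(st, k, l)
  }
  trace <- list()
  lo <- interval[1]; hi <- interval[2]
  p_lo <- eval_power(lo, derive_seed(seed, 1))
  p_hi <- eval_power(hi, derive_seed(seed, 2))
  trace[[1]] <- tibble(value = lo, power = p_lo)
  trace[[2]] <- tibble(value = hi, power = p_hi)
  if (p_lo > target_power || p_hi < target_power)
    abort("Search interval does not bracket the target power.",
          class = "umbrellasim_calibration_error",
          body = c(sprintf("power(%.3g) = %.3f", lo, p_lo),
                   sprintf("power(%.3g) = %.3f", hi, p_hi)))
  mid <- (lo + hi) / 2
  p_mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    p_mid <- eval_power(mid, derive_seed(seed, 2 + it))
    trace[[2 + it]] <- tibble(value = mid, power = p_mid)
    se <- sqrt(p_mid * (1 - p_mid) / reps)
    if (abs(p_mid - target_power) <= tol_se * se) break
    if (p_mid < target_power) lo <- mid else hi <- mid
  }
  list(value = mid, power = p_mid,
       mc_se = sqrt(p_mid * (1 - p_mid) / reps),
       trace = dplyr::bind_rows(trace))
}
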