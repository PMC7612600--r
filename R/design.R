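#' Define an umbrella-trial design
#'
#' Bundles the structural quantities of the trial: the number of experimental
#' treatments `K` (each linked one-to-one with a biomarker), the biomarker
#' prevalences, the maximum enrolment, the interim-analysis schedule used by
#' Bayesian adaptive randomisation, and the one-sided test level of the final
#' analysis.  The defaults describe a four-biomarker phase II design enrolling
#' up to 400 patients with interim looks after 100, 175, 250 and 325 patients.
#'
#' Patients negative for every biomarker are, by default, eligible for all
#' experimental arms plus control (`negative_policy = "all_arms"`); the
#' `"excluded"` policy instead restricts them to control, emulating designs
#' that route no-match patients to a separate sub-study.
#'
#' @param K Number of experimental treatments (integer, at least 2).
#' @param prevalences Length-`K` vector of biomarker positivity probabilities,
#'   each strictly inside (0, 1).  Biomarkers are sampled independently.
#' @param n_max Maximum enrolment.
#' @param interims Strictly increasing enrolment counts (all below `n_max`) at
#'   which Bayesian adaptive randomisation refits its posterior.  The other
#'   strategies perform no interim analysis.
#' @param test_level One-sided significance level of the final Wald tests,
#'   strictly between 0 and 0.5.
#' @param negative_policy Eligibility rule for all-negative patients, see
#'   Details.
#'
#' @return An object of class `trial_design`.
#' @examples
#' trial_design()
#' trial_design(prevalences = c(0.1, 0.25, 0.3, 0.25))
#' @export
trial_design <- function(K = 4,
                         prevalences = c(0.30, 0.25, 0.30, 0.25),
                         n_max = 400,
                         interims = c(100, 175, 250, 325),
                         test_level = 0.05,
                         negative_policy = c("all_arms", "excluded")) {
  negative_policy <- match.arg(negative_policy)
  if (length(K) != 1L || !is.finite(K) || K != round(K) || K < 2)
    abort_config("`K` must be a single integer >= 2.")
  K <- as.integer(K)
  if (length(prevalences) != K)
    abort_config("`prevalences` must have length `K`.")
  if (!is.numeric(prevalences) || any(!is.finite(prevalences)) ||
      any(prevalences <= 0) || any(prevalences >= 1))
    abort_config("Every biomarker prevalence must lie strictly in (0, 1).")
  if (length(n_max) != 1L || !is.finite(n_max) || n_max < 1 || n_max != round(n_max))
    abort_config("`n_max` must be a single positive integer.")
  interims <- as.integer(interims)
  if (length(interims) > 0) {
    if (any(interims < 1) || any(interims >= n_max) ||
        (length(interims) > 1 && any(diff(interims) <= 0)))
      abort_config("`interims` must be strictly increasing and all below `n_max`.")
  }
  if (length(test_level) != 1L || !is.finite(test_level) ||
      test_level <= 0 || test_level >= 0.5)
    abort_config("`test_level` must lie strictly in (0, 0.5).")
  structure(
    list(K = K,
         prevalences = as.numeric(prevalences),
         n_max = as.integer(n_max),
         interims = interims,
         test_level = as.numeric(test_level),
         negative_policy = negative_policy),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design>\n")
  cat("  K =", x$K, "experimental arms + control; n_max =", x$n_max, "\n")
  cat("  prevalences:", paste(format(x$prevalences), collapse = ", "), "\n")
  cat("  interims:", if (length(x$interims)) paste(x$interims, collapse = ", ") else "none", "\n")
  cat("  one-sided test level:", x$test_level,
      "; all-negative policy:", x$negative_policy, "\n")
  invisible(x)
}

# All 2^K biomarker profiles as a 0/1 matrix, row r corresponding to
# profile id r = 1 + sum_l b_l 2^(l-1).
profile_matrix <- function(K) {
  m <- as.matrix(expand.grid(rep(list(0:1), K), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- list(NULL, paste0("b", seq_len(K)))
  storage.mode(m) <- "integer"
  m
}

profile_id <- function(profiles) {
  K <- ncol(profiles)
  as.integer(profiles %*% (2^(seq_len(K) - 1))) + 1L
}

#' Enumerate all biomarker profiles
#'
#' @param K Number of biomarkers.
#' @return A tibble with one row per profile: `id` (1-based profile index),
#'   indicator columns `b1 ... bK`, and `n_positive`.
#' @examples
#' biomarker_profiles(4)
#' @export
biomarker_profiles <- function(K = 4) {
  m <- profile_matrix(K)
  out <- as_tibble(m)
  dplyr::mutate(out, id = profile_id(m), n_positive = rowSums(m),
                .before = 1)
}

.sample_profile_matrix <- function(n, prevalences, profile_probs = NULL) {
  K <- length(prevalences)
  if (!is.null(profile_probs)) {
    if (length(profile_probs) != 2^K)
      abort_config("`profile_probs` must have one entry per profile (2^K).")
    if (any(profile_probs < 0) || abs(sum(profile_probs) - 1) > 1e-8)
      abort_config("`profile_probs` must be a probability distribution.")
    ids <- sample.int(2^K, n, replace = TRUE, prob = profile_probs)
    m <- profile_matrix(K)[ids, , drop = FALSE]
  } else {
    m <- matrix(rbinom(n * K, 1L, rep(prevalences, each = n)), nrow = n,
                dimnames = list(NULL, paste0("b", seq_len(K))))
    storage.mode(m) <- "integer"
  }
  m
}

#' Sample synthetic biomarker profiles
#'
#' Draws each biomarker independently as a Bernoulli variable with its
#' prevalence.  An optional full profile-probability table (one entry per
#' profile, in `biomarker_profiles()` order) replaces independent sampling and
#' can emulate correlated or mutually exclusive biomarkers.
#'
#' @param n Number of patients.
#' @param prevalences Vector of biomarker prevalences, each in (0, 1).
#' @param seed Optional integer seed for reproducibility.
#' @param profile_probs Optional length-`2^K` probability vector over profiles.
#' @return A tibble with a `patient` column and indicator columns `b1 ... bK`.
#' @examples
#' sample_profiles(5, c(0.3, 0.25, 0.3, 0.25), seed = 1)
#' @export
sample_profiles <- function(n, prevalences, seed = NULL, profile_probs = NULL) {
  if (length(n) != 1L || n < 1) abort_config("`n` must be a positive count.")
  if (is.null(profile_probs) &&
      (any(prevalences <= 0) || any(prevalences >= 1)))
    abort_config("Every biomarker prevalence must lie strictly in (0, 1).")
  if (!is.null(seed)) set.seed(seed)
  m <- .sample_profile_matrix(n, prevalences, profile_probs)
  dplyr::mutate(as_tibble(m), patient = seq_len(n), .before = 1)
}

#' Probability of a biomarker profile
#'
#' Closed-form probability of observing a given positivity profile under
#' independent biomarkers: the product over biomarkers of the prevalence (if
#' positive) or its complement (if negative).
#'
#' @param profile A 0/1 vector, or a matrix/data frame of profiles (one row
#'   per patient, biomarker indicator columns).
#' @param prevalences Vector of biomarker prevalences.
#' @return A numeric probability (vector, for matrix input).
#' @examples
#' profile_probability(c(0, 0, 0, 0), c(0.3, 0.25, 0.3, 0.25)) # 0.275625
#' @export
profile_probability <- function(profile, prevalences) {
  if (is.data.frame(profile)) profile <- as.matrix(profile[paste0("b", seq_along(prevalences))])
  if (is.matrix(profile)) {
    if (ncol(profile) != length(prevalences))
      abort_config("Profile and prevalence lengths differ.")
    p <- matrix(rep(prevalences, each = nrow(profile)), nrow = nrow(profile))
    return(apply(ifelse(profile == 1, p, 1 - p), 1, prod))
  }
  if (length(profile) != length(prevalences))
    abort_config("Profile and prevalence lengths differ.")
  prod(ifelse(profile == 1, prevalences, 1 - prevalences))
}

#' Arms a patient is eligible for
#'
#' The control arm (index 0) is always eligible.  A patient positive for
#' biomarker `l` is eligible for the linked experimental arm `l`; an
#' all-negative patient is eligible for every experimental arm under the
#' `"all_arms"` policy, or for control only under `"excluded"`.
#'
#' @param profile 0/1 biomarker positivity vector.
#' @param K Number of experimental arms (defaults to the profile length).
#' @param negative_policy `"all_arms"` or `"excluded"`.
#' @return Sorted integer vector of arm indices (0 = control).
#' @examples
#' eligible_arms(c(0, 0, 0, 0)) # 0:4
#' eligible_arms(c(1, 0, 1, 0)) # c(0, 1, 3)
#' @export
eligible_arms <- function(profile, K = length(profile),
                          negative_policy = "all_arms") {
  if (length(profile) != K || any(!profile %in% c(0L, 1L)))
    abort_contract("`profile` must be a 0/1 vector of length K.")
  if (sum(profile) == 0) {
    if (identical(negative_policy, "excluded")) return(0L)
    return(0:K)
  }
  c(0L, which(profile == 1))
}
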