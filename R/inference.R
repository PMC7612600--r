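analysis_terms <- function(K) {
  c("alpha", paste0("beta", seq_len(K)), paste0("gamma", seq_len(K)),
    unlist(lapply(seq_len(K), function(k)
      paste0("delta", k, "_", setdiff(seq_len(K), k)))))
}

#' Design matrix of the analysis model
#'
#' Builds the logistic analysis-model matrix: intercept, `K` treatment
#' indicators, `K` biomarker indicators, and the `K(K-1)` off-diagonal
#' treatment-by-biomarker interaction columns.  The diagonal interactions
#' are structurally fixed at zero for identifiability and are excluded, so
#' the matrix has `1 + 2K + K(K-1)` columns (21 when `K = 4`).
#'
#' @param arms Integer vector of assigned arms (0 = control).
#' @param profiles 0/1 matrix of biomarker profiles, one row per patient.
#' @return Numeric model matrix with named columns.
#' @export
build_model_matrix <- function(arms, profiles, K = ncol(profiles)) {
  n <- length(arms)
  Tm <- matrix(0, n, K)
  on <- which(arms > 0)
  Tm[cbind(on, arms[on])] <- 1
  inter <- matrix(0, n, K * (K - 1))
  j <- 0L
  for (k in seq_len(K)) for (l in setdiff(seq_len(K), k)) {
    j <- j + 1L
    inter[, j] <- Tm[, k] * profiles[, l]
  }
  X <- cbind(1, Tm, profiles, inter)
  colnames(X) <- analysis_terms(K)
  X
}

#' @param K Number of experimental arms.
#' @rdname build_model_matrix
#' @export
n_free_parameters <- function(K) 1L + 2L * K + K * (K - 1L)

# Maximum-likelihood logistic fit with covariance recovered from the QR
# decomposition (dispersion fixed at 1), tolerant of rank deficiency.
.fit_glm <- function(X, y) {
  p <- ncol(X)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
  co <- fit$coefficients
  V <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  rank <- fit$rank
  ok <- FALSE
  if (rank > 0) {
    piv <- fit$qr$pivot[seq_len(rank)]
    Vu <- tryCatch(chol2inv(fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(Vu)) { V[piv, piv] <- Vu; ok <- TRUE }
  }
  se <- sqrt(diag(V))
  separation <- any(abs(co) > 10, na.rm = TRUE) ||
    any(!is.na(co) & !is.finite(se))
  list(coefficients = co, vcov = V, se = se,
       converged = isTRUE(fit$converged) && ok,
       separation = separation,
       rank_deficient = rank < p,
       n = length(y), deviance = fit$deviance,
       df_residual = fit$df.residual)
}

#' Fit the frequentist analysis model
#'
#' Maximum-likelihood logistic regression of the binary response on
#' treatment indicators, biomarker indicators and the off-diagonal
#' treatment-by-biomarker interactions (diagonal interactions fixed at 0).
#' The fit never throws on degenerate data: complete separation (any
#' coefficient magnitude above 10 or a non-finite standard error) and
#' non-convergence are recorded as flags and handled downstream by treating
#' the affected hypotheses as non-rejections.
#'
#' @param patients A data frame with columns `arm`, `response` and biomarker
#'   indicators `b1 ... bK` (the `patients` tibble of [run_trial()] works
#'   as-is).
#' @param K Number of experimental arms; defaults to the number of `b*`
#'   columns.
#' @return An object of class `umbrella_fit` with elements `coefficients`,
#'   `vcov`, `se`, and flags `converged`, `separation`, `rank_deficient`.
#' @examples
#' des <- trial_design()
#' tr <- run_trial(des, get_scenario("scenario1"), strategy_er(), seed = 1)
#' fit <- fit_outcome_model(tr$patients)
#' glance(fit)
#' @export
fit_outcome_model <- function(patients, K = NULL) {
  K <- K %||% sum(grepl("^b[0-9]+$", names(patients)))
  profiles <- as.matrix(patients[paste0("b", seq_len(K))])
  X <- build_model_matrix(patients$arm, profiles, K)
  res <- .fit_glm(X, patients$response)
  res$K <- K
  class(res) <- "umbrella_fit"
  res
}

#' @export
print.umbrella_fit <- function(x, ...) {
  cat("<umbrella_fit> logistic analysis model,", x$n, "patients,",
      length(x$coefficients), "free parameters\n")
  cat("  converged:", x$converged, " separation:", x$separation,
      " rank deficient:", x$rank_deficient, "\n")
  invisible(x)
}

#' @export
tidy.umbrella_fit <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(z),
         p.value = unname(2 * pnorm(abs(z), lower.tail = FALSE)))
}

#' @export
glance.umbrella_fit <- function(x, ...) {
  tibble(n = x$n, df.residual = x$df_residual, deviance = x$deviance,
         converged = x$converged, separation = x$separation,
         rank_deficient = x$rank_deficient)
}

.hyp_grid_cache <- new.env(parent = emptyenv())

# The K(K+1) hypotheses with the coefficient positions each one combines.
hypothesis_grid <- function(K) {
  key <- as.character(K)
  g <- .hyp_grid_cache[[key]]
  if (!is.null(g)) return(g)
  terms <- analysis_terms(K)
  g <- expand.grid(biomarker = 0:K, treatment = seq_len(K))[, 2:1]
  g$bi <- match(paste0("beta", g$treatment), terms)
  g$di <- ifelse(g$biomarker == 0 | g$biomarker == g$treatment, NA_integer_,
                 match(paste0("delta", g$treatment, "_", g$biomarker), terms))
  .hyp_grid_cache[[key]] <- g
  g
}

#' One-sided tests of the treatment-in-subgroup hypotheses
#'
#' Performs the `K(K + 1)` one-sided Wald z-tests of
#' `H0(k, l): beta_k + delta_kl <= 0` for biomarker populations `l = 1..K`
#' and `H0(k, 0): beta_k <= 0` for the biomarker-negative population
#' (20 tests when `K = 4`).  Because the analysis model fixes
#' `delta_kk = 0`, the linked test (`l = k`) coincides with the
#' biomarker-negative test for the same treatment.  Standard errors come
#' from the delta method on the fitted covariance.  Hypotheses whose
#' coefficients are affected by separation, rank deficiency or
#' non-convergence are flagged and counted as non-rejections.
#'
#' @param fit An `umbrella_fit`.
#' @param level One-sided significance level.
#' @return A tibble with one row per hypothesis: `treatment`, `biomarker`
#'   (0 = biomarker-negative population), `estimate`, `std_error`,
#'   `statistic`, `p_value`, `reject`, `flagged`.
#' @examples
#' des <- trial_design()
#' tr <- run_trial(des, get_scenario("scenario1"), strategy_er(), seed = 1)
#' test_hypotheses(tr$fit)
#' @export
test_hypotheses <- function(fit, level = 0.05) {
  K <- fit$K
  co <- unname(fit$coefficients)
  V <- fit$vcov
  crit <- qnorm(1 - level)
  g <- hypothesis_grid(K)
  est <- co[g$bi]
  v <- diag(V)[g$bi]
  hd <- which(!is.na(g$di))
  di <- g$di[hd]
  est[hd] <- est[hd] + co[di]
  v[hd] <- v[hd] + diag(V)[di] + 2 * V[cbind(g$bi[hd], di)]
  bad <- is.na(co) | !is.finite(unname(fit$se)) | abs(co) > 10
  bad[is.na(bad)] <- TRUE
  flagged <- bad[g$bi] | !fit$converged
  flagged[hd] <- flagged[hd] | bad[di]
  se <- sqrt(v)
  z <- est / se
  reject <- !flagged & is.finite(z) & z > crit
  reject[is.na(reject)] <- FALSE
  tibble(treatment = g$treatment, biomarker = g$biomarker,
         estimate = est, std_error = se, statistic = z,
         p_value = pnorm(z, lower.tail = FALSE),
         reject = reject, flagged = flagged)
}

# Which of the 20 null hypotheses are TRUE under a generating scenario.
hypothesis_truth <- function(scenario) {
  K <- scenario$K
  grid <- tidyr::expand_grid(treatment = seq_len(K), biomarker = 0:K)
  dplyr::mutate(grid, true_effect = purrr::map2_dbl(
    .data$treatment, .data$biomarker,
    function(k, l) scenario$beta[k] + if (l > 0) scenario$delta[k, l] else 0
  ), h0_true = .data$true_effect <= 1e-12)
}
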