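---
title: "Allocating multi-biomarker patients in umbrella trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allocating multi-biomarker patients in umbrella trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(umbrellasim)
library(dplyr)
```

## The design problem

An umbrella trial evaluates several experimental treatments, each matched
("linked") to one biomarker-defined subtype of a single disease, against a
shared control.  When the biomarkers can co-occur, a patient positive for
several of them is eligible for several sub-studies at once, and the trial
must pre-specify how such patients are allocated.  umbrellasim simulates a
phase II design of this kind — by default four biomarkers with prevalences
0.30, 0.25, 0.30, 0.25 sampled independently, four linked experimental arms
plus control, a binary response endpoint, and up to 400 patients — and
estimates how the choice among five allocation strategies changes the
trial's operating characteristics.

Eligibility follows the linked-pair rule: a patient positive for biomarker
$l$ is eligible for arm $T_l$ and control; a patient negative for every
biomarker is eligible for all arms (a configurable policy, since some
real designs route such patients to a separate no-match cohort instead).
Patients positive for exactly one biomarker are randomised 1:1 between
control and the linked arm under every strategy; the strategies only
disagree about multi-eligible patients.

## The five strategies and their tuning constants

* **ER** (equal randomisation): uniform over the eligible arms.
* **RFAC** (fixed control probability): control gets $\theta \in (0,1)$,
  the rest is split equally.  `scope = "all_patients"` applies $\theta$ to
  everyone and makes the expected experimental share exactly $1-\theta$;
  the default scope leaves single-biomarker patients on the 1:1 rule.
* **HIER** (biomarker hierarchy): with belief $\rho \in [0.5, 1]$ the
  patient is randomised 1:1 between control and the arm linked to their
  highest-ranked positive biomarker, with $1-\rho$ equally between control
  and the remaining eligible arms.  $\rho = 1$ is complete belief.
* **CR** (constrained randomisation): with probability $\phi \in [0.5, 1]$
  the least-accrued eligible experimental arm is randomised 1:1 against
  control (ties broken uniformly), with $1-\phi$ one of the others.  The
  `arm_balance` mode instead sends mass $\phi$ straight to the
  least-accrued arm among all eligible arms including control, which is
  the minimisation-style behaviour that drives per-arm balance and an
  experimental share near $1 - 1/(K+1)$.
* **BAR** (Bayesian adaptive randomisation): starts as ER; after each
  interim analysis (after 100, 175, 250 and 325 patients by default) a
  Bayesian logistic model with independent $U(-10, 10)$ priors is
  refitted, and a multi-eligible patient's experimental mass is split
  proportionally to each arm's posterior probability of being best *for
  that patient's profile* (raised to a tuning power, 1 by default), with
  control fixed at $1/(m+1)$ for $m$ eligible experimental arms.  The
  other four strategies perform no interim analysis.

## Outcome model and hypotheses

Responses are Bernoulli, $Y_i \sim \mathrm{Bern}(p_i)$, with

$$\mathrm{logit}(p_i) = \alpha + \sum_{k=1}^K T_{ik}\beta_k
  + \sum_{l=1}^K x_{il}\gamma_l
  + \sum_{k=1}^K\sum_{l=1}^K T_{ik} x_{il} \delta_{kl},$$

where $T_{ik}$ indicates allocation to arm $k$ and $x_{il}$ biomarker-$l$
positivity.  The analysis model fixes $\delta_{kk} = 0$ for
identifiability, leaving $1 + 2K + K(K-1) = 21$ free parameters, and the
final analysis tests the $K(K+1) = 20$ one-sided hypotheses
$H_0(k,l): \beta_k + \delta_{kl} \le 0$ (for $l \ge 1$) and
$H_0(k,0): \beta_k \le 0$ by Wald $z$-tests at one-sided level 0.05, with
delta-method standard errors.  No multiplicity adjustment is applied: each
hypothesis is reported marginally.

The *generating* model is allowed a non-zero diagonal: "treatment $k$
works in its linked subgroup" is encoded as $\delta_{kk} > 0$.  The
mismatch with the constrained analysis model is deliberate and has a
visible consequence: the tested contrast $\hat\beta_1$ pools the
treatment-versus-control effect over biomarker-positive *and*
biomarker-negative patients on $T_1$, so its expectation is a dilution of
the subgroup effect.  Which strategy routes more biomarker-negative
patients onto $T_1$ therefore directly moves the power of $H_0(1,1)$ —
see "Strategy variants for comparisons" below.

### Degenerate fits

With 400 patients and 21 parameters, the off-diagonal interaction cells
(e.g. patients on $T_2$ positive for $B_1$) often hold fewer than ten
patients, and a cell with all non-responders drives its coefficient to
$-\infty$ (separation).  A fit is flagged when any coefficient magnitude
exceeds 10 or a standard error is non-finite; a hypothesis whose own
coefficients are affected (or any hypothesis from a non-converged fit) is
counted as a non-rejection and flagged.  This is conservative and matches
what the Wald statistic does anyway — a separated cell has an enormous
standard error and a $z$ near zero.  Bias/MSE of the tracked estimand
excludes replicates whose estimand was flagged.

## Synthetic scenarios and calibration

The packaged scenario library (`scenario_library()`,
`inst/extdata/scenario-library.yaml`) covers a global null, linked and
unlinked benefits, a detrimental linked effect, mixed benefit/harm, and an
everywhere-beneficial treatment.  All library scenarios use a 20% baseline
response ($\alpha = \mathrm{logit}(0.2)$), the response level typical of
objective-response endpoints in this setting, and zero biomarker main
effects ($\gamma = 0$), so that biomarker positivity is purely predictive
rather than prognostic.  Both choices are overridable per scenario.

The linked-interaction magnitude was calibrated once with
`calibrate_effect()` (bisection over Monte-Carlo power) so that *every*
allocation strategy reaches at least 80% power for $H_0(1,1)$ at the
default design; the weakest strategy in the comparison set (constrained
randomisation in its arm-balancing mode) anchors the calibration, giving
$\delta_{11} = 2.1$ on the log-odds scale ($0.2 \to \approx 0.67$ response
for a linked-subgroup patient on $T_1$).  The "some benefit for all" main
effect is fixed at $\beta_1 = 0.30$, deliberately modest.  These values
are the package's study conditions and are not tuned per analysis.

What the generator does *not* emulate: correlated or mutually exclusive
biomarkers (though `sample_profiles()` accepts a full profile-probability
table to express them), assay error, accrual-time patterns, response
delay (outcomes are available immediately), dropout, and arm stopping.
Passing results therefore speak to the randomisation arithmetic and the
analysis model, not to operational complications of a real trial.

## Strategy variants for comparisons

Two strategy options deserve explanation because the defaults and the
comparison studies differ:

* **HIER for all-negative patients.**  The hierarchy rule is stated for
  biomarker-positive patients.  The constructor default treats
  all-negative patients as positive for everything (the hierarchy's top
  arm gets mass $\rho$); `negative = "er"` randomises them equally.  Under
  the default, the 27.6% all-negative patients flood the top arm with
  biomarker-negative (hence unaffected) patients, diluting $\hat\beta_1$
  and making HIER the *least* powerful strategy.  The comparative studies
  in this package use `negative = "er"`, under which HIER's experimental
  share and power ranking match the behaviour reported for hierarchy
  designs (highest power for a correctly specified hierarchy).
* **CR mode.**  The `control_paired` default follows the rule as usually
  stated — after choosing the experimental arm, randomise 1:1 against
  control — which gives multi-eligible patients a 50% control share and an
  overall experimental share near 50%.  Reported hierarchy/minimisation
  trials, however, show constrained approaches allocating about 80% of
  patients to experimental arms, which is what the `arm_balance` mode
  reproduces.  The comparative studies use `arm_balance`.

## Numerical choices

* **Wald tests**: one-sided $z$ on the linear combination, standard for
  GLM contrasts and cheap at $10^4$ replicates; a likelihood-ratio variant
  is not provided.
* **Bayesian computation**: the interim posterior is available as a
  Laplace approximation (normal at the clamped MLE, covariance from the
  inverse observed information with flat directions capped at standard
  deviation 5, draws clipped to the prior support) or random-walk
  Metropolis (Laplace-shaped proposal, global scale adapted during
  burn-in to a 25–45% acceptance rate; defaults 4,000 iterations, 1,000
  burn-in).  The two modes agree on best-arm probabilities to within 0.05
  on a reference trial dataset once the chain is long enough; the Laplace
  mode is the practical choice inside replication loops.
* **Ties**: minimal-accrual ties in CR break uniformly; best-arm ties
  within a posterior draw split equally; a patient whose eligible arms all
  tie on the true response probability has no "best" arm and never counts
  towards the best-treatment proportion.
* **Seeding**: replicate $r$ of a study uses a seed derived
  deterministically from the base seed and $r$ (kept below $2^{31}$), so
  studies are reproducible and independent of execution order.
* **Proportion on best treatment**: the denominator is all enrolled
  patients; a patient counts when their assigned arm attains the maximal
  true response probability among their eligible arms and not all eligible
  arms tie.  Under the global null the proportion is undefined and
  reported as `NA`.

## Problem sizes used by the test suite

The packaged checks run the design at full size ($N = 400$) but choose
replicate counts by the precision each check needs: exact closed forms are
verified analytically; the null rejection rate uses 10,000 replicates
(binomial standard error 0.22 percentage points); strategy power
comparisons use 2,000 replicates (1 point); adaptive-randomisation checks
use 200 replicates with the Laplace mode; balance and trend properties use
250–500 replicates.  The estimator-bias check uses a correctly specified
generating model (effect in $\beta_1$, zero interaction diagonal) at
$N = 2000$, because under the diagonal-encoded scenarios the constrained
analysis model is misspecified by construction and its estimand is the
diluted contrast discussed above, not the generating coefficient.

## A worked example

```{r example}
design <- trial_design()
scenario <- get_scenario("scenario2")   # T1 works in B1-positive patients

study <- run_study(design, scenario, strategy_er(), reps = 200, seed = 2024)
glance(study)

tidy(study) |> filter(biomarker <= 2, treatment <= 2)
```

Under scenario 2 only $H_0(1,1)$ is false; its rejection rate is the
power, every other rate is a type I error.  The experimental-arm
proportion reproduces the closed form
`expected_exp_proportion(strategy_er(), design)` = 63.9%.

## Known limitations

The simulator inherits the frame of its design: a shared binary endpoint
across sub-studies, a common control arm, known prevalences, and
allocation-only interim analyses (no early stopping or arm dropping).
Family-wise error control is intentionally out of scope — the 20
hypotheses are reported marginally.  The analysis-model dilution of
subgroup effects is a property of the constrained model, not an artefact
the package attempts to correct; an estimand-faithful analysis would need
the diagonal interactions to be identified through other constraints.
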