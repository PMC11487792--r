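---
title: "Emulating a prophylaxis-stopping trial: clone-censor-weight with reference-based multiple imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a prophylaxis-stopping trial: clone-censor-weight with reference-based multiple imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccwmi)
```

## The estimand and the design

The package targets the effect of two deterministic strategies for stopping
pneumocystis-pneumonia (PcP) prophylaxis in people living with HIV on
combination antiretroviral therapy, on the composite outcome *PcP diagnosis
or death from any cause* over 60 months:

* population — people taking PcP prophylaxis at a qualifying visit;
* treatments — stop prophylaxis guided by CD4 recovery (regime 1: stop
  after CD4 > 200 cells/µL at more than 3 consecutive monthly visits)
  versus guided by confirmed viral suppression (regime 2: stop after two
  consecutive HIV-RNA measurements < 400 copies/ml);
* summary — one hazard ratio over the whole follow-up period;
* intercurrent event — non-compliance with the assigned strategy, handled
  by a *while-on-regime* strategy: follow-up contributes only while the
  patient's observed prophylaxis state is consistent with the assigned
  regime.

Because every eligible patient is, at time 0, consistent with both
strategies, each is cloned into both arms; clones are artificially censored
at first non-compliance, and that censoring is corrected by stabilized
inverse-probability-of-censoring weights (IPCW).  The hazard model is a
pooled logistic regression on person-months — the discrete-time
approximation to a proportional-hazards model —

$$\operatorname{logit} h(t) = \beta_0 + \beta_1 t + \beta_2 t^2 +
  \beta_3 t^3 + \theta\,\text{arm2} + \gamma\, t \cdot \text{arm2},$$

fitted with the IPC weights.

## Operationalising the regimes

The published rule texts leave three details open; the package fixes them as
follows (all configurable through `regime_spec()` and `clone_and_follow()`):

* **"> 3 months"** means *more than three consecutive monthly records* above
  threshold — the stopping condition first fires at the 4th consecutive
  qualifying record.  The monthly grid is the native resolution of the
  analysis (weights are per patient-month), so a finer reading has nothing
  to attach to.
* **Restart**: the continuation conditions ("continue if CD4 < 200",
  "continue if RNA > 400") are read as reactivating — after a CD4 relapse or
  viral rebound the regime requires prophylaxis again (`restart = TRUE` by
  default).
* **Compliance grace**: regimes are deterministic strategies, so in
  principle a patient is non-compliant the first month the observed
  prophylaxis state differs from the required one.  Real behaviour lags lab
  results, so a grace period (default 1 month) excuses *lagging*: an
  observed state is compliant if it matches a state the regime required
  within the last `grace` months.  Taking a state that was never recently
  required — e.g. stopping after a single suppressed measurement — is an
  immediate intercurrent event.  This asymmetric rule reproduces both
  hand-traceable boundary cases (a patient who fails to stop under regime 1
  is censored one month after the rule fires; a patient who stops
  prematurely under regime 2 is censored on the spot).

When several terminal causes coincide in a month the precedence is
event > ICE censoring > LTFU: an event observed while the clone is still
at-risk is counted.  Loss to follow-up must be flagged explicitly in the
input (`ltfu_after`); histories that simply end early (late cohort entry
relative to an administrative close) are administrative censoring, not LTFU.

## Censoring weights

The original study delegates its weight-model covariates to an unavailable
appendix, so the package declares its own defaults and treats them as
configuration, not as a claim about the original: the denominator model of
remaining uncensored regresses on current CD4, an RNA-suppression indicator
(RNA < 400), the current prophylaxis state and a cubic in month — the
variables the regimes themselves condition on, which are what drives ICE
censoring; the numerator uses the cubic in month only.  Weights are
stabilized cumulative products, truncated at the 99th percentile (flagged,
togglable), with a hard positivity error when a denominator probability
falls below 10⁻⁶ rather than silent capping.

Two numerical conventions matter.  With *no* ICE censoring in an arm the
package returns an exact degenerate fit (probability identically 1) instead
of a saturated regression, so the no-censoring identity — all weights
exactly 1 — holds bit-for-bit.  And the mean-one property of stabilized
weights is only guaranteed under a correctly specified censoring model; the
test suite checks it in a controlled world whose censoring mechanism is
exactly the fitted model.  In the bundled simulator the true ICE mechanism
depends on rule-state history that the default covariates summarise only
approximately, so per-month mean weights can drift from 1 — a realistic
property of applied IPCW, not a defect, and one reason the weight summary
is written to the run log.

## Summarising the hazard ratio

The fitted model carries a month-by-regime interaction, yet the estimand is
a single whole-period hazard ratio; how the interaction is collapsed is a
reporting decision the package makes explicit.  `summarise_hr()` offers the
month-0 contrast `exp(θ)` (`"main-effect"`, the package default for
reporting) and the person-time-weighted average
`exp(θ + γ t̄)` (`"time-averaged"`).  For *parameter recovery* against the
simulator's known truth the acceptance suite uses the time-averaged
summary: when the true hazards are proportional the two estimate the same
quantity, but the time average uses the information of the whole follow-up
and has materially smaller replicate variance (empirically sd ≈ 0.13
versus ≈ 0.29 at n = 2000), so the replicate mean of the exponentiated
estimate is not inflated by the curvature of `exp` at high noise.

Model-based Wald intervals are reported by default; `bootstrap_ci()`
resamples *patients* (both clones of a resampled patient enter together —
clones of one person are not independent, which is why clone-month
resampling is rejected) and re-estimates weights and the outcome fit on
each replicate.  Screening and cloning are per-patient deterministic maps,
so the per-patient clone blocks are computed once and resampled — the
replicate estimate is identical to re-running the full pipeline on the
resampled cohort, at a fraction of the cost.

## Reference-based multiple imputation for loss to follow-up

The primary analysis assumes all censoring — including LTFU — is at random
(CAR).  People lost from HIV cohorts are plausibly at *higher* risk, so the
sensitivity analysis asks: what if those LTFU stopped prophylaxis when they
disappeared?  Post-LTFU person-months are multiply imputed from the hazard
of a clinically meaningful reference group:

* `car` — own-arm on-regime hazard (the primary model refitted to observed
  clone-months; congeniality cross-check);
* `j2op` — the pooled hazard of person-months *off prophylaxis* (regime
  terms dropped), applied to LTFU clones of both arms;
* `j2op-arm2` — the same reference applied to the experimental arm only
  (the asymmetric post-hoc variant); regime-1 clones stay censored exactly
  as in the primary analysis.

`run_mi()` pools, per imputation, either the month-0 main-effect contrast
(the default, mirroring `summarise_hr()`) or the whole-period time-averaged
contrast (`hr_method = "time-averaged"`).  The distinction matters for
sensitivity analyses: imputation appends *late* person-months, so the
month-by-regime interaction absorbs much of the change and the month-0
contrast can even move away from 1 while the whole-period hazard ratio
attenuates toward it.  The attenuation acceptance property is therefore
asserted on the time-averaged contrast — the measurement that matches the
estimand's "one HR over the whole study period".

Each of `m` imputations (default 25) draws coefficients from the
multivariate-normal approximation around the reference MLE (approximate
Bayesian proper MI), draws Bernoulli event indicators month by month from
`expit(x(t)'β)` until the first event or the 60-month horizon, refits the
weighted outcome model on the completed data, and records the log-HR and
its variance.  Estimates are pooled by Rubin's rules
(`T = W̄ + (1 + 1/m)B`) with Barnard–Rubin degrees of freedom.

Three deliberate choices, all logged because the source material is silent:

* imputed months carry **weight 1** in the refit — IPC weights are defined
  only over observed follow-up; imputation *replaces* the missing stretch
  rather than re-weighting it;
* imputed off-prophylaxis behaviour is **not** ICE-censored, although it
  may contradict the assigned regime — the scenario is deliberately a
  worst-case description of post-dropout behaviour, and censoring it away
  would undo the sensitivity analysis;
* the default imputation formula is the primary model's time-and-regime
  terms, which contains no lab covariates, so no post-LTFU CD4/RNA values
  need to be invented; custom imputation formulas with lab terms would
  require a carry-forward convention and are intentionally out of default
  scope (imputed rows carry the last observed labs for bookkeeping only).

With zero LTFU clones in scope every scenario reduces *exactly* to the
primary analysis (`B = 0`, `T = W̄`), which the tests assert identically.

## The synthetic cohort: a stated world

`simulate_cohort()` generates the world the analysis assumes, with known
truth.  Defaults (all on a monthly grid, 60 months):

* baseline CD4 lognormal (meanlog `log(100)`, sdlog 0.5 — about 90% of
  entrants below the 200 cells/µL recommendation threshold), recovering
  10 cells/µL per month on therapy with lognormal noise (sdlog 0.15),
  capped at 800;
* HIV-RNA suppresses below 400 copies/ml with probability 0.25 per month
  (median ≈ 3 months to suppression) and stays suppressed;
* prophylaxis behaviour: each patient follows regime 1 or regime 2 (an
  even mixture by default), conforming to the rule's required state with
  probability 0.9 per month and otherwise carrying last month's state — so
  non-compliance is stochastic given recorded covariates, as the weight
  models assume; `random_stop` behaviour is available to populate
  rule-free stopping;
* composite event: monthly log-odds `qlogis(0.0015)` (≈ 8.6% cumulative
  over 60 months), increased by 0.4 on the log-odds scale in off-prophylaxis
  months, multiplied by the regime effect `log_hr_regime = log(0.78)` for
  patients following the suppression-guided strategy; an event is a PcP
  diagnosis with probability 0.25, else a death;
* LTFU: 8 × 10⁻⁴ per month (≈ 4.7% over 60 months, matching the scale of
  the motivating cohort), optionally inflated by `ltfu_informative_log_or`
  in off-prophylaxis months — 0 gives censoring at random *by
  construction*.

The regime effect is attached to the patient's behavioural *strategy*, so
`true_marginal_hr()` = `exp(log_hr_regime)` is exactly the quantity a
randomized, fully compliant, dropout-free version of the trial estimates.
That world (`adherence_probability = 1`, no LTFU, own-strategy clone kept
via `as_randomized_trial()`) is the parameter-recovery benchmark.  In
cloned worlds with a latent behaviour mixture the strategy indicator is
unobservable before behaviours diverge, so the IPW estimate is *not*
asserted against this truth — the acceptance properties there compare
analyses with each other (CAR-MI against primary; jump-to-off-prophylaxis
against primary), which is also how the motivating study argued.

What the generator does **not** emulate: multi-cohort heterogeneity,
calendar-time trends, realistic correlated lab noise, visit irregularity,
competing-risk structure between PcP and death.  A green test therefore
establishes internal statistical correctness of the estimators under the
stated world, not fidelity to any particular cohort's marginals.

Reproducibility: one master seed; per-patient substreams are derived
deterministically, so enlarging `n_patients` extends the cohort without
reshuffling existing patients.

## Numerical choices and degenerate inputs

* GLM convergence at gradient tolerance 10⁻⁸–10⁻¹⁰, 100 iterations;
  non-convergence is an error, never a silent result.
* All-event, no-event, single-arm (under a regime formula) and all-zero
  weight inputs are refused with informative errors; `n_patients = 0`
  yields a well-formed empty cohort; an event in month 0 terminates both
  clones at month 0.
* Bootstrap and MI replicates that fail to fit are skipped with a message;
  more than 20% failures aborts.
* Composite-event ties (PcP and death in one month) record PcP; the
  composite endpoint is unchanged either way.
* Percentages and descriptive p-values print to one decimal; analysis
  p-values to three, with `< 0.001` below that threshold.

## Known limitations

* The hazard ratio inherits its usual causal-interpretation caveats; no
  restricted-mean or absolute-risk summaries are provided.
* IPCW validity rests on no unmeasured confounding of the censoring
  process; the simulator's latent behaviour type deliberately violates
  this in mixture worlds, which is visible as residual weight drift.
* LTFU weights are not modelled in the primary analysis (LTFU is handled
  by assumption there, and by imputation in the sensitivity analyses).
* The imputation model is parametric and shares its functional form with
  the outcome model; uncongenial user-supplied formulas are not protected
  against.
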