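# ccwmi

Clone-censor-weight trial emulation with reference-based multiple
imputation, for discrete-time (person-month) survival analyses of
treatment-stopping strategies in observational cohorts.

## The problem

People living with HIV with CD4 counts below 200 cells/µL are prescribed
antibiotic prophylaxis against pneumocystis pneumonia (PcP).  Once
combination antiretroviral therapy suppresses viral replication, continuing
prophylaxis carries pill burden, adverse-event and resistance costs, so the
question is *when it is safe to stop*.  Two deterministic stopping
strategies are compared:

* **Regime 1** (current recommendation): stop once CD4 has risen above
  200 cells/µL for more than 3 consecutive monthly visits;
* **Regime 2** (experimental): stop once viral suppression is confirmed by
  two consecutive HIV-RNA measurements below 400 copies/ml.

A randomised trial is impractical (PcP is rare on therapy), so the package
emulates the hypothetical target trial from longitudinal cohort data with
the **clone-censor-weight** design:

1. **Screen & clone** — each patient eligible at their first qualifying
   visit (time 0) is duplicated into both regimes; follow-up of each clone
   ends at the composite *PcP-or-death* event, loss to follow-up (LTFU),
   first non-compliance with the assigned regime (the intercurrent event,
   ICE), or 60 months.
2. **Weight** — artificial censoring at the ICE is corrected by stabilized
   inverse-probability-of-censoring weights,
   `w(t) = ∏_{s≤t} num(s)/den(s)`, from per-arm pooled logistic models of
   remaining uncensored.
3. **Fit** — a weighted pooled logistic regression for the discrete-time
   hazard, `logit h(t) = β₀ + β₁t + β₂t² + β₃t³ + θ·arm2 + γ·t·arm2`,
   summarised as a hazard ratio (main-effect `exp(θ)` or person-time
   averaged `exp(θ + γ·t̄)`), with patient-level bootstrap CIs.
4. **Impute** — because LTFU may be informative (patients who drop out are
   plausibly at higher risk), reference-based multiple imputation completes
   post-LTFU histories under explicit scenarios: censoring at random
   (`car`), "jump to off prophylaxis" in both arms (`j2op`), or in the
   experimental arm only (`j2op-arm2`); per-imputation log-HRs are pooled
   by Rubin's rules with Barnard–Rubin degrees of freedom.

A synthetic-cohort generator with known ground truth (CD4/RNA trajectories,
behaviour-driven prophylaxis, configurable event and LTFU processes)
backs every stage with testable truth.

## Worked example

```r
library(ccwmi)
cfg  <- cohort_config(n_patients = 300, seed = 3)
run  <- run_pipeline(cfg, analysis_options(m = 3), seed = 5)
print(run)
```

```
Descriptive table
                        row count_1 pct_1 count_2 pct_2 p_value
             Total patients     287    NA     287    NA      NA
       Event: PcP diagnosis       3   1.0       3   1.0     1.0
                Event: Died      17   5.9      11   3.8     0.2
 Event: PcP diagnosis/death      20   7.0      14   4.9     0.3
   Lost to follow-up (LTFU)       8   2.8       6   2.1     0.6

Analysis rows (HR [95% CI], p)
                                                         analysis   hr           ci     p
                       Primary analysis: HR under CAR (using IPW) 1.48 [0.33, 6.72] 0.609
       Supplementary analysis: HR under CAR (IPW and MI for LTFU) 1.55 [0.34, 7.07] 0.575
       Sensitivity analysis 1: HR under 'jump to off prophylaxis' 1.54 [0.34, 7.00] 0.579
 Sensitivity analysis 2: 'jump to off prophylaxis', regime 2 only 1.47 [0.32, 6.67] 0.616
```

The descriptive block counts, per arm, the patients reaching each terminal
state (with percentages of the arm's baseline N and two-proportion
chi-square p-values comparing the arms).  The analysis rows give the hazard
ratio of regime 2 versus regime 1 under each censoring assumption; at
n = 300 the interval is wide — the configured true HR here is 0.78, and the
parameter-recovery tests show the estimator centres on it across replicate
cohorts at n = 2000.

Step-by-step access to every stage:

```r
coh  <- simulate_cohort(cfg)                       # long-format cohort
t0   <- screen_eligibility(coh)                    # patient -> time 0
cm   <- clone_and_follow(coh, t0)                  # clone-censor table
cmw  <- estimate_ipcw(cm)                          # stabilized weights
fit  <- fit_pooled_logistic(cmw)                   # weighted hazard model
summarise_hr(fit)                                  # HR [95% CI]
run_mi(cmw, "j2op", m = 25, seed = 1)              # RBMI sensitivity
```

A command-line interface mirrors the pipeline
(`inst/exec/ccwmi <simulate|emulate|analyze|report> --config cfg.json
--seed 1 --out DIR`).

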