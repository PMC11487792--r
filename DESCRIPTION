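Package: ccwmi
Title: Clone-Censor-Weight Trial Emulation with Reference-Based Multiple
    Imputation
Version: 0.1.0
Authors@R:
    person("CCW", "Maintainers", , "maintainers@ccwmi.example.org",
           role = c("aut", "cre"))
Description: Emulates a two-arm target trial of prophylaxis-stopping regimes
    from longitudinal observational cohort data using the clone-censor-weight
    design: eligibility screening and time-zero alignment, duplication of each
    eligible patient into both regimes, artificial censoring at non-compliance
    (the intercurrent event), stabilized inverse-probability-of-censoring
    weights, and a weighted discrete-time pooled logistic hazard model with
    patient-level bootstrap confidence intervals.  Informative loss to
    follow-up is addressed by reference-based multiple imputation ("jump to
    off prophylaxis") with Rubin's-rules pooling and Barnard-Rubin degrees of
    freedom.  Includes a synthetic longitudinal cohort generator (CD4 and
    HIV-RNA trajectories, prophylaxis behaviour, composite event and
    loss-to-follow-up processes) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
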