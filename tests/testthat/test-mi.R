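# weighted clone-month table with LTFU for MI tests, small but non-trivial
mi_fixture <- function(seed = 13, n = 400, ltfu = 4e-3, ...) {
  coh <- simulate_cohort(cohort_config(n, seed = seed,
                                       ltfu_monthly_probability = ltfu, ...))
  estimate_ipcw(clone_and_follow(coh, screen_eligibility(coh)))
}

test_that("scenario definitions fix the reference group and imputed arms", {
  expect_identical(mi_scenario("car")$arms_imputed, 1:2)
  expect_identical(mi_scenario("j2op")$reference, "off-prophylaxis")
  expect_identical(mi_scenario("j2op-arm2")$arms_imputed, 2L)
  expect_error(mi_scenario("banana"))
})

test_that("imputation model guards empty or event-free reference groups", {
  # nobody ever stops prophylaxis: CD4 never recovers, RNA never suppresses
  coh <- simulate_cohort(cohort_config(
    60, seed = 2, cd4_recovery_rate = 0, cd4_noise_sdlog = 0,
    rna_suppression_probability = 0, ltfu_monthly_probability = 5e-3))
  cm <- estimate_ipcw(clone_and_follow(coh, screen_eligibility(coh)))
  expect_false(any(!cm$on_prophylaxis))
  expect_error(fit_imputation_model(cm, mi_scenario("j2op")),
               "empty reference")
})

test_that("intercept-only reference fit is the Bernoulli MLE", {
  ref <- make_clone_table(1000, events_per_arm = c(20, 20))
  ref$on_prophylaxis <- FALSE
  fit <- fit_imputation_model(ref, mi_scenario("j2op"),
                              formula_spec = event ~ 1)
  expect_equal(unname(fit$coefficients), qlogis(0.02), tolerance = 1e-8)
})

test_that("parameter draws are proper and deterministic", {
  ref <- make_clone_table(500, events_per_arm = c(25, 25))
  fit <- fit_imputation_model(ref, mi_scenario("car"),
                              formula_spec = event ~ arm2)
  set.seed(1); d1 <- draw_parameters(fit)
  set.seed(1); d2 <- draw_parameters(fit)
  expect_identical(d1, d2)
  # zero covariance collapses the draw onto the point estimate
  degenerate <- fit
  degenerate$covariance[] <- 0
  expect_equal(draw_parameters(degenerate), fit$coefficients,
               tolerance = 1e-12)
  # law of large numbers: mean of many draws near the MLE
  set.seed(2)
  draws <- t(replicate(2000, draw_parameters(fit)))
  se <- sqrt(diag(fit$covariance) / 2000)
  expect_true(all(abs(colMeans(draws) - fit$coefficients) < 4 * se))
})

test_that("imputed histories respect degenerate reference hazards", {
  cm <- mi_fixture()
  ltfu_arms <- unique(cm$clone_arm[cm$censored_ltfu])
  expect_true(length(ltfu_arms) > 0)
  f <- event ~ month
  never <- impute_event_times(cm, c("(Intercept)" = -1e6, month = 0), f)
  imp <- never[never$imputed, ]
  expect_false(any(imp$event))
  # every imputed clone reaches the horizon event-free
  ends <- tapply(imp$month, paste(imp$patient_id, imp$clone_arm), max)
  expect_true(all(ends == 59))
  always <- impute_event_times(cm, c("(Intercept)" = 1e6, month = 0), f)
  imp2 <- always[always$imputed, ]
  cens <- cm[cm$censored_ltfu & cm$month < 59, ]  # month-59 LTFU: admin end
  expect_identical(nrow(imp2), nrow(cens))  # exactly one month each, c+1
  expect_true(all(imp2$event))
  expect_equal(imp2$month, cens$month + 1L, ignore_attr = TRUE)
  # untouched clones are bit-identical
  key <- function(d) paste(d$patient_id, d$clone_arm)
  reset <- function(d) { rownames(d) <- NULL; d }
  all_lt <- cm[cm$censored_ltfu, ]
  untouched <- !(key(cm) %in% key(all_lt))
  expect_identical(reset(cm[untouched, ]),
                   reset(never[!(key(never) %in% key(all_lt)), ]))
})

test_that("rubin_pool reproduces the worked example and its identities", {
  pooled <- rubin_pool(c(0.10, 0.20, 0.30), c(0.04, 0.04, 0.04))
  expect_equal(pooled$pooled_estimate, 0.20)
  expect_equal(pooled$within_variance, 0.04)
  expect_equal(pooled$between_variance, 0.01)
  expect_equal(pooled$total_variance, 0.04 + (1 + 1 / 3) * 0.01,
               tolerance = 1e-12)
  same <- rubin_pool(rep(0.5, 4), rep(0.02, 4))
  expect_identical(same$between_variance, 0)
  expect_identical(same$total_variance, same$within_variance)
  expect_error(rubin_pool(0.1, 0.1), "m >= 2")
  # CI widens monotonically in B at fixed W
  widths <- vapply(c(0, 0.005, 0.02, 0.08), function(b) {
    est <- c(0.2 - sqrt(b), 0.2 + sqrt(b))  # var(est) = 2b -> B = 2b
    p <- rubin_pool(est, c(0.04, 0.04))
    log(p$ci_high) - log(p$ci_low)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("zero LTFU makes every scenario equal the primary analysis", {
  cm <- mi_fixture(ltfu = 0)
  expect_false(any(cm$censored_ltfu))
  fit <- fit_pooled_logistic(cm)
  theta <- unname(fit$coefficients["arm2"])
  for (sc in c("car", "j2op", "j2op-arm2")) {
    res <- run_mi(cm, sc, m = 3, seed = 1)
    expect_identical(res$n_ltfu_clones, 0L)
    expect_identical(res$pooled_estimate, theta)
    expect_identical(res$total_variance, fit$covariance["arm2", "arm2"])
  }
})

test_that("run_mi is deterministic and the asymmetric scenario leaves arm 1 alone", {
  cm <- mi_fixture()
  r1 <- run_mi(cm, "j2op", m = 4, seed = 9)
  r2 <- run_mi(cm, "j2op", m = 4, seed = 9)
  expect_identical(r1$per_imputation, r2$per_imputation)
  asym <- run_mi(cm, "j2op-arm2", m = 4, seed = 9)
  expect_identical(asym$n_ltfu_clones, sum(cm$censored_ltfu &
                                           cm$clone_arm == 2L))
  # arm-1 LTFU clones of the asymmetric scenario stay censored: the imputer
  # touches only arm-2 rows
  imp <- impute_event_times(cm, draw_parameters(
    fit_imputation_model(cm, mi_scenario("j2op"))),
    event ~ month + I(month^2) + I(month^3), arms = 2L)
  arm1 <- function(d) { d <- d[d$clone_arm == 1L, ]; rownames(d) <- NULL; d }
  expect_identical(arm1(imp), arm1(cm))
})

test_that("imputed event times follow the truncated geometric law", {
  # constant reference hazard p = 0.05, censoring month c = 9, horizon 60:
  # P(event at c+1+k) = (1-p)^k p, survivor mass at the horizon
  p <- 0.05; cmonth <- 9L; horizon <- 60L
  n <- 4000
  cm <- data.frame(patient_id = sprintf("G%05d", 1:n), clone_arm = 1L,
                   month = cmonth, cd4 = 150, rna = 50,
                   on_prophylaxis = FALSE, event = FALSE, event_pcp = FALSE,
                   event_death = FALSE, censored_ice = FALSE,
                   censored_ltfu = TRUE, admin_end = FALSE, imputed = FALSE,
                   weight = 1)
  set.seed(4)
  done <- impute_event_times(cm, c("(Intercept)" = qlogis(p), month = 0),
                             event ~ month, horizon = horizon)
  imp <- done[done$imputed, ]
  ends <- tapply(seq_len(nrow(imp)), imp$patient_id, function(i) {
    j <- i[which.max(imp$month[i])]
    c(month = imp$month[j], event = imp$event[j])
  })
  ends <- do.call(rbind, ends)
  k_max <- horizon - cmonth - 1L  # 50 possible months
  observed <- table(factor(ifelse(ends[, "event"] == 1,
                                  ends[, "month"], horizon),
                           levels = c(cmonth + seq_len(k_max), horizon)))
  probs <- c((1 - p)^(seq_len(k_max) - 1) * p, (1 - p)^k_max)
  # pool sparse tail cells for a valid chi-square
  grp <- pmin(seq_along(probs), 30)
  obs_g <- tapply(as.numeric(observed), grp, sum)
  probs_g <- tapply(probs, grp, sum)
  gof <- suppressWarnings(stats::chisq.test(obs_g, p = probs_g))
  expect_gt(gof$p.value, 0.001)
})
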