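# small clone-month scaffold for controlled censoring fits
censor_fixture <- function(n, censored, covariate) {
  data.frame(patient_id = sprintf("W%04d", seq_len(n)),
             clone_arm = 1L, month = 1L, cd4 = 150, rna = 50,
             on_prophylaxis = covariate, event = FALSE, event_pcp = FALSE,
             event_death = FALSE, censored_ice = censored,
             censored_ltfu = FALSE, admin_end = !censored, imputed = FALSE,
             stringsAsFactors = FALSE)
}

test_that("no ICE censoring gives identity weights exactly", {
  cfg <- cohort_config(80, seed = 2, adherence_probability = 1,
                       ltfu_monthly_probability = 0)
  coh <- simulate_cohort(cfg)
  cm <- as_randomized_trial(clone_and_follow(coh, screen_eligibility(coh)),
                            coh)
  w <- estimate_ipcw(cm)
  expect_identical(unique(w$weight), 1)
  expect_false(any(w$truncated))
})

predict_uncensored_for_test <- function(model, newdata) {
  as.numeric(predict(model, newdata = newdata, type = "response"))
}

test_that("saturated denominator model recovers known censoring probabilities", {
  # covariate TRUE: half censored; covariate FALSE: none censored
  dat <- censor_fixture(8, censored = c(TRUE, FALSE, TRUE, FALSE,
                                        rep(FALSE, 4)),
                        covariate = c(rep(TRUE, 4), rep(FALSE, 4)))
  fit <- fit_censoring_model(dat, arm = 1L,
                             denominator_formula = ~ on_prophylaxis,
                             numerator_formula = ~ 1)
  p <- predict_uncensored_for_test(fit$denominator,
                                   data.frame(on_prophylaxis = c(TRUE, FALSE)))
  expect_equal(p[1], 0.5, tolerance = 1e-6)
  expect_equal(p[2], 1.0, tolerance = 1e-3)  # boundary MLE
  # intercept-only numerator on 25% censored rows: Bernoulli MLE 0.75
  pn <- predict_uncensored_for_test(fit$numerator,
                                    data.frame(on_prophylaxis = TRUE))
  expect_equal(pn, 0.75, tolerance = 1e-8)
})

test_that("stabilized weights are the cumulative product of monthly ratios", {
  # numerator identically 1, denominator identically 0.8 -> ratio 1.25
  den_dat <- censor_fixture(10, censored = rep(c(TRUE, FALSE),
                                               c(2, 8)),
                            covariate = TRUE)
  den <- suppressWarnings(glm(I(!censored_ice) ~ 1, binomial(),
                              data = den_dat))
  fit <- structure(list(numerator = "none", denominator = den, arm = 1L),
                   class = "censor_fit")
  fit2 <- structure(list(numerator = "none", denominator = "none",
                         arm = 2L), class = "censor_fit")
  clone <- data.frame(patient_id = "X", clone_arm = 1L, month = 0:2,
                      cd4 = 150, rna = 50, on_prophylaxis = TRUE,
                      event = FALSE, event_pcp = FALSE, event_death = FALSE,
                      censored_ice = FALSE, censored_ltfu = FALSE,
                      admin_end = c(FALSE, FALSE, TRUE), imputed = FALSE)
  w <- compute_stabilized_weights(list(fit, fit2), clone,
                                  truncation_percentile = 1)
  expect_equal(w$weight, c(1.25, 1.5625, 1.953125), tolerance = 1e-9)
})

test_that("numerator == denominator stabilizes every weight to one", {
  dat <- censor_fixture(20, censored = rep(c(TRUE, FALSE), 10),
                        covariate = TRUE)
  dat$clone_arm <- rep(1:2, each = 10)
  fits <- lapply(1:2, function(a)
    fit_censoring_model(dat, a, denominator_formula = ~ 1,
                        numerator_formula = ~ 1))
  w <- compute_stabilized_weights(fits, dat, truncation_percentile = 1)
  expect_equal(w$weight, rep(1, 20), tolerance = 1e-12)
})

test_that("positivity violations and truncation are enforced", {
  dat <- censor_fixture(20, censored = rep(c(TRUE, FALSE), 10),
                        covariate = TRUE)
  dat$clone_arm <- rep(1:2, each = 10)
  fits <- lapply(1:2, function(a)
    fit_censoring_model(dat, a, denominator_formula = ~ 1,
                        numerator_formula = ~ 1))
  expect_error(compute_stabilized_weights(fits, dat,
                                          positivity_floor = 0.9),
               "positivity")
  # growing weights capped at the configured percentile and flagged
  den_dat <- censor_fixture(10, censored = rep(c(TRUE, FALSE), c(2, 8)),
                            covariate = TRUE)
  den <- suppressWarnings(glm(I(!censored_ice) ~ 1, binomial(),
                              data = den_dat))
  fit1 <- structure(list(numerator = "none", denominator = den, arm = 1L),
                    class = "censor_fit")
  fit2 <- structure(list(numerator = "none", denominator = "none",
                         arm = 2L), class = "censor_fit")
  clone <- data.frame(patient_id = "X", clone_arm = 1L, month = 0:2,
                      cd4 = 150, rna = 50, on_prophylaxis = TRUE,
                      event = FALSE, event_pcp = FALSE, event_death = FALSE,
                      censored_ice = FALSE, censored_ltfu = FALSE,
                      admin_end = c(FALSE, FALSE, TRUE), imputed = FALSE)
  w <- compute_stabilized_weights(list(fit1, fit2), clone,
                                  truncation_percentile = 0.5)
  expect_equal(w$weight, c(1.25, 1.5625, 1.5625), tolerance = 1e-9)
  expect_identical(w$truncated, c(FALSE, FALSE, TRUE))
})

test_that("mean stabilized weight stays near one under a correct model", {
  # controlled world: censoring hazard expit(-2 + 1.2 * on_prophylaxis),
  # exactly the covariate the denominator model sees
  set.seed(77)
  n <- 600; horizon <- 10
  rows <- list()
  for (arm in 1:2) for (i in seq_len(n)) {
    proph <- runif(horizon) < 0.5
    p_cens <- plogis(-2 + 1.2 * proph)
    cens_at <- which(runif(horizon) < p_cens)[1]
    last <- min(cens_at, horizon, na.rm = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = sprintf("M%d_%04d", arm, i), clone_arm = arm,
      month = seq_len(last) - 1L, cd4 = 150, rna = 50,
      on_prophylaxis = proph[seq_len(last)], event = FALSE,
      event_pcp = FALSE, event_death = FALSE,
      censored_ice = c(rep(FALSE, last - 1L),
                       !is.na(cens_at) && cens_at == last),
      censored_ltfu = FALSE,
      admin_end = c(rep(FALSE, last - 1L), is.na(cens_at)),
      imputed = FALSE)
  }
  cm <- do.call(rbind, rows)
  w <- estimate_ipcw(cm, denominator_formula = ~ on_prophylaxis + month,
                     numerator_formula = ~ month,
                     truncation_percentile = 1)
  at_risk <- !w$censored_ice
  mw <- tapply(w$weight[at_risk], w$month[at_risk], mean)
  nn <- tapply(w$weight[at_risk], w$month[at_risk], length)
  expect_true(all(abs(mw[nn > 200] - 1) < 0.1))
  # monotone construction: weight(t) = weight(t-1) * ratio(t) exactly
  ord <- order(w$patient_id, w$clone_arm, w$month)
  ws <- w[ord, ]
  same_clone <- duplicated(paste(ws$patient_id, ws$clone_arm))
  ratio <- ws$p_uncensored_numerator / ws$p_uncensored_denominator
  lagged <- c(NA, ws$weight[-nrow(ws)])
  expect_equal(ws$weight[same_clone],
               (lagged * ratio)[same_clone], tolerance = 1e-12)
})
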