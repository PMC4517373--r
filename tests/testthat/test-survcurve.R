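test_that("Kaplan-Meier matches the hand product-limit on a toy set", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$estimate, c(2 / 3, 1 / 3, 0))
  # Greenwood at the first event time: (2/3)^2 * 1/(3*2)
  expect_equal(km$variance[1], (2 / 3)^2 / 6, tolerance = 1e-12)
  # all censored -> flat at 1
  flat <- km_curve(c(5, 6, 7), c(0, 0, 0))
  expect_length(flat$time, 0L)
  expect_equal(eval_curve(flat, c(1, 10))$estimate, c(1, 1))
})

test_that("Kaplan-Meier agrees with an independent hand computation", {
  set.seed(10)
  time <- sample(1:40, 25, replace = TRUE)
  event <- rbinom(25, 1, 0.6)
  km <- km_curve(time, event)
  hk <- hand_km(time, event)
  expect_equal(km$time, hk$time)
  expect_equal(km$estimate, hk$surv, tolerance = 1e-12)
  keep <- hk$surv > 0
  expect_equal(km$variance[keep], hk$var[keep], tolerance = 1e-12)
})

test_that("censoring beyond the last event adds no step and can move freely", {
  a <- km_curve(c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 0))
  b <- km_curve(c(1, 2, 3, 4, 9), c(1, 1, 0, 1, 0))
  # a censored observation after the last event contributes only its
  # at-risk presence; its exact time is irrelevant and adds no grid point
  expect_equal(a$time, b$time)
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$variance, b$variance)
  expect_equal(eval_curve(a, 100)$estimate, a$estimate[length(a$estimate)])
})

test_that("cause-specific KM censors other-cause deaths", {
  coh <- toy_cohort()
  cs <- cs_km_curve(coh$followup_days, coh$dead, coh$cause)
  # events at 300 and 600 only; other-cause deaths at 200/500 censored
  hk <- hand_km(coh$followup_days,
                as.integer(coh$dead == 1 & coh$cause == "prostate" &
                             !is.na(coh$cause)))
  expect_equal(cs$time, hk$time)
  expect_equal(cs$estimate, hk$surv, tolerance = 1e-12)
  # all causes prostate -> identical to the overall KM
  all_p <- coh
  all_p$cause[all_p$dead == 1] <- "prostate"
  cs2 <- cs_km_curve(all_p$followup_days, all_p$dead, all_p$cause)
  ov <- km_curve(coh$followup_days, coh$dead)
  expect_equal(cs2$estimate, ov$estimate)
  expect_equal(cs2$variance, ov$variance)
  # all deaths other-cause -> flat at 1
  all_o <- coh
  all_o$cause[all_o$dead == 1] <- "other"
  cs3 <- cs_km_curve(all_o$followup_days, all_o$dead, all_o$cause)
  expect_length(cs3$time, 0L)
  # incomplete causes are refused
  bad <- coh; bad$cause[2] <- NA
  expect_error(cs_km_curve(bad$followup_days, bad$dead, bad$cause),
               "impute first")
})

test_that("Aalen-Johansen CIFs match the hand computation and conserve", {
  coh <- toy_cohort()
  cc <- cuminc_curves(coh$followup_days, coh$dead, coh$cause)
  status <- ifelse(coh$dead == 0, 0,
                   ifelse(coh$cause == "prostate", 1, 2))
  hp <- hand_cif(coh$followup_days, status, 1)
  ho <- hand_cif(coh$followup_days, status, 2)
  expect_equal(cc$cif$estimate, hp$cif, tolerance = 1e-12)
  expect_equal(cc$cif_competing$estimate, ho$cif, tolerance = 1e-12)
  # conservation: S_overall + sum of CIFs = 1 at every grid time
  ov <- eval_curve(cc$overall, cc$cif$time)$estimate
  expect_equal(ov + cc$cif$estimate + cc$cif_competing$estimate,
               rep(1, length(ov)), tolerance = 1e-12)
  # 1 - CIF is the reported competing-risks survival
  expect_equal(cc$surv$estimate, 1 - cc$cif$estimate)
})

test_that("single-cause cumulative incidence reduces to 1 - KM", {
  set.seed(11)
  time <- sample(1:50, 30, replace = TRUE)
  dead <- rbinom(30, 1, 0.5)
  cause <- ifelse(dead == 1, "prostate", NA)
  cc <- cuminc_curves(time, dead, cause)
  km <- km_curve(time, dead)
  at <- eval_curve(km, cc$cif$time)$estimate
  expect_equal(cc$cif$estimate, 1 - at, tolerance = 1e-12)
})

test_that("conservation holds on larger simulated cohorts", {
  g <- generate_cohort(n = 800, seed = 21, missing_covariates = FALSE)
  coh <- g$complete
  cc <- cuminc_curves(coh$followup_days, coh$dead, coh$cause)
  ov <- eval_curve(cc$overall, cc$cif$time)$estimate
  expect_equal(ov + cc$cif$estimate + cc$cif_competing$estimate,
               rep(1, length(ov)), tolerance = 1e-12)
})

test_that("curve evaluation is right-continuous with LVCF", {
  cv <- survcurve(c(2, 5), c(0.8, 0.5), c(0.01, 0.02))
  got <- eval_curve(cv, c(1, 2, 3, 5, 100))
  expect_equal(got$estimate, c(1, 0.8, 0.8, 0.5, 0.5))
  expect_equal(got$variance, c(0, 0.01, 0.01, 0.02, 0.02))
})
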