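small_cohort <- function(n = 250, seed = 60) generate_cohort(n, seed = seed)

test_that("a complete cohort yields m identical copies", {
  comp <- generate_cohort(n = 120, seed = 61,
                          missing_covariates = FALSE)$complete
  fit <- mice_impute(comp, m = 3, maxit = 2, seed = 1)
  expect_length(fit$active, 0L)
  for (i in 2:3)
    expect_identical(complete_data(fit, i), complete_data(fit, 1))
  expect_identical(complete_data(fit, 1)[names(comp)][1:16],
                   misurv:::add_derived(as.data.frame(comp))[1:16])
})

test_that("the chained equations are deterministic under a fixed seed", {
  coh <- small_cohort()$cohort
  a <- mice_impute(coh, m = 2, maxit = 2, seed = 99)
  b <- mice_impute(coh, m = 2, maxit = 2, seed = 99)
  expect_identical(a$imputations, b$imputations)
  expect_identical(a$chain_mean, b$chain_mean)
  c2 <- mice_impute(coh, m = 2, maxit = 2, seed = 100)
  expect_false(identical(a$imputations, c2$imputations))
})

test_that("observed values are never altered and domains are respected", {
  g <- small_cohort(300, 62)
  coh <- g$cohort
  fit <- mice_impute(coh, m = 3, maxit = 3, seed = 7)
  for (i in 1:3) {
    d <- complete_data(fit, i)
    for (v in fit$active) {
      obs <- !is.na(coh[[v]])
      expect_identical(as.character(d[[v]][obs]),
                       as.character(coh[[v]][obs]), label = v)
    }
    # cause defined exactly for the dead
    expect_false(anyNA(d$cause[d$dead == 1]))
    expect_true(all(is.na(d$cause[d$dead == 0])))
    # pT/pN defined exactly for (current) surgical patients
    surg <- d$first_treatment == "surgery"
    expect_false(anyNA(d$pT[surg]))
    expect_true(all(is.na(d$pT[!surg])))
    expect_false(anyNA(d$pN[surg]))
    expect_true(all(is.na(d$pN[!surg])))
    # imputed categories stay inside the observed support
    expect_true(all(d$cause[d$dead == 1] %in% c("prostate", "other")))
    # passive consistency
    der <- derive_covariates(d)
    expect_identical(as.character(d$T_new), as.character(der$T_new))
    expect_identical(d$N_new, der$N_new)
    expect_identical(as.character(d$damico_group),
                     as.character(der$damico_group))
  }
})

test_that("gelman-rubin statistic behaves at its landmarks", {
  # all chains constant and equal -> 1 (with warning)
  flat <- matrix(5, nrow = 10, ncol = 4)
  expect_warning(r <- rhat(flat), "zero within-chain")
  expect_equal(r, 1)
  # i.i.d. chains from one distribution stay below 1.1 almost always
  set.seed(63)
  ok <- replicate(100, rhat(matrix(rnorm(20 * 20), 20, 20)) < 1.1)
  expect_gte(mean(ok), 0.95)
  # disjoint chains blow up: between-variance dominates
  set.seed(64)
  far <- cbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 10), 20, 2))
  expect_gt(rhat(far), 3)
})

test_that("chains on MAR synthetic data converge by the 1.1 rule", {
  cfg <- generator_config(700, mechanism = "MAR")
  g <- generate_cohort(config = cfg, seed = 65)
  fit <- mice_impute(g$cohort, m = 5, maxit = 8, seed = 3)
  r <- rhat(fit)
  expect_true(all(r < 1.25))
  expect_lt(median(r), 1.1)
})

test_that("observed-vs-imputed comparison reports the printed layout", {
  # observed split 106/55 prints as 65.8% / 34.2%
  expect_equal(misurv:::round_half_up(100 * 106 / 161, 1), 65.8)
  expect_equal(misurv:::round_half_up(100 * 55 / 161, 1), 34.2)
  g <- small_cohort(400, 66)
  fit <- mice_impute(g$cohort, m = 4, maxit = 3, seed = 11)
  cmp <- compare_observed_imputed(fit, "cause")
  tab <- cmp$table
  obs_tab <- table(g$cohort$cause[g$cohort$dead == 1])
  expect_equal(tab$observed, as.integer(obs_tab))
  expect_equal(tab$observed_pct,
               misurv:::round_half_up(100 * as.integer(obs_tab) /
                                        sum(obs_tab), 1))
  expect_true(all(tab$imputed_min <= tab$imputed_median))
  expect_true(all(tab$imputed_median <= tab$imputed_max))
  n_missing_cause <- sum(fit$where[, "cause"])
  expect_equal(sum(tab$imputed_mean), n_missing_cause)
  expect_error(compare_observed_imputed(fit, "age_at_diagnosis"),
               "not imputed")
})

test_that("chi-square comparison flags a constructed shift", {
  # identical distributions -> p near 1
  p_same <- suppressWarnings(
    chisq.test(cbind(c(100, 50), c(100, 50)))$p.value)
  expect_gt(p_same, 0.99)
  # strong constructed shift -> small p
  p_shift <- suppressWarnings(
    chisq.test(cbind(c(100, 50), c(40, 110)))$p.value)
  expect_lt(p_shift, 0.05)
})

test_that("imputed cause proportions are calibrated under MAR", {
  # MAR masking tied to diagnosis year; the imputation model sees the year
  # only through correlated covariates, the calibration is on proportions
  cfg <- generator_config(1500, mechanism = "MAR")
  g <- generate_cohort(config = cfg, seed = 67)
  coh <- g$cohort
  dead <- coh$dead == 1
  true_prop <- mean(g$truth$true_cause[dead] == "prostate")
  fit <- mice_impute(coh, m = 10, maxit = 5, seed = 21)
  props <- vapply(fit$imputations, function(d)
    mean(d$cause[d$dead == 1] == "prostate"), 0)
  pooled_prop <- mean(props)
  n_dead <- sum(dead)
  mc_se <- sqrt(true_prop * (1 - true_prop) / n_dead)
  expect_lt(abs(pooled_prop - true_prop), 4 * mc_se)
})
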