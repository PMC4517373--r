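test_that("read_cohort excludes zero-follow-up records and counts them", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(toy_cohort())[1:3, ]
  df$followup_days[2] <- 0
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "")
  expect_message(coh <- read_cohort(path), "excluded 1 record")
  expect_equal(nrow(coh), 2L)
  expect_equal(attr(coh, "n_excluded"), 1L)
})

test_that("cohort validation rejects invariant violations", {
  df <- as.data.frame(toy_cohort())
  bad <- df; bad$cause[1] <- "prostate"      # cause but dead = 0
  expect_error(cohort(bad), "not recorded as dead")
  bad <- df; bad$pT[2] <- "2a"               # pT without surgery
  expect_error(cohort(bad), "not surgery")
  bad <- df; bad$followup_days[3] <- 0
  expect_error(cohort(bad), "followup_days")
  bad <- df; bad$cT <- as.character(bad$cT); bad$cT[1] <- "9z"
  expect_error(cohort(bad), "unknown level")
  bad <- df; bad$id[2] <- bad$id[1]
  expect_error(cohort(bad), "duplicate")
})

test_that("cohort round-trips through delimited text field-for-field", {
  coh <- generate_cohort(n = 40, seed = 5)$cohort
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  for (col in misurv:::COHORT_COLUMNS) {
    expect_equal(back[[col]], coh[[col]], tolerance = 1e-8,
                 ignore_attr = TRUE, label = col)
  }
})

test_that("cause-of-death coding follows the part-1 mention rule", {
  out <- code_cause_of_death(
    raw_cause = c("prostate", "cardiac", NA, NA, "copd"),
    part1_mentions_cancer = c(0, 1, 0, 1, 0))
  expect_equal(as.character(out),
               c("prostate", "prostate", NA, "prostate", "other"))
})

test_that("derived covariates follow the surgery rule", {
  d <- derive_covariates(toy_cohort())
  # surgery rows take pT/pN, others fall back to cT/cN
  expect_equal(as.character(d$T_new), c("2a", "2a", "3a", "2b", "2b", "4"))
  expect_equal(d$N_new, c(0L, 0L, 1L, 0L, 0L, 1L))
})

test_that("d'Amico grouping matches the documented rule table", {
  expect_equal(as.character(damico_group(5, "low", "1c", 0, 0)), "low")
  expect_equal(as.character(damico_group(15, "low", "1c", 0, 0)),
               "intermediate")
  expect_equal(as.character(damico_group(5, "intermediate", "2b", 0, 0)),
               "intermediate")
  expect_equal(as.character(damico_group(25, "low", "1c", 0, 0)),
               "high+locally advanced")
  expect_equal(as.character(damico_group(5, "high", "1c", 0, 0)),
               "high+locally advanced")
  expect_equal(as.character(damico_group(5, "low", "3a", 0, 0)),
               "high+locally advanced")
  # nodal/metastatic disease overrides everything
  expect_equal(as.character(damico_group(5, "low", "1c", 1, 0)), "N+M+")
  expect_equal(as.character(damico_group(80, "high", "4", 0, 1)), "N+M+")
  # undecidable on partial data unless already N+/M+ or high
  expect_true(is.na(damico_group(5, NA, "1c", 0, 0)))
  expect_equal(as.character(damico_group(25, NA, "1c", 0, 0)),
               "high+locally advanced")
})

test_that("derive_covariates is deterministic and total on complete input", {
  coh <- generate_cohort(n = 100, seed = 2, missing_covariates = FALSE)$complete
  d1 <- derive_covariates(coh)
  d2 <- derive_covariates(coh)
  expect_identical(d1, d2)
  expect_false(anyNA(d1$T_new))
  expect_false(anyNA(d1$damico_group))
})

test_that("missingness summary reproduces printed count arithmetic", {
  # 161 missing causes among 322 deceased is 50.0%; 177 of 2844 is 6.2%
  expect_equal(misurv:::round_half_up(100 * 161 / 322, 1), 50.0)
  expect_equal(misurv:::round_half_up(100 * 177 / 2844, 1), 6.2)
  coh <- toy_cohort()
  ms <- missingness_summary(coh)
  expect_equal(ms$n_missing[ms$variable == "cause"], 0L)
  expect_equal(ms$percent[ms$variable == "cause"], 0)
  expect_equal(ms$denominator[ms$variable == "cause"], 4)  # deceased only
  expect_equal(ms$denominator[ms$variable == "pT"], 2)     # surgery only
  # percent times denominator recovers the count within rounding
  coh2 <- generate_cohort(n = 500, seed = 9)$cohort
  ms2 <- missingness_summary(coh2)
  back <- ms2$percent * ms2$denominator / 100
  expect_true(all(abs(back - ms2$n_missing) <=
                    0.05 * ms2$denominator / 100 + 1e-9))
})

test_that("follow-up helper subtracts ISO dates in days", {
  expect_equal(followup_days("2003-01-01", "2003-01-31"), 30L)
})
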