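test_that("Fisher p-values match hypergeometric enumeration", {
  # the 2x2 table [[3,1],[1,3]]
  d <- data.frame(target = c(rep(NA, 4), rep(1, 4)),
                  comp = c("a", "a", "a", "b", "a", "b", "b", "b"))
  rep_ <- dixon_battery(d, "target", "comp", p_adjust = "none")
  # enumeration: P(X = k) for k successes in the first margin
  pk <- dhyper(0:4, 4, 4, 4)
  p_exact <- sum(pk[pk <= pk[4] + 1e-12])     # observed k = 3
  expect_equal(rep_$p_value[1], p_exact, tolerance = 1e-10)
  expect_equal(rep_$p_value[1], 34 / 70, tolerance = 1e-10)
  expect_equal(rep_$test[1], "fisher-exact")
})

test_that("Fisher p-values agree with enumeration on random 2x2 tables", {
  set.seed(50)
  for (rep_i in 1:20) {
    n <- sample(8:40, 1)
    miss <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(miss)) < 2) next
    comp <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(comp)) < 2) next
    d <- data.frame(target = ifelse(miss, NA, 1), comp = comp)
    got <- dixon_battery(d, "target", "comp", p_adjust = "none")$p_value[1]
    tab <- table(comp, miss)
    # full enumeration over the hypergeometric support
    k_obs <- tab[1, 1]
    m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); cs <- sum(tab[, 1])
    support <- max(0, cs - m2):min(m1, cs)
    pk <- dhyper(support, m1, m2, cs)
    p_enum <- sum(pk[pk <= pk[match(k_obs, support)] * (1 + 1e-7)])
    expect_equal(got, p_enum, tolerance = 1e-8)
  }
})

test_that("continuous companions use Mann-Whitney and detect shifts", {
  set.seed(51)
  n <- 200
  miss <- rbinom(n, 1, 0.4) == 1
  shifted <- rnorm(n) + 3 * miss          # 3 SD shift
  d <- data.frame(target = ifelse(miss, NA, 1), shifted = shifted)
  rep_ <- dixon_battery(d, "target", "shifted")
  expect_equal(rep_$test[1], "mann-whitney")
  expect_lt(rep_$p_adjusted[1], 0.05)
  expect_equal(attr(rep_, "verdict"), "evidence-against-MCAR")
})

test_that("MCAR-by-construction data is usually judged MCAR", {
  set.seed(52)
  verdicts <- replicate(60, {
    n <- 150
    d <- data.frame(target = ifelse(rbinom(n, 1, 0.3) == 1, NA, 1),
                    x1 = rnorm(n),
                    x2 = factor(sample(c("a", "b", "c"), n, TRUE)))
    attr(dixon_battery(d, "target", c("x1", "x2")), "verdict")
  })
  expect_gte(mean(verdicts == "consistent-with-MCAR"), 0.9)
})

test_that("per-test type-I error is near alpha without multiplicity", {
  set.seed(53)
  hits <- replicate(400, {
    n <- 120
    d <- data.frame(target = ifelse(rbinom(n, 1, 0.4) == 1, NA, 1),
                    x = rnorm(n))
    dixon_battery(d, "target", "x", p_adjust = "none")$p_value[1] < 0.05
  })
  mc_se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(hits) - 0.05), 2.5 * mc_se + 0.01)
})

test_that("constant companions are skipped with a note", {
  d <- data.frame(target = c(NA, NA, 1, 1), k = rep(5, 4))
  rep_ <- dixon_battery(d, "target", "k")
  expect_equal(rep_$test[1], "skipped")
})

test_that("baseline-by-missingness table keeps its books", {
  coh <- generate_cohort(n = 600, seed = 54)$cohort
  tab <- baseline_by_missingness(coh, "cause",
                                 c("gleason_group", "first_treatment"))
  for (v in unique(tab$covariate)) {
    sub <- tab[tab$covariate == v, ]
    dead <- coh[coh$dead == 1, ]
    expect_equal(sum(sub$n_observed), sum(!is.na(dead$cause)))
    expect_equal(sum(sub$n_missing), sum(is.na(dead$cause)))
    expect_equal(sub$n_total, sub$n_observed + sub$n_missing)
  }
})

test_that("chi-square in the baseline table matches the textbook formula", {
  # hand-built 2x3 contingency table
  tab <- matrix(c(10, 20, 30, 15, 25, 20), nrow = 3)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_counts)^2 / exp_counts)
  p_hand <- pchisq(stat, df = 2, lower.tail = FALSE)
  miss <- rep(c(FALSE, TRUE), times = c(sum(tab[, 1]), sum(tab[, 2])))
  lev <- c(rep(c("a", "b", "c"), times = tab[, 1]),
           rep(c("a", "b", "c"), times = tab[, 2]))
  d <- data.frame(target = ifelse(miss, NA, 1), v = lev)
  got <- baseline_by_missingness(d, "target", "v")
  expect_equal(got$chisq_p[1], p_hand, tolerance = 1e-6)
})
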