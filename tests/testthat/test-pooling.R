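test_that("complementary log-log transform and inverse are exact", {
  expect_equal(cll_transform(0.5), log(-log(0.5)), tolerance = 1e-15)
  expect_equal(cll_transform(0.5), -0.36651292, tolerance = 1e-7)
  for (s in c(0.1, 0.3, 0.9))
    expect_equal(cll_back(cll_transform(s)), s, tolerance = 1e-12)
  expect_gt(cll_transform(0.6), cll_transform(0.5))
  expect_error(cll_transform(1.2), "lie in")
  expect_error(cll_transform(-0.1), "lie in")
})

test_that("delta-method variance matches the printed formula and a
           finite-difference oracle", {
  expect_equal(delta_variance(0.5, 0), 0)
  expect_equal(delta_variance(0.5, 0.01),
               0.01 / (log(0.5) * 0.5)^2, tolerance = 1e-12)
  expect_equal(delta_variance(0.5, 0.01), 0.08325476, tolerance = 1e-7)
  # numerical g'(S)^2 * var oracle
  h <- 1e-6
  for (s in seq(0.2, 0.95, by = 0.05)) {
    gprime <- (cll_transform(s + h) - cll_transform(s - h)) / (2 * h)
    expect_equal(delta_variance(s, 0.004), gprime^2 * 0.004,
                 tolerance = 1e-8)
  }
  expect_error(delta_variance(0.5, -1), "nonnegative")
})

test_that("Rubin's rules match hand arithmetic", {
  got <- rubin_pool(c(0, 2), c(1, 1))
  expect_equal(got$Q_bar, 1)
  expect_equal(got$U_bar, 1)
  expect_equal(got$B, 2)
  expect_equal(got$T_total, 1 + 1.5 * 2)
  # identical imputations: between-variance vanishes
  same <- rubin_pool(rep(0.4, 5), rep(0.2, 5))
  expect_equal(same$B, 0)
  expect_equal(same$T_total, 0.2)
  expect_error(rubin_pool(1, 1), "m >= 2")
  # large-m limit: T -> U_bar + B
  set.seed(40)
  q <- rnorm(1e4); u <- runif(1e4, 0.5, 1.5)
  big <- rubin_pool(q, u)
  expect_equal(big$T_total, big$U_bar + big$B, tolerance = 1e-3)
})

test_that("pooled curves match an end-to-end hand computation", {
  c1 <- survcurve(c(10, 20), c(0.9, 0.8), c(0.004, 0.006),
                  kind = "cause-specific-km")
  c2 <- survcurve(c(15, 20), c(0.85, 0.7), c(0.005, 0.008),
                  kind = "cause-specific-km")
  pooled <- pool_curves(list(c1, c2))
  expect_equal(pooled$time, c(10, 15, 20))
  # hand computation through the pooling equations at each union-grid time
  S <- rbind(c(0.9, 1), c(0.9, 0.85), c(0.8, 0.7))
  V <- rbind(c(0.004, 0), c(0.004, 0.005), c(0.006, 0.008))
  eps <- 1e-10
  Sc <- pmin(pmax(S, eps), 1 - eps)
  Q <- log(-log(1 - Sc))
  U <- pmax(V / (log(1 - Sc) * (1 - Sc))^2, 1e-12)
  Qbar <- rowMeans(Q)
  Ubar <- rowMeans(U)
  B <- apply(Q, 1, var)
  Tt <- Ubar + 1.5 * B
  expect_equal(pooled$Q_bar, Qbar, tolerance = 1e-12)
  expect_equal(pooled$U_bar, Ubar, tolerance = 1e-12)
  expect_equal(pooled$B, B, tolerance = 1e-12)
  expect_equal(pooled$T_total, Tt, tolerance = 1e-12)
  expect_equal(pooled$S, 1 - exp(-exp(Qbar)), tolerance = 1e-12)
  z <- qnorm(0.975)
  expect_equal(pooled$ci_low, 1 - exp(-exp(Qbar - z * sqrt(Tt))),
               tolerance = 1e-12)
  expect_equal(pooled$ci_high, 1 - exp(-exp(Qbar + z * sqrt(Tt))),
               tolerance = 1e-12)
  # order correctness
  expect_true(all(pooled$ci_low <= pooled$S & pooled$S <= pooled$ci_high))
})

test_that("pooling m identical curves returns the curve itself", {
  cv <- survcurve(c(5, 9), c(0.95, 0.6), c(0.001, 0.01),
                  kind = "cause-specific-km")
  pooled <- pool_curves(list(cv, cv, cv))
  expect_equal(pooled$S, cv$estimate, tolerance = 1e-9)
  expect_equal(pooled$B, c(0, 0))
  expect_equal(pooled$T_total, pooled$U_bar)
})

test_that("pooling is permutation invariant and monotone", {
  set.seed(41)
  curves <- lapply(1:5, function(i) {
    tm <- sort(sample(1:60, 8))
    s <- cumprod(runif(8, 0.85, 0.99))
    survcurve(tm, s, runif(8, 1e-4, 1e-3), kind = "cause-specific-km")
  })
  a <- pool_curves(curves)
  b <- pool_curves(rev(curves))
  expect_equal(a$S, b$S, tolerance = 1e-14)
  expect_equal(a$T_total, b$T_total, tolerance = 1e-14)
  # each input nonincreasing -> pooled nonincreasing
  expect_true(all(diff(a$S) <= 1e-12))
})

test_that("grid points before every first event pass through as 1", {
  c1 <- survcurve(c(10, 30), c(1, 0.8), c(0, 0.004),
                  kind = "cause-specific-km")
  c2 <- survcurve(c(20, 30), c(0.9, 0.7), c(0.003, 0.005),
                  kind = "cause-specific-km")
  pooled <- pool_curves(list(c1, c2))
  expect_equal(pooled$S[1], 1)
  expect_equal(pooled$ci_low[1], 1)
  expect_equal(pooled$ci_high[1], 1)
  expect_true(pooled$S[2] < 1)
  # inconsistent kinds are refused
  c3 <- survcurve(5, 0.5, 0.01, kind = "cif")
  expect_error(pool_curves(list(c1, c3)), "inconsistent")
})

test_that("relative efficiency follows the closed form", {
  expect_equal(relative_efficiency(0, U_bar = 1, m = 5)$mean, 1)
  # gamma = 0.3 at m = 10 -> RE = 1/1.03
  B <- 0.3; m <- 10
  T_total <- (B + B / m) / 0.3          # makes gamma exactly 0.3
  U_bar <- T_total - (1 + 1 / m) * B
  got <- relative_efficiency(B, U_bar = U_bar, m = m)
  expect_equal(got$mean, 1 / 1.03, tolerance = 1e-12)
  # nondecreasing in m for fixed gamma
  re_m <- vapply(2:30, function(mm) 1 / (1 + 0.3 / mm), 0)
  expect_true(all(diff(re_m) > 0))
})
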