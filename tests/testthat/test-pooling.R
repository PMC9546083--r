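test_that("CE pooling matches closed forms", {
  e <- eff_df(c(0, 2), c(1, 1))
  ce <- pool_ce(e)
  expect_equal(ce$estimate, 1)
  expect_equal(ce$se, 1 / sqrt(2))
  expect_equal(ce$tau2, 0)
  expect_equal(ce$Q, 2)          # 1*(0-1)^2 + 1*(2-1)^2
  # single study is the identity
  one <- pool_ce(eff_df(0.7, 0.09))
  expect_equal(one$estimate, 0.7)
  expect_equal(one$se, 0.3)
  # duplicating a study k times divides its variance by k
  dup <- pool_ce(eff_df(rep(0.7, 4), rep(0.09, 4)))
  expect_equal(dup$se^2, 0.09 / 4)
})

test_that("REML tau2 has the equal-variance closed form and boundary", {
  expect_equal(as.numeric(reml_tau2(eff_df(c(0, 2), c(1, 1)))), 1,
               tolerance = 1e-8)
  expect_equal(as.numeric(reml_tau2(eff_df(c(1.3, 1.3, 1.3), c(1, 2, 3)))), 0)
  expect_error(reml_tau2(eff_df(1, 1)), class = "prepostMA_domain_error")
})

test_that("REML tau2 agrees with the grid-search oracle on random instances", {
  set.seed(2024)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    vi <- runif(k, 0.05, 2)
    yi <- rnorm(k, 0, sqrt(runif(1, 0, 2) + vi))
    t2 <- as.numeric(reml_tau2(eff_df(yi, vi)))
    t2_grid <- grid_reml(yi, vi, upper = 20, step = 1e-4)
    expect_equal(t2, t2_grid, tolerance = 2e-3)
  }
})

test_that("RE and Hartung-Knapp pooling match the worked closed forms", {
  e <- eff_df(c(0, 2), c(1, 1))
  re <- pool_re(e)
  expect_equal(re$tau2, 1, tolerance = 1e-8)
  expect_equal(re$estimate, 1)
  expect_equal(re$se, 1, tolerance = 1e-8)   # sum w* = 1
  hk <- pool_re(e, hk = TRUE)
  expect_equal(hk$se, 1, tolerance = 1e-8)
  expect_equal(hk$ci_high - hk$estimate, qt(0.975, 1), tolerance = 1e-6)
  # tau2 forced to 0 without HK reproduces CE exactly
  re0 <- pool_re(e, tau2 = 0)
  ce <- pool_ce(e)
  expect_equal(re0$estimate, ce$estimate)
  expect_equal(re0$se, ce$se)
})

test_that("heterogeneity statistics match the worked example", {
  e <- eff_df(c(0, 2), c(1, 1))
  h <- heterogeneity_stats(e, tau2 = 1)
  expect_equal(h$Q, 2)
  expect_equal(h$I2, 50)      # s2 = 1
  expect_equal(h$H2, 2)
  h0 <- heterogeneity_stats(e, tau2 = 0)
  expect_equal(h0$I2, 0)
  expect_equal(h0$H2, 1)
  expect_equal(heterogeneity_stats(eff_df(c(1, 1, 1), c(1, 2, 0.5)), 0)$Q, 0)
})

test_that("pooling is order-invariant and location-equivariant", {
  set.seed(77)
  yi <- rnorm(8); vi <- runif(8, 0.1, 1)
  e <- eff_df(yi, vi)
  perm <- sample(8)
  for (f in list(pool_ce, function(x) pool_re(x, hk = TRUE))) {
    a <- f(e); b <- f(e[perm, ])
    expect_equal(a$estimate, b$estimate, tolerance = 1e-10)
    expect_equal(a$se, b$se, tolerance = 1e-10)
    shifted <- f(eff_df(yi + 5, vi))
    expect_equal(shifted$estimate, a$estimate + 5, tolerance = 1e-8)
    expect_equal(shifted$se, a$se, tolerance = 1e-8)
  }
})

test_that("the untruncated HK interval is usually, not always, the wider one", {
  # the HK variance is deliberately untruncated, so in a minority of
  # small-k datasets the HK interval is narrower than the normal RE interval;
  # the width ordering holds in the large majority of replicates
  set.seed(404)
  wider <- replicate(200, {
    vi <- runif(9, 0.05, 0.6)
    yi <- rnorm(9, -0.5, sqrt(0.25 + vi))
    e <- eff_df(yi, vi)
    hk <- pool_re(e, hk = TRUE)
    re <- pool_re(e, tau2 = hk$tau2)
    (hk$ci_high - hk$ci_low) >= (re$ci_high - re$ci_low)
  })
  expect_gt(mean(wider), 0.75)
  expect_lt(mean(wider), 1)  # truncation would make this exactly 1
})

test_that("pooling_result invariants hold on random inputs", {
  set.seed(99)
  for (i in 1:25) {
    k <- sample(2:15, 1)
    e <- eff_df(rnorm(k, -0.5, 1), runif(k, 0.02, 1.5))
    r <- pool_re(e, hk = (i %% 2 == 0))
    expect_true(r$se > 0)
    expect_true(r$ci_low < r$estimate && r$estimate < r$ci_high)
    expect_gte(r$tau2, 0)
    expect_true(r$I2 >= 0 && r$I2 < 100)
    expect_gte(r$H2, 1)
  }
})
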