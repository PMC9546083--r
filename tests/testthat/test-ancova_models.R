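test_that("fit_trial_ancova matches the recovered closed form on the toy trial", {
  p <- generate_pseudo_ipd(toy_trial(), seed = 3)
  fit <- fit_trial_ancova(p)
  expect_equal(fit$estimate, -1.5, tolerance = 1e-10)
  expect_equal(fit$sigma2, 3.6, tolerance = 1e-10)
  expect_equal(fit$se, sqrt(1.95), tolerance = 1e-10)
  # identical arms -> zero coefficient
  ds0 <- toy_trial(); ds0$mean_F <- c(12, 12); ds0$mean_B <- c(10, 10)
  ds0$mean_CS <- ds0$mean_F - ds0$mean_B
  p0 <- generate_pseudo_ipd(ds0, seed = 4)
  expect_equal(fit_trial_ancova(p0)$estimate, 0, tolerance = 1e-10)
  # centring does not change the treatment coefficient
  p1 <- p; p1$y_baseline <- p1$y_baseline + 100
  expect_equal(fit_trial_ancova(p1)$estimate, fit$estimate, tolerance = 1e-8)
  expect_error(fit_trial_ancova(p[p$arm == "control", ]), "both arms",
               class = "prepostMA_domain_error")
})

test_that("twostage equals pooling the recovered estimates trial-for-trial", {
  ds <- sim_dataset(k = 6, n = 25, seed = 29, baseline_imbalance_sd = 2)
  p <- generate_pseudo_ipd(ds, seed = 8)
  eff <- compute_effects(ds, "ancova")
  for (cfg in list(list(model = "RE", hk = FALSE), list(model = "RE", hk = TRUE),
                   list(model = "CE", hk = FALSE))) {
    ts <- twostage(p, model = cfg$model, hk = cfg$hk)
    direct <- if (cfg$model == "RE") {
      pool_re(eff, hk = cfg$hk)
    } else {
      pool_ce(eff)
    }
    expect_equal(ts$theta$estimate, direct$estimate, tolerance = 1e-8)
    expect_equal(ts$theta$se, direct$se, tolerance = 1e-8)
    expect_equal(ts$theta$tau2, direct$tau2, tolerance = 1e-8)
  }
  # single-trial CE returns that trial's ANCOVA coefficient
  one <- generate_pseudo_ipd(toy_trial(), seed = 5)
  ts1 <- twostage(one, model = "CE")
  expect_equal(ts1$theta$estimate, -1.5, tolerance = 1e-10)
})

test_that("one-stage collapses to the per-trial ANCOVA for a single trial", {
  p <- generate_pseudo_ipd(toy_trial(), seed = 6)
  os <- fit_onestage(p, resid_structure = "single", model = "CE")
  ols <- fit_trial_ancova(p)
  expect_equal(os$theta, ols$estimate, tolerance = 1e-6)
  # same residual variance up to the REML/OLS df convention (identical here:
  # both use N - 3)
  expect_equal(unname(os$sigma^2), ols$sigma2, tolerance = 1e-4)
})

test_that("restricted log-likelihood matches the dense-matrix oracle", {
  ds <- sim_dataset(k = 3, n = 8, seed = 37)
  p <- generate_pseudo_ipd(ds, seed = 2)
  for (st in c("single", "arm", "study", "arm_study")) {
    m <- switch(st, single = 1, arm = 2, study = 3, arm_study = 6)
    sig <- seq(3, 5, length.out = m)
    for (tau in c(0, 0.7)) {
      expect_equal(
        onestage_reml_loglik(p, sig, tau, resid_structure = st),
        dense_reml_loglik(p, sig, tau, resid_structure = st),
        tolerance = 1e-8)
    }
  }
  # with interaction columns too
  expect_equal(
    onestage_reml_loglik(p, c(3, 4, 5), 0.5, "study", interaction = TRUE),
    dense_reml_loglik(p, c(3, 4, 5), 0.5, "study", interaction = TRUE),
    tolerance = 1e-8)
})

test_that("optimiser solution beats random perturbations and inflated sigmas", {
  ds <- sim_dataset(k = 4, n = 15, seed = 41)
  p <- generate_pseudo_ipd(ds, seed = 3)
  os <- fit_onestage(p, resid_structure = "study")
  ll_hat <- os$loglik_restricted
  set.seed(1)
  for (i in 1:100) {
    sig <- os$sigma * exp(rnorm(length(os$sigma), 0, 0.2))
    tau <- sqrt(os$tau2) * exp(rnorm(1, 0, 0.2)) + abs(rnorm(1, 0, 0.05))
    expect_lte(onestage_reml_loglik(p, sig, tau, "study"), ll_hat + 1e-6)
  }
  # monotone decrease for grossly inflated residual SDs
  lls <- vapply(c(1, 3, 10, 30), function(f) {
    onestage_reml_loglik(p, os$sigma * f, sqrt(os$tau2), "study")
  }, numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("structure nesting never decreases the maximised likelihood", {
  ds <- sim_dataset(k = 4, n = 12, seed = 43, resid_structure = "arm",
                    resid_sd = c(2, 4))
  p <- generate_pseudo_ipd(ds, seed = 5)
  ll <- vapply(c("single", "arm", "study", "arm_study"), function(st) {
    fit_onestage(p, resid_structure = st, model = "CE")$loglik_restricted
  }, numeric(1))
  expect_gte(ll[["arm"]], ll[["single"]] - 1e-6)
  expect_gte(ll[["study"]], ll[["single"]] - 1e-6)
  expect_gte(ll[["arm_study"]], ll[["arm"]] - 1e-6)
  expect_gte(ll[["arm_study"]], ll[["study"]] - 1e-6)
})

test_that("all one- and two-stage outputs are invariant to the pseudo seed", {
  ds <- sim_dataset(k = 5, n = 14, seed = 47)
  p1 <- generate_pseudo_ipd(ds, seed = 1)
  p2 <- generate_pseudo_ipd(ds, seed = 2)
  t1 <- twostage(p1, hk = TRUE, interaction = TRUE)
  t2 <- twostage(p2, hk = TRUE, interaction = TRUE)
  expect_equal(t1$theta$estimate, t2$theta$estimate, tolerance = 1e-8)
  expect_equal(t1$theta$se, t2$theta$se, tolerance = 1e-8)
  expect_equal(t1$interaction$estimate, t2$interaction$estimate,
               tolerance = 1e-8)
  o1 <- fit_onestage(p1, "study", interaction = TRUE)
  o2 <- fit_onestage(p2, "study", interaction = TRUE)
  expect_equal(o1$theta, o2$theta, tolerance = 1e-6)
  expect_equal(o1$se, o2$se, tolerance = 1e-6)
  expect_equal(o1$gamma_within, o2$gamma_within, tolerance = 1e-6)
})

test_that("one-stage agrees with nlme on a heteroscedastic CE fit", {
  skip_if_not_installed("nlme")
  ds <- sim_dataset(k = 4, n = 20, seed = 53, resid_structure = "study",
                    resid_sd = c(2, 3, 4, 5))
  p <- generate_pseudo_ipd(ds, seed = 7)
  os <- fit_onestage(p, resid_structure = "study", model = "CE")
  d <- do.call(rbind, lapply(split(as.data.frame(p), p$trial_id), function(x) {
    x$bc <- x$y_baseline - mean(x$y_baseline); x
  }))
  d$trial <- factor(d$trial_id)
  d$treat <- as.numeric(d$arm == "treatment")
  g <- nlme::gls(y_final ~ trial + trial:bc + treat, data = d,
                 weights = nlme::varIdent(form = ~ 1 | trial), method = "REML")
  expect_equal(os$theta, unname(coef(g)["treat"]), tolerance = 1e-5)
  expect_equal(os$se, sqrt(vcov(g)["treat", "treat"]), tolerance = 1e-4)
  expect_equal(os$loglik_restricted, as.numeric(stats::logLik(g)),
               tolerance = 1e-6)
})

test_that("arm-specific residual SDs are recovered at large N", {
  ipd <- simulate_ipd(k = 5, n_per_arm = 200, resid_structure = "arm",
                      resid_sd = c(1, 2), seed = 59)
  os <- fit_onestage(ipd, resid_structure = "arm")
  expect_equal(unname(os$sigma["control"]), 1, tolerance = 0.1)
  expect_equal(unname(os$sigma["treatment"]), 2, tolerance = 0.1)
})

test_that("degenerate requests produce clear errors", {
  ds <- sim_dataset(k = 2, n = 3, seed = 61)
  p <- generate_pseudo_ipd(ds, seed = 1)
  expect_error(fit_onestage(p, resid_structure = "arm_study"),
               class = "prepostMA_domain_error")
})
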