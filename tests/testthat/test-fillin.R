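test_that("scalar conversions follow the identities", {
  expect_equal(sd_from_se(0.5, 16), 2)
  expect_equal(sd_from_se(3.7, 1), 3.7)
  expect_equal(sd_from_se(1, 2), sqrt(2))
  expect_error(sd_from_se(-1, 4), class = "prepostMA_domain_error")

  expect_equal(correlation_from_sds(1, 1, 0), 1)
  expect_equal(correlation_from_sds(1, 1, sqrt(2)), 0)
  expect_equal(correlation_from_sds(2, 3, 2), 0.75)
  # implied r marginally above 1 (within 1e-8): clamped with a warning
  sdF_eps <- 1 + 1e-4
  sdCS_eps <- sqrt(sdF_eps^2 + 1 - 2 * (1 + 2e-9) * sdF_eps)
  expect_warning(rc <- correlation_from_sds(1, sdF_eps, sdCS_eps), "clamped")
  expect_equal(rc, 1)
  expect_error(correlation_from_sds(1, 1, 3), "cannot coexist|implied",
               class = "prepostMA_domain_error")

  expect_equal(sd_change_from_correlation(2, 2, 1), 0)
  expect_equal(sd_change_from_correlation(1, 1, 0), sqrt(2))
  expect_equal(sd_change_from_correlation(2, 3, 0.75), 2)
})

test_that("correlation <-> change-SD round trip is the identity", {
  set.seed(42)
  for (i in 1:50) {
    sdB <- runif(1, 0.1, 10); sdF <- runif(1, 0.1, 10)
    r <- runif(1, -1, 1)
    sdCS <- sd_change_from_correlation(sdB, sdF, r)
    if (sdCS > 0) {
      expect_equal(correlation_from_sds(sdB, sdF, sdCS), r, tolerance = 1e-12)
    }
  }
})

test_that("stepwise fills behave and are flagged in provenance", {
  ds <- sim_dataset(k = 3, n = 12, seed = 21)
  truth_sdF <- ds$sd_F
  ds$sd_F[1] <- NA
  out <- impute_sdF_equals_sdB(ds)
  expect_equal(out$sd_F[1], ds$sd_B[1])
  expect_equal(unname(provenance(out)[1, "sd_F"]), "imputed:sdF_equals_sdB")
  expect_equal(out$sd_F[-1], truth_sdF[-1])      # others untouched
  expect_equal(unname(provenance(out)[2, "sd_F"]), "observed")

  ds2 <- sim_dataset(k = 2, n = 12, seed = 22)
  ds2$mean_CS <- NA
  ds2$mean_F[2] <- NA
  ds2$mean_CS[2] <- -1; m_b <- ds2$mean_B[2]
  out2 <- fill_means(ds2)
  expect_equal(out2$mean_CS[1], out2$mean_F[1] - out2$mean_B[1])
  expect_equal(out2$mean_F[2], m_b - 1)

  # weighted-mean correlation imputation: (2*0.5 + 4*1.0)/6
  ds3 <- sim_dataset(k = 2, n = 12, seed = 23)
  ds3$n <- c(3, 5, 7, 9)
  ds3$r <- c(0.5, 1.0, NA, NA)
  out3 <- impute_missing_correlations(ds3, "weighted_mean")
  expect_equal(out3$r[3], 5 / 6)
  expect_equal(out3$r[4], 5 / 6)
  out3f <- impute_missing_correlations(ds3, "fixed", fixed_value = 0.5)
  expect_equal(out3f$r[3:4], c(0.5, 0.5))
  expect_equal(unname(provenance(out3f)[3, "r"]), "imputed:fixed")
  ds3$r <- NA
  expect_error(impute_missing_correlations(ds3, "weighted_mean"),
               "fixed", class = "prepostMA_domain_error")
})

test_that("run_fillin completes SE-only data and is idempotent", {
  ds <- sim_dataset(k = 4, n = 25, seed = 31)
  # SEs only, SDs deleted, change SD retained -> completed via sd_from_se
  masked <- ds
  for (q in c("B", "F")) {
    masked[[paste0("se_", q)]] <- masked[[paste0("sd_", q)]] / sqrt(masked$n)
    masked[[paste0("sd_", q)]] <- NA
  }
  masked$r <- NA
  res <- run_fillin(masked)
  expect_true(is_complete(res$dataset))
  expect_equal(res$dataset$sd_B, ds$sd_B, tolerance = 1e-10)
  expect_equal(res$dataset$r, ds$r, tolerance = 1e-10)

  # idempotence: running again changes nothing and everything is "observed"
  res2 <- run_fillin(res$dataset)
  for (cl in prepostMA:::NUMERIC_COLS) {
    expect_equal(res2$dataset[[cl]], res$dataset[[cl]], tolerance = 1e-12)
  }
  again <- run_fillin(meta_dataset(as.data.frame(res$dataset)))
  expect_true(all(again$provenance %in% c("observed", "missing")))

  # irrecoverable row -> error naming it
  hopeless <- ds
  hopeless$sd_B[1] <- NA; hopeless$sd_F[1] <- NA; hopeless$sd_CS[1] <- NA
  expect_error(run_fillin(hopeless), "trial01",
               class = "prepostMA_fillin_error")
})

test_that("masking recoverable cells is undone exactly", {
  ds <- sim_dataset(k = 6, n = 20, seed = 41)
  for (pat in c("drop_sdCS", "drop_r", "sd_to_se", "drop_sdF")) {
    m <- mask_summaries(ds, pat, fraction = 1, seed = 5)
    res <- run_fillin(m)
    tr <- attr(m, "masked")
    for (j in seq_len(nrow(tr))) {
      expect_equal(res$dataset[[tr$field[j]]][tr$row[j]], tr$value[j],
                   tolerance = 1e-10)
    }
  }
  # bookkeeping: filled cells = masked cells (all recoverable here)
  m <- mask_summaries(ds, "mixed", fraction = 0.5, seed = 6)
  res <- run_fillin(m)
  n_filled <- sum(startsWith(res$provenance, "calculated") |
                  startsWith(res$provenance, "imputed"))
  expect_gte(n_filled, nrow(attr(m, "masked")))
})
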