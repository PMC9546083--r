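test_that("read_dataset parses the template layout and preserves structure", {
  ds <- sim_dataset(k = 9, n = 20, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  rd <- read_dataset(path)
  expect_s3_class(rd, "meta_dataset")
  expect_equal(nrow(rd), 18)
  expect_equal(n_trials(rd), 9)
  expect_identical(rd$trial_id, ds$trial_id)  # row order preserved
  expect_true(is_complete(rd))
})

test_that("round trip write/read is the identity, with and without blanks", {
  ds <- sim_dataset(k = 2, n = 15, seed = 3)
  ds$r[2] <- NA; ds$sd_CS[3] <- NA  # blanks restored as missing
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  rd <- read_dataset(path)
  for (cl in names(ds)) expect_equal(rd[[cl]], ds[[cl]], tolerance = 1e-12)
})

test_that("schema, parse and structure errors are specific", {
  ds <- as.data.frame(sim_dataset(k = 2, n = 10, seed = 1))
  expect_error(meta_dataset(ds[, -3]), "missing: n",
               class = "prepostMA_schema_error")
  expect_error(meta_dataset(cbind(ds, junk = 1)), "unknown: junk",
               class = "prepostMA_schema_error")
  bad <- ds; bad$mean_B <- as.character(bad$mean_B); bad$mean_B[2] <- "oops"
  expect_error(meta_dataset(bad), "mean_B.*row", class = "prepostMA_parse_error")
  expect_error(meta_dataset(ds[-1, ]), "trial01",
               class = "prepostMA_structure_error")
  two_ctrl <- ds; two_ctrl$arm <- "control"
  expect_error(meta_dataset(two_ctrl), "one control and one treatment",
               class = "prepostMA_structure_error")
  # 0/1 arm aliases accepted
  alias <- ds; alias$arm <- rep(c(0, 1), 2)
  expect_identical(meta_dataset(alias)$arm, rep(c("control", "treatment"), 2))
})

test_that("describe_dataset reports counts, missingness and statistics", {
  ds <- sim_dataset(k = 9, n = 12, seed = 5)
  ds$r[c(1, 4, 17, 18)] <- NA
  d <- describe_dataset(ds)
  rr <- d[d$column == "r", ]
  expect_equal(rr$n_present, 14)
  expect_equal(rr$missing_rate, 4 / 18)
  # hand-checkable column
  ds2 <- sim_dataset(k = 2, n = 10, seed = 2)
  ds2$r <- NA
  ds2$mean_B <- c(1, 2, 3, 4)
  d2 <- describe_dataset(ds2)
  mb <- d2[d2$column == "mean_B", ]
  expect_equal(mb$mean, 2.5)
  expect_equal(mb$sd, sd(1:4))          # n - 1 denominator
  expect_equal(mb$median, 2.5)
  r2 <- d2[d2$column == "r", ]
  expect_equal(r2$missing_rate, 1)
  expect_true(is.na(r2$mean))
  # constant column
  ds2$mean_F <- 5
  d3 <- describe_dataset(ds2)
  mf <- d3[d3$column == "mean_F", ]
  expect_equal(unlist(mf[c("mean", "sd", "median")]),
               c(mean = 5, sd = 0, median = 5))
})

test_that("validate_dataset flags each invariant and agrees with describe", {
  ds <- sim_dataset(k = 3, n = 10, seed = 9)
  ds$r[1] <- 1.3
  v <- validate_dataset(ds)
  expect_equal(nrow(v), 1)
  expect_match(v$message, "r outside")
  # sd/se consistency: 0.5 * sqrt(16) = 2 is consistent
  ds2 <- sim_dataset(k = 2, n = 16, seed = 2)
  ds2$sd_B[1] <- 2; ds2$se_B[1] <- 0.5
  ds2$sd_CS[1] <- sd_change_from_correlation(2, ds2$sd_F[1], ds2$r[1])
  expect_equal(nrow(validate_dataset(ds2)), 0)
  ds2$se_B[1] <- 0.7
  expect_match(validate_dataset(ds2)$rule, "sd_se_consistency")
  # completeness checks
  ds3 <- sim_dataset(k = 2, n = 10, seed = 4)
  ds3$mean_CS[1] <- ds3$mean_CS[1] + 0.5
  v3 <- validate_dataset(ds3, require_complete = TRUE)
  expect_true("mean_consistency" %in% v3$rule)
  ds3$r[2] <- NA
  v3b <- validate_dataset(ds3, require_complete = TRUE)
  expect_true(any(v3b$rule == "complete" & v3b$field == "r"))
  # missing-field counts line up with describe's missingness
  n_missing_desc <- sum(describe_dataset(ds3)$n_present[-1] < nrow(ds3)) # ex n
  expect_true(n_missing_desc >= 1)
})

test_that("unsupported formats fail with guidance", {
  ds <- sim_dataset(k = 2, n = 10, seed = 1)
  expect_error(write_dataset(ds, withr::local_tempfile(fileext = ".xlsx"),
                             "xlsx"),
               "csv", class = "prepostMA_io_error")
  expect_error(read_dataset(textConnectionName <- withr::local_tempfile(
    fileext = ".dat", lines = "x")), "infer format",
    class = "prepostMA_io_error")
})

test_that("write_template produces a readable canonical file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_template(path)
  ds <- read_dataset(path)
  expect_equal(names(ds), prepostMA:::CANONICAL_COLS)
})
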