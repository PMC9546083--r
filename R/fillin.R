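#' Sequential fill-in of missing summary data
#'
#' Published pre/post trials rarely report every summary statistic. The
#' fill-in engine completes a [meta_dataset()] by a fixed sequence of
#' algebraic calculations and transparent imputations, recording for every
#' cell whether it was observed, calculated (algebraically determined) or
#' imputed, and by which rule. The steps, applied in this order, are:
#'
#' 1. SDs from SEs: `sd = se * sqrt(n)` for baseline, follow-up and change.
#' 2. Missing follow-up SDs imputed equal to baseline SDs.
#' 3. Within-group correlation from the three SDs:
#'    `r = (sd_B^2 + sd_F^2 - sd_CS^2) / (2 sd_B sd_F)`.
#' 4. The third mean from the other two via `mean_CS = mean_F - mean_B`.
#' 5. Correlations still missing imputed (sample-size-weighted mean of the
#'    observed/calculated correlations, or a fixed value).
#' 6. Missing change-score SDs from the correlation:
#'    `sd_CS = sqrt(sd_B^2 + sd_F^2 - 2 r sd_B sd_F)`.
#'
#' @name fillin
NULL

# -- provenance bookkeeping ---------------------------------------------------

init_provenance <- function(ds) {
  prov <- attr(ds, "provenance")
  if (!is.null(prov)) return(prov)
  prov <- matrix("observed", nrow(ds), length(STAT_COLS),
                 dimnames = list(NULL, STAT_COLS))
  prov[is.na(as.matrix(ds[STAT_COLS]))] <- "missing"
  prov
}

set_prov <- function(ds, rows, col, code) {
  prov <- init_provenance(ds)
  prov[rows, col] <- code
  attr(ds, "provenance") <- prov
  ds
}

#' Cell-level provenance of a (possibly filled-in) dataset
#'
#' @param ds a [meta_dataset()] as returned by the fill-in functions.
#' @return character matrix (rows x statistic columns) with entries
#'   `"observed"`, `"missing"`, `"calculated:<rule>"` or `"imputed:<rule>"`.
#' @export
provenance <- function(ds) init_provenance(ds)

# -- scalar operations --------------------------------------------------------

#' Standard deviation from standard error
#'
#' @param se standard error (> 0), vectorised.
#' @param n sample size (>= 1), vectorised.
#' @return `se * sqrt(n)`.
#' @export
sd_from_se <- function(se, n) {
  if (any(se <= 0, na.rm = TRUE)) {
    stop_prepost("se must be strictly positive", class = "prepostMA_domain_error")
  }
  if (any(n < 1, na.rm = TRUE)) {
    stop_prepost("n must be >= 1", class = "prepostMA_domain_error")
  }
  se * sqrt(n)
}

#' Within-group correlation from the three SDs
#'
#' `r = (sd_B^2 + sd_F^2 - sd_CS^2) / (2 sd_B sd_F)`. Values within `clamp_tol`
#' outside `[-1, 1]` (rounding in published summaries) are clamped to the
#' boundary with a warning; values further out are an error: the three SDs
#' cannot coexist.
#'
#' @param sd_B,sd_F,sd_CS positive SDs, vectorised.
#' @param clamp_tol clamping tolerance.
#' @return correlation(s) in `[-1, 1]`.
#' @export
correlation_from_sds <- function(sd_B, sd_F, sd_CS, clamp_tol = 1e-8) {
  if (any(c(sd_B, sd_F) <= 0, na.rm = TRUE) || any(sd_CS < 0, na.rm = TRUE)) {
    stop_prepost("SDs must be positive", class = "prepostMA_domain_error")
  }
  r <- (sd_B^2 + sd_F^2 - sd_CS^2) / (2 * sd_B * sd_F)
  bad <- which(abs(r) > 1 + clamp_tol)
  if (length(bad)) {
    stop_prepost("inconsistent SDs at position(s) %s: implied |r| = %s > 1",
                 paste(bad, collapse = ", "),
                 paste(sprintf("%.6g", abs(r[bad])), collapse = ", "),
                 class = "prepostMA_domain_error")
  }
  clamped <- which(!is.na(r) & abs(r) > 1)
  if (length(clamped)) {
    warning(sprintf("correlation clamped to +/-1 at position(s) %s",
                    paste(clamped, collapse = ", ")))
    r[clamped] <- sign(r[clamped])
  }
  r
}

#' Change-score SD from the within-group correlation
#'
#' Inverse of [correlation_from_sds()]:
#' `sd_CS = sqrt(sd_B^2 + sd_F^2 - 2 r sd_B sd_F)`.
#'
#' @param sd_B,sd_F positive SDs, vectorised.
#' @param r correlation in `[-1, 1]`.
#' @return non-negative change-score SD.
#' @export
sd_change_from_correlation <- function(sd_B, sd_F, r) {
  if (any(c(sd_B, sd_F) <= 0, na.rm = TRUE)) {
    stop_prepost("SDs must be positive", class = "prepostMA_domain_error")
  }
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop_prepost("r must lie in [-1, 1]", class = "prepostMA_domain_error")
  }
  sqrt(pmax(sd_B^2 + sd_F^2 - 2 * r * sd_B * sd_F, 0))
}

# -- dataset-level steps ------------------------------------------------------

#' @describeIn fillin fill each missing SD whose SE is present.
#' @export
fill_sd_from_se <- function(ds) {
  ds <- structure(ds, provenance = init_provenance(ds))
  for (q in c("B", "F", "CS")) {
    sdc <- paste0("sd_", q); sec <- paste0("se_", q)
    idx <- which(is.na(ds[[sdc]]) & !is.na(ds[[sec]]))
    if (length(idx)) {
      ds[[sdc]][idx] <- sd_from_se(ds[[sec]][idx], ds$n[idx])
      ds <- set_prov(ds, idx, sdc, "calculated:sd_from_se")
    }
  }
  ds
}

#' @describeIn fillin impute missing follow-up SDs as the baseline SD.
#' @export
impute_sdF_equals_sdB <- function(ds) {
  ds <- structure(ds, provenance = init_provenance(ds))
  idx <- which(is.na(ds$sd_F) & !is.na(ds$sd_B))
  if (length(idx)) {
    ds$sd_F[idx] <- ds$sd_B[idx]
    ds <- set_prov(ds, idx, "sd_F", "imputed:sdF_equals_sdB")
  }
  ds
}

#' @describeIn fillin compute missing correlations where all three SDs exist.
#' @export
fill_correlations <- function(ds, clamp_tol = 1e-8) {
  ds <- structure(ds, provenance = init_provenance(ds))
  idx <- which(is.na(ds$r) & !is.na(ds$sd_B) & !is.na(ds$sd_F) & !is.na(ds$sd_CS))
  if (length(idx)) {
    ds$r[idx] <- correlation_from_sds(ds$sd_B[idx], ds$sd_F[idx], ds$sd_CS[idx],
                                      clamp_tol = clamp_tol)
    ds <- set_prov(ds, idx, "r", "calculated:correlation_from_sds")
  }
  ds
}

#' @describeIn fillin complete the mean triplet where two of the three exist.
#' @export
fill_means <- function(ds) {
  ds <- structure(ds, provenance = init_provenance(ds))
  i <- which(is.na(ds$mean_CS) & !is.na(ds$mean_B) & !is.na(ds$mean_F))
  if (length(i)) {
    ds$mean_CS[i] <- ds$mean_F[i] - ds$mean_B[i]
    ds <- set_prov(ds, i, "mean_CS", "calculated:mean_identity")
  }
  i <- which(is.na(ds$mean_F) & !is.na(ds$mean_B) & !is.na(ds$mean_CS))
  if (length(i)) {
    ds$mean_F[i] <- ds$mean_B[i] + ds$mean_CS[i]
    ds <- set_prov(ds, i, "mean_F", "calculated:mean_identity")
  }
  i <- which(is.na(ds$mean_B) & !is.na(ds$mean_F) & !is.na(ds$mean_CS))
  if (length(i)) {
    ds$mean_B[i] <- ds$mean_F[i] - ds$mean_CS[i]
    ds <- set_prov(ds, i, "mean_B", "calculated:mean_identity")
  }
  ds
}

#' @describeIn fillin impute correlations still missing after the formula step.
#' @param strategy `"weighted_mean"` (the `(n - 1)`-weighted mean of all
#'   observed or calculated correlations) or `"fixed"`.
#' @param fixed_value correlation in `[-1, 1]`, required for
#'   `strategy = "fixed"`.
#' @export
impute_missing_correlations <- function(ds, strategy = c("weighted_mean", "fixed"),
                                        fixed_value = NULL) {
  strategy <- match.arg(strategy)
  ds <- structure(ds, provenance = init_provenance(ds))
  idx <- which(is.na(ds$r))
  if (!length(idx)) return(ds)
  if (strategy == "fixed") {
    if (is.null(fixed_value) || is.na(fixed_value) || abs(fixed_value) > 1) {
      stop_prepost("strategy 'fixed' requires fixed_value in [-1, 1]",
                   class = "prepostMA_domain_error")
    }
    ds$r[idx] <- fixed_value
    ds <- set_prov(ds, idx, "r", "imputed:fixed")
  } else {
    obs <- which(!is.na(ds$r))
    if (!length(obs)) {
      stop_prepost(paste("no observed or calculable correlations to average;",
                         "supply strategy = 'fixed' with a fixed_value"),
                   class = "prepostMA_domain_error")
    }
    w <- ds$n[obs] - 1
    if (sum(w) <= 0) w <- rep(1, length(obs))
    ds$r[idx] <- sum(w * ds$r[obs]) / sum(w)
    ds <- set_prov(ds, idx, "r", "imputed:weighted_mean")
  }
  ds
}

#' @describeIn fillin fill missing change-score SDs from the correlation.
#' @export
fill_sd_change <- function(ds) {
  ds <- structure(ds, provenance = init_provenance(ds))
  idx <- which(is.na(ds$sd_CS) & !is.na(ds$sd_B) & !is.na(ds$sd_F) & !is.na(ds$r))
  if (length(idx)) {
    ds$sd_CS[idx] <- sd_change_from_correlation(ds$sd_B[idx], ds$sd_F[idx],
                                                ds$r[idx])
    ds <- set_prov(ds, idx, "sd_CS", "calculated:sd_change_from_correlation")
  }
  ds
}

#' Run the full fill-in sequence
#'
#' Applies the steps documented in [fillin] in their fixed order and verifies
#' that the result satisfies the complete-dataset invariants. Rows that cannot
#' be completed are an error naming the irrecoverable fields.
#'
#' @param ds a [meta_dataset()].
#' @param corr_strategy,corr_value passed to [impute_missing_correlations()].
#' @param clamp_tol clamping tolerance for implied correlations.
#' @param tol relative tolerance of the final consistency check.
#' @return list with elements `dataset` (a complete [meta_dataset()]),
#'   `provenance` (cell-level matrix, see [provenance()]) and `report`
#'   (data frame counting observed / calculated / imputed cells per column).
#' @export
run_fillin <- function(ds, corr_strategy = c("weighted_mean", "fixed"),
                       corr_value = NULL, clamp_tol = 1e-8, tol = 1e-6) {
  corr_strategy <- match.arg(corr_strategy)
  stopifnot(inherits(ds, "meta_dataset"))
  ds <- fill_sd_from_se(ds)
  ds <- impute_sdF_equals_sdB(ds)
  ds <- fill_correlations(ds, clamp_tol = clamp_tol)
  ds <- fill_means(ds)
  ds <- impute_missing_correlations(ds, strategy = corr_strategy,
                                    fixed_value = corr_value)
  ds <- fill_sd_change(ds)
  # final pass: the correlation step may now be feasible for rows whose sd_CS
  # arrived late, and means may be derivable from newly filled values
  ds <- fill_means(ds)

  required <- c("mean_B", "mean_F", "mean_CS", "sd_B", "sd_F", "sd_CS", "r")
  incomplete <- which(apply(is.na(as.matrix(ds[required])), 1, any))
  if (length(incomplete)) {
    fields <- vapply(incomplete, function(i) {
      paste(required[is.na(unlist(ds[i, required]))], collapse = ", ")
    }, character(1))
    stop_prepost("cannot complete row(s): %s",
                 paste(sprintf("%s/%s (missing %s)", ds$trial_id[incomplete],
                               ds$arm[incomplete], fields), collapse = "; "),
                 class = "prepostMA_fillin_error")
  }
  issues <- validate_dataset(ds, require_complete = TRUE, tol = tol)
  if (nrow(issues)) {
    stop_prepost("filled dataset fails consistency checks: %s",
                 paste(utils::head(issues$message, 5), collapse = "; "),
                 class = "prepostMA_fillin_error")
  }
  prov <- provenance(ds)
  counts <- t(vapply(STAT_COLS, function(cl) {
    p <- prov[, cl]
    c(observed = sum(p == "observed"),
      calculated = sum(startsWith(p, "calculated")),
      imputed = sum(startsWith(p, "imputed")),
      missing = sum(p == "missing"))
  }, numeric(4)))
  report <- data.frame(column = STAT_COLS, counts, row.names = NULL)
  list(dataset = ds, provenance = prov, report = report)
}
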