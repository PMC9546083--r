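#' Per-trial mean-difference effects from aggregate data
#'
#' Three ways to express the treatment effect of a two-arm pre/post trial as a
#' mean difference (treatment minus control):
#'
#' * *follow-up scores*: difference of follow-up means; ignores baseline.
#' * *change scores*: difference of mean changes (follow-up minus baseline).
#' * *ANCOVA recovered estimates*: the treatment coefficient of a single-slope
#'   analysis of covariance, reconstructed algebraically from the summary
#'   statistics. With pooled within-group sums of squares/products
#'   `S_xx, S_yy, S_xy` (baseline = x, follow-up = y) and `N = n_T + n_C`:
#'   `beta = S_xy / S_xx`,
#'   `theta = (mF_T - mF_C) - beta * (mB_T - mB_C)`,
#'   `sigma2 = (S_yy - S_xy^2 / S_xx) / (N - 3)`,
#'   `var(theta) = sigma2 * (1/n_T + 1/n_C + (mB_T - mB_C)^2 / S_xx)`.
#'   These equal the coefficient and model-based SE of an ordinary
#'   least-squares ANCOVA fitted to exact-moment pseudo participant data for
#'   the trial (see [generate_pseudo_ipd()]), which is why the
#'   baseline-imbalance term is kept in the variance.
#'
#' Each function takes the two rows of one trial from a complete
#' [meta_dataset()] and returns a one-row data frame with columns
#' `trial_id, method, estimate, variance, se`.
#'
#' @name effects_ad
NULL

trial_rows <- function(trial) {
  stopifnot(nrow(trial) == 2, all(c("control", "treatment") %in% trial$arm))
  list(C = trial[trial$arm == "control", , drop = FALSE],
       T = trial[trial$arm == "treatment", , drop = FALSE])
}

effect_row <- function(trial_id, method, estimate, variance) {
  if (!is.finite(variance) || variance <= 0) {
    stop_prepost("degenerate effect for trial '%s' (%s): variance = %g",
                 trial_id, method, variance, class = "prepostMA_domain_error")
  }
  data.frame(trial_id = trial_id, method = method, estimate = estimate,
             variance = variance, se = sqrt(variance))
}

#' @describeIn effects_ad mean difference of follow-up scores.
#' @param trial two-row subset of a complete [meta_dataset()] (one trial).
#' @export
effect_followup <- function(trial) {
  a <- trial_rows(trial)
  effect_row(a$C$trial_id, "followup",
             a$T$mean_F - a$C$mean_F,
             a$T$sd_F^2 / a$T$n + a$C$sd_F^2 / a$C$n)
}

#' @describeIn effects_ad mean difference of change scores.
#' @export
effect_change <- function(trial) {
  a <- trial_rows(trial)
  effect_row(a$C$trial_id, "change",
             a$T$mean_CS - a$C$mean_CS,
             a$T$sd_CS^2 / a$T$n + a$C$sd_CS^2 / a$C$n)
}

#' @describeIn effects_ad ANCOVA treatment effect recovered from summaries.
#' @export
effect_ancova_recovered <- function(trial) {
  a <- trial_rows(trial)
  nT <- a$T$n; nC <- a$C$n; N <- nT + nC
  if (N <= 3) {
    stop_prepost("trial '%s': ANCOVA needs N >= 4 (got %d)", a$C$trial_id, N,
                 class = "prepostMA_domain_error")
  }
  Sxx <- (nT - 1) * a$T$sd_B^2 + (nC - 1) * a$C$sd_B^2
  Syy <- (nT - 1) * a$T$sd_F^2 + (nC - 1) * a$C$sd_F^2
  Sxy <- (nT - 1) * a$T$r * a$T$sd_B * a$T$sd_F +
         (nC - 1) * a$C$r * a$C$sd_B * a$C$sd_F
  if (Sxx <= 0) {
    stop_prepost("trial '%s': zero pooled baseline variance", a$C$trial_id,
                 class = "prepostMA_domain_error")
  }
  beta <- Sxy / Sxx
  db <- a$T$mean_B - a$C$mean_B
  theta <- (a$T$mean_F - a$C$mean_F) - beta * db
  rss <- Syy - Sxy^2 / Sxx
  if (rss <= 0) {
    stop_prepost("trial '%s': degenerate ANCOVA fit (zero residual variance)",
                 a$C$trial_id, class = "prepostMA_domain_error")
  }
  sigma2 <- rss / (N - 3)
  out <- effect_row(a$C$trial_id, "ancova_recovered", theta,
                    sigma2 * (1 / nT + 1 / nC + db^2 / Sxx))
  out$slope <- beta
  out$sigma2 <- sigma2
  out
}

#' Compute per-trial effects for every trial in a dataset
#'
#' @param ds a complete [meta_dataset()] (see [run_fillin()]).
#' @param method `"ancova"` (default; recovered estimates), `"followup"` or
#'   `"change"`.
#' @return data frame of per-trial effects, one row per trial, in dataset
#'   order, with columns `trial_id, method, estimate, variance, se` (plus
#'   `slope`, `sigma2` for ANCOVA).
#' @examples
#' ds <- aggregate_ipd(simulate_ipd(k = 5, seed = 42))
#' compute_effects(ds, "ancova")
#' @export
compute_effects <- function(ds, method = c("ancova", "followup", "change")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "meta_dataset"))
  if (!is_complete(ds)) {
    stop_prepost("dataset is not complete; run run_fillin() first",
                 class = "prepostMA_domain_error")
  }
  f <- switch(method, ancova = effect_ancova_recovered,
              followup = effect_followup, change = effect_change)
  out <- do.call(rbind, lapply(split_trials(ds), f))
  rownames(out) <- NULL
  out[match(unique(ds$trial_id), out$trial_id), , drop = FALSE]
}
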