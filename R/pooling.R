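#' Inverse-variance pooling of per-trial effects
#'
#' Common-effect (CE) and random-effects (RE) meta-analysis of mean
#' differences. Under RE the between-study variance tau^2 is estimated by
#' restricted maximum likelihood (REML), and the Hartung-Knapp (HK) refinement
#' replaces the usual standard error by
#' `se_HK^2 = sum(w* (y - mu)^2) / ((k - 1) sum(w*))` with a t(k - 1)
#' confidence interval. The HK variance is used untruncated (no floor at the
#' conventional RE variance), matching the estimator as originally proposed;
#' as a consequence the HK interval can occasionally be narrower than the
#' normal-theory interval.
#'
#' @name pooling
NULL

check_effects <- function(effects, kmin = 1) {
  stopifnot(is.data.frame(effects), all(c("estimate", "variance") %in% names(effects)))
  if (nrow(effects) < kmin) {
    stop_prepost("at least %d effect(s) required (got %d)", kmin, nrow(effects),
                 class = "prepostMA_domain_error")
  }
  if (any(!is.finite(effects$variance)) || any(effects$variance <= 0)) {
    stop_prepost("all effect variances must be finite and > 0",
                 class = "prepostMA_domain_error")
  }
  effects
}

new_pooling_result <- function(estimate, se, level, tau2, Q, I2, H2, k, model,
                               hk, df = NULL) {
  crit <- if (hk) stats::qt(1 - (1 - level) / 2, df) else stats::qnorm(1 - (1 - level) / 2)
  structure(list(estimate = estimate, se = se,
                 ci_low = estimate - crit * se, ci_high = estimate + crit * se,
                 level = level, tau2 = tau2, Q = Q, I2 = I2, H2 = H2, k = k,
                 model = model, hk = hk, tau2_method = "REML",
                 df = if (hk) df else NA_real_),
            class = "pooling_result")
}

# Q and the typical within-study variance s^2 of Higgins & Thompson
het_core <- function(yi, vi, tau2) {
  w <- 1 / vi
  mu_ce <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - mu_ce)^2)
  s2 <- if (length(yi) > 1) {
    (length(yi) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  } else {
    NA_real_
  }
  list(Q = Q, s2 = s2, I2 = 100 * tau2 / (tau2 + s2), H2 = (tau2 + s2) / s2)
}

#' Common-effect (fixed-effect) pooling
#'
#' @param effects data frame with columns `estimate` and `variance` (e.g. from
#'   [compute_effects()] or [twostage()]).
#' @param level confidence level.
#' @return a `pooling_result`: summary estimate, SE, CI, `tau2` (0 by
#'   definition), `Q`, `I2`, `H2`, `k` and method flags.
#' @export
pool_ce <- function(effects, level = 0.95) {
  effects <- check_effects(effects, 1)
  yi <- effects$estimate; vi <- effects$variance
  w <- 1 / vi
  est <- sum(w * yi) / sum(w)
  hc <- het_core(yi, vi, 0)
  new_pooling_result(est, sqrt(1 / sum(w)), level, 0, hc$Q,
                     I2 = if (length(yi) > 1) hc$I2 else 0,
                     H2 = if (length(yi) > 1) hc$H2 else 1,
                     k = length(yi), model = "CE", hk = FALSE)
}

# restricted log-likelihood of tau2 (additive constants dropped)
reml_ll <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - mu)^2))
}

#' REML estimate of the between-study variance
#'
#' Maximises the restricted log-likelihood over `tau2 >= 0` by bounded
#' golden-section/parabolic search followed by Newton polishing, with an
#' explicit comparison against the boundary `tau2 = 0`.
#'
#' @inheritParams pool_ce
#' @return non-negative `tau2` with attributes `loglik` and `converged`.
#' @export
reml_tau2 <- function(effects) {
  effects <- check_effects(effects, 2)
  yi <- effects$estimate; vi <- effects$variance
  upper <- max(100 * max(vi), 10 * stats::var(yi), 1e-8)
  opt <- stats::optimize(reml_ll, c(0, upper), yi = yi, vi = vi,
                         maximum = TRUE, tol = 1e-12)
  t2 <- opt$maximum
  # Newton polish (profiled score in tau2)
  for (it in 1:50) {
    h <- 1e-6 * max(t2, 1)
    g  <- (reml_ll(t2 + h, yi, vi) - reml_ll(max(t2 - h, 0), yi, vi)) /
          (t2 + h - max(t2 - h, 0))
    hh <- (reml_ll(t2 + h, yi, vi) - 2 * reml_ll(t2, yi, vi) +
           reml_ll(max(t2 - h, 0), yi, vi)) / h^2
    if (!is.finite(hh) || hh >= 0) break
    step <- g / hh
    t2new <- min(max(t2 - step, 0), upper)
    if (abs(t2new - t2) < 1e-10) { t2 <- t2new; break }
    t2 <- t2new
  }
  if (reml_ll(0, yi, vi) >= reml_ll(t2, yi, vi)) t2 <- 0
  structure(t2, loglik = reml_ll(t2, yi, vi), converged = TRUE)
}

#' Random-effects pooling with optional Hartung-Knapp adjustment
#'
#' @inheritParams pool_ce
#' @param hk apply the Hartung-Knapp standard-error refinement and t(k - 1)
#'   interval.
#' @param tau2 optional fixed `tau2`; default is the REML estimate.
#' @return a `pooling_result`.
#' @export
pool_re <- function(effects, level = 0.95, hk = FALSE, tau2 = NULL) {
  effects <- check_effects(effects, 2)
  yi <- effects$estimate; vi <- effects$variance
  k <- length(yi)
  t2 <- if (is.null(tau2)) as.numeric(reml_tau2(effects)) else tau2
  w <- 1 / (vi + t2)
  est <- sum(w * yi) / sum(w)
  se <- if (hk) {
    sqrt(sum(w * (yi - est)^2) / ((k - 1) * sum(w)))
  } else {
    sqrt(1 / sum(w))
  }
  hc <- het_core(yi, vi, t2)
  new_pooling_result(est, se, level, t2, hc$Q, hc$I2, hc$H2, k,
                     model = "RE", hk = hk, df = k - 1)
}

#' Heterogeneity statistics
#'
#' Cochran's `Q` (computed at the CE weights), and `I2`/`H2` based on the
#' typical within-study variance
#' `s2 = (k - 1) sum(w) / ((sum(w))^2 - sum(w^2))`, `w = 1/v`:
#' `I2 = 100 tau2 / (tau2 + s2)` (percent), `H2 = (tau2 + s2) / s2`.
#'
#' @inheritParams pool_ce
#' @param tau2 between-study variance (e.g. from [reml_tau2()]).
#' @return list with `Q`, `I2`, `H2`.
#' @export
heterogeneity_stats <- function(effects, tau2) {
  effects <- check_effects(effects, 2)
  hc <- het_core(effects$estimate, effects$variance, tau2)
  list(Q = hc$Q, I2 = hc$I2, H2 = hc$H2)
}

#' @export
print.pooling_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s model meta-analysis (k = %d)%s\n",
              x$model, x$k,
              if (isTRUE(x$hk)) sprintf(", Hartung-Knapp (df = %d)", x$df) else ""))
  cat(sprintf("  estimate %.*f  se %.*f  %g%% CI [%.*f, %.*f]\n",
              digits, x$estimate, digits, x$se, 100 * x$level,
              digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  tau2 (%s) %.*f   Q %.*f   I2 %.1f%%   H2 %.*f\n",
              x$tau2_method, digits, x$tau2, digits, x$Q, x$I2, digits, x$H2))
  invisible(x)
}
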