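#' Simulated pre/post trials for validation
#'
#' Simulates true participant-level data from the data-generating process the
#' one-stage model assumes, aggregates it to summary form, and masks summary
#' cells to exercise the fill-in engine. Defaults emulate a body-weight-like
#' outcome: baselines around 60-90 kg with SD 10 kg, strong baseline tracking
#' (slope 0.9, residual SD 4 kg, implying within-group correlations near
#' 0.9), a modest harmful-to-beneficial effect range and moderate
#' heterogeneity.
#'
#' @name synthetic
NULL

#' @describeIn synthetic simulate participant-level data.
#' @param k number of trials.
#' @param n_per_arm per-arm sample size; a single count or a `c(lo, hi)` range
#'   sampled uniformly per trial.
#' @param theta mean treatment effect (outcome units, treatment - control).
#' @param tau2 between-study variance of the true trial effects.
#' @param beta baseline slope (shared by all trials).
#' @param gamma_w within-trial treatment-by-baseline interaction per unit of
#'   centred baseline.
#' @param baseline_imbalance_sd SD of the per-trial random shift added to the
#'   treatment arm's baseline mean (0 = perfectly balanced randomisation).
#' @param mu_B_range range of trial baseline means, sampled uniformly.
#' @param sigma_B within-arm baseline SD.
#' @param resid_structure,resid_sd residual error model: a structure as in
#'   [fit_onestage()] and the corresponding SD(s) -- length 1 for `single`,
#'   2 (control, treatment) for `arm`, `k` for `study`, `2k`
#'   (control/treatment per trial) for `arm_study`.
#' @param seed integer seed.
#' @return IPD data frame `trial_id, arm, id, y_baseline, y_final` with
#'   attribute `truth` (the generating parameters and per-trial effects).
#' @export
simulate_ipd <- function(k = 9, n_per_arm = 50, theta = -0.5, tau2 = 0.25,
                         beta = 0.9, gamma_w = 0, baseline_imbalance_sd = 0,
                         mu_B_range = c(60, 90), sigma_B = 10,
                         resid_structure = "single", resid_sd = 4,
                         seed = 1L) {
  stopifnot(k >= 1, all(n_per_arm >= 2), tau2 >= 0, sigma_B > 0,
            all(resid_sd > 0))
  n_sd <- switch(resid_structure, single = 1L, arm = 2L, study = k,
                 arm_study = 2L * k,
                 stop_prepost("unknown resid_structure '%s'", resid_structure,
                              class = "prepostMA_domain_error"))
  if (length(resid_sd) == 1) resid_sd <- rep(resid_sd, n_sd)
  if (length(resid_sd) != n_sd) {
    stop_prepost("resid_sd must have length 1 or %d for structure '%s'",
                 n_sd, resid_structure, class = "prepostMA_domain_error")
  }
  force(seed)  # force before capturing RNG state (seed may be an RNG draw)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ids <- sprintf("trial%02d", seq_len(k))
  theta_i <- stats::rnorm(k, theta, sqrt(tau2))
  mu_B <- stats::runif(k, mu_B_range[1], mu_B_range[2])
  shift <- stats::rnorm(k, 0, baseline_imbalance_sd)
  alpha_i <- mu_B + stats::rnorm(k, 0, 1)  # trial-level drift of control mean
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    n <- if (length(n_per_arm) > 1) {
      sample(seq(n_per_arm[1], n_per_arm[2]), 1)
    } else n_per_arm
    arm <- rep(c("control", "treatment"), each = n)
    t_ <- as.numeric(arm == "treatment")
    b <- stats::rnorm(2 * n, mu_B[i] + shift[i] * t_, sigma_B)
    sd_idx <- switch(resid_structure,
                     single = rep(1L, 2 * n),
                     arm = 1L + t_,
                     study = rep(i, 2 * n),
                     arm_study = 2L * (i - 1L) + 1L + t_)
    bbar <- mean(b)
    y <- alpha_i[i] + beta * (b - bbar) + (theta_i[i] + gamma_w * (b - bbar)) * t_ +
      stats::rnorm(2 * n, 0, resid_sd[sd_idx])
    rows[[i]] <- data.frame(trial_id = ids[i], arm = arm, id = seq_len(2 * n),
                            y_baseline = b, y_final = y)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            truth = list(theta = theta, tau2 = tau2, beta = beta,
                         gamma_w = gamma_w, theta_i = theta_i,
                         alpha_i = alpha_i, mu_B = mu_B, shift = shift,
                         resid_structure = resid_structure,
                         resid_sd = resid_sd, seed = seed))
}

#' @describeIn synthetic aggregate IPD to a complete summary dataset.
#' @param ipd IPD data frame with columns `trial_id, arm, y_baseline,
#'   y_final`.
#' @return a complete [meta_dataset()] (per arm: `n`, baseline / follow-up /
#'   change means and SDs, within-group correlation; SE columns left empty).
#' @export
aggregate_ipd <- function(ipd) {
  stopifnot(all(c("trial_id", "arm", "y_baseline", "y_final") %in% names(ipd)))
  key <- interaction(factor(ipd$trial_id, levels = unique(ipd$trial_id)),
                     ipd$arm, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(as.data.frame(ipd), key), function(a) {
    if (nrow(a) < 2) {
      stop_prepost("arm '%s'/%s has fewer than 2 observations",
                   a$trial_id[1], a$arm[1], class = "prepostMA_domain_error")
    }
    cs <- a$y_final - a$y_baseline
    if (stats::sd(a$y_baseline) == 0 || stats::sd(a$y_final) == 0) {
      stop_prepost("degenerate arm '%s'/%s: zero variance",
                   a$trial_id[1], a$arm[1], class = "prepostMA_domain_error")
    }
    data.frame(trial_id = a$trial_id[1], arm = a$arm[1], n = nrow(a),
               mean_B = mean(a$y_baseline), sd_B = stats::sd(a$y_baseline),
               se_B = NA_real_,
               mean_F = mean(a$y_final), sd_F = stats::sd(a$y_final),
               se_F = NA_real_,
               mean_CS = mean(cs), sd_CS = stats::sd(cs), se_CS = NA_real_,
               r = stats::cor(a$y_baseline, a$y_final))
  })
  df <- do.call(rbind, rows)
  df <- df[order(match(df$trial_id, unique(ipd$trial_id)), df$arm), ]
  meta_dataset(df)
}

#' @describeIn synthetic delete summary cells to create a recoverable
#'   incomplete dataset.
#' @param ds a complete [meta_dataset()].
#' @param pattern which cells to delete in the affected rows: `drop_sdF`
#'   (follow-up SD), `drop_sdCS` (change-score SD), `drop_r` (correlation),
#'   `sd_to_se` (replace every SD by the implied SE, then delete the SDs) or
#'   `mixed` (one of the above per affected row, chosen at random).
#' @param fraction fraction of rows affected.
#' @return a [meta_dataset()] with attribute `masked` (data frame of row,
#'   field and deleted value) recording the ground truth.
#' @export
mask_summaries <- function(ds, pattern = c("drop_sdF", "drop_sdCS", "drop_r",
                                           "sd_to_se", "mixed"),
                           fraction = 0.5, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(ds, "meta_dataset"), fraction >= 0, fraction <= 1)
  force(seed)  # force before capturing RNG state (seed may be an RNG draw)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "mask"))
  n_rows <- nrow(ds)
  rows <- sort(sample(n_rows, round(fraction * n_rows)))
  masked <- list()
  drop <- function(i, field) {
    masked[[length(masked) + 1L]] <<- data.frame(row = i, field = field,
                                                 value = ds[[field]][i])
    ds[[field]][i] <<- NA_real_
  }
  for (i in rows) {
    pat <- if (pattern == "mixed") {
      sample(c("drop_sdF", "drop_sdCS", "drop_r", "sd_to_se"), 1)
    } else pattern
    switch(pat,
           drop_sdF = {
             # keep the information as an SE (trials often report SEs), so the
             # deletion stays algebraically recoverable by the fill-in engine
             ds$se_F[i] <- ds$sd_F[i] / sqrt(ds$n[i])
             drop(i, "sd_F")
           },
           drop_sdCS = drop(i, "sd_CS"),
           drop_r = drop(i, "r"),
           sd_to_se = {
             for (q in c("B", "F", "CS")) {
               sdc <- paste0("sd_", q)
               if (!is.na(ds[[sdc]][i])) {
                 ds[[paste0("se_", q)]][i] <- ds[[sdc]][i] / sqrt(ds$n[i])
                 drop(i, sdc)
               }
             }
           })
  }
  attr(ds, "masked") <- if (length(masked)) {
    do.call(rbind, masked)
  } else {
    data.frame(row = integer(), field = character(), value = numeric())
  }
  ds
}
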