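#' Exact-moment pseudo participant data
#'
#' An ANCOVA fitted to participant-level data depends on the data only through
#' the per-arm sample sizes, means, SDs and baseline--follow-up correlations.
#' Pseudo individual participant data (pseudo IPD) are therefore constructed
#' to match those summary statistics *exactly*, not in expectation: every
#' model downstream then yields the same answers as the (unavailable) real IPD
#' would, as long as it is a function of the matched sufficient statistics.
#'
#' Construction per arm: draw an `n x 2` standard-normal matrix, column-centre
#' it, orthonormalise (so the centred columns are orthogonal with sample
#' covariance the identity under the `n - 1` denominator), multiply by the
#' Cholesky factor of the target covariance
#' `[[sd_B^2, r sd_B sd_F], [r sd_B sd_F, sd_F^2]]` and add the target means.
#' The match is algebraically exact; different seeds give different point
#' clouds with identical moments.
#'
#' @name pseudo_ipd
NULL

#' @describeIn pseudo_ipd generate one arm of `n` (baseline, follow-up) pairs.
#' @param n number of participants (>= 3, so that two means, two SDs and a
#'   correlation can be fixed).
#' @param mean_B,sd_B,mean_F,sd_F target baseline/follow-up moments.
#' @param r target sample correlation, `|r| < 1`.
#' @param seed integer seed.
#' @return data frame with columns `id, y_baseline, y_final`.
#' @export
generate_arm <- function(n, mean_B, sd_B, mean_F, sd_F, r, seed) {
  if (n < 3) {
    stop_prepost("n must be >= 3 to fix five sample moments (got %d)", n,
                 class = "prepostMA_domain_error")
  }
  if (sd_B <= 0 || sd_F <= 0) {
    stop_prepost("target SDs must be positive", class = "prepostMA_domain_error")
  }
  if (abs(r) >= 1) {
    stop_prepost("|r| = 1 is a rank-deficient target; supply |r| < 1 %s",
                 "(perfectly correlated arms cannot be represented exactly)",
                 class = "prepostMA_domain_error")
  }
  force(seed)  # force before capturing RNG state (seed may be an RNG draw)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (attempt in 1:10) {
    Z <- matrix(stats::rnorm(2 * n), n, 2)
    Zc <- sweep(Z, 2, colMeans(Z))
    qrz <- qr(Zc)
    if (qrz$rank == 2) break
    if (attempt == 10) {
      stop_prepost("degenerate random draw (rank-deficient noise)",
                   class = "prepostMA_domain_error")
    }
  }
  Q <- qr.Q(qrz)                      # orthonormal, columns mean-zero
  Zs <- Q * sqrt(n - 1)               # sample covariance = identity
  Sigma <- matrix(c(sd_B^2, r * sd_B * sd_F, r * sd_B * sd_F, sd_F^2), 2, 2)
  Y <- Zs %*% chol(Sigma)
  data.frame(id = seq_len(n),
             y_baseline = Y[, 1] + mean_B,
             y_final = Y[, 2] + mean_F)
}

#' @describeIn pseudo_ipd generate pseudo IPD for every arm of a complete
#'   dataset. Per-arm seeds are a stable hash of `(seed, trial_id, arm)`, so
#'   subsetting or reordering trials never changes another trial's points.
#' @param ds a complete [meta_dataset()].
#' @return a `pseudo_ipd` data frame with columns
#'   `trial_id, arm, id, y_baseline, y_final` and attribute `seed`.
#' @export
generate_pseudo_ipd <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "meta_dataset"))
  if (!is_complete(ds)) {
    stop_prepost("pseudo IPD requires a complete dataset; run run_fillin() first",
                 class = "prepostMA_domain_error")
  }
  parts <- lapply(seq_len(nrow(ds)), function(i) {
    row <- ds[i, ]
    arm <- tryCatch(
      generate_arm(row$n, row$mean_B, row$sd_B, row$mean_F, row$sd_F, row$r,
                   seed = derive_seed(seed, paste0(row$trial_id, "/", row$arm))),
      prepostMA_error = function(e) {
        stop_prepost("trial '%s', %s arm: %s", row$trial_id, row$arm,
                     conditionMessage(e), class = "prepostMA_domain_error")
      })
    cbind(trial_id = row$trial_id, arm = row$arm, arm)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, seed = seed, class = c("pseudo_ipd", "data.frame"))
}

#' @describeIn pseudo_ipd check that pseudo (or real) IPD reproduces the
#'   summary dataset.
#' @param ipd a `pseudo_ipd` (or any IPD data frame with the same columns).
#' @param tol absolute tolerance on each of the five moments.
#' @return data frame per arm with the worst absolute discrepancy across the
#'   five moments and a `pass` flag; attribute `pass` is the overall verdict.
#' @export
verify_moments <- function(ipd, ds, tol = 1e-10) {
  stopifnot(inherits(ds, "meta_dataset"))
  agg <- aggregate_ipd(ipd)
  key_ipd <- paste(agg$trial_id, agg$arm)
  key_ds <- paste(ds$trial_id, ds$arm)
  if (!setequal(key_ipd, key_ds)) {
    stop_prepost("trial/arm keys of IPD and dataset do not match",
                 class = "prepostMA_domain_error")
  }
  agg <- agg[match(key_ds, key_ipd), ]
  disc <- abs(cbind(mean_B = agg$mean_B - ds$mean_B,
                    sd_B = agg$sd_B - ds$sd_B,
                    mean_F = agg$mean_F - ds$mean_F,
                    sd_F = agg$sd_F - ds$sd_F,
                    r = agg$r - ds$r))
  out <- data.frame(trial_id = ds$trial_id, arm = ds$arm,
                    worst = apply(disc, 1, max),
                    worst_moment = colnames(disc)[apply(disc, 1, which.max)])
  out$pass <- out$worst < tol
  structure(out, pass = all(out$pass))
}
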