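# fixtures built in code; no data files

# the hand-checkable two-arm trial used throughout:
# control  n=4  mB=10 sdB=2 mF=12 sdF=2 r=0.5
# treat    n=4  mB=11 sdB=2 mF=11 sdF=2 r=0.5
toy_trial <- function() {
  sd_cs <- sd_change_from_correlation(2, 2, 0.5)
  meta_dataset(data.frame(
    trial_id = "toy", arm = c("control", "treatment"), n = 4,
    mean_B = c(10, 11), sd_B = 2, se_B = NA_real_,
    mean_F = c(12, 11), sd_F = 2, se_F = NA_real_,
    mean_CS = c(2, 0), sd_CS = sd_cs, se_CS = NA_real_, r = 0.5))
}

# complete k-trial dataset from the simulator
sim_dataset <- function(k = 5, n = 30, seed = 7, ...) {
  aggregate_ipd(simulate_ipd(k = k, n_per_arm = n, seed = seed, ...))
}

# effects data frame from raw vectors
eff_df <- function(estimate, variance) {
  data.frame(trial_id = sprintf("t%02d", seq_along(estimate)),
             estimate = estimate, variance = variance,
             se = sqrt(variance))
}

# brute-force REML oracle: grid search over tau2
grid_reml <- function(yi, vi, upper = 100, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, function(t2) {
    w <- 1 / (vi + t2)
    mu <- sum(w * yi) / sum(w)
    -0.5 * (sum(log(vi + t2)) + log(sum(w)) + sum(w * (yi - mu)^2))
  }, numeric(1))
  grid[which.max(ll)]
}

# dense-matrix REML log-likelihood oracle for the one-stage model
dense_reml_loglik <- function(ipd, sigma, tau, resid_structure,
                              interaction = FALSE, common_slope = FALSE) {
  ids <- unique(ipd$trial_id)
  k <- length(ids)
  bbar_i <- vapply(ids, function(id) mean(ipd$y_baseline[ipd$trial_id == id]),
                   numeric(1))
  bbar_centre <- mean(bbar_i)
  N <- nrow(ipd)
  X <- NULL; V <- matrix(0, N, N); y <- ipd$y_final
  p_alpha <- k; p_beta <- if (common_slope) 1 else k
  p <- p_alpha + p_beta + 1 + if (interaction) 2 else 0
  X <- matrix(0, N, p)
  strata <- switch(resid_structure,
                   arm_study = as.vector(t(outer(ids, c("control", "treatment"),
                                                 paste, sep = ":"))),
                   study = ids, arm = c("control", "treatment"), single = "all")
  sig <- if (!is.null(names(sigma))) sigma[strata] else sigma
  row0 <- 0
  for (i in seq_len(k)) {
    tr <- ipd[ipd$trial_id == ids[i], ]
    n_i <- nrow(tr)
    idx <- row0 + seq_len(n_i)
    t_ <- as.numeric(tr$arm == "treatment")
    bc <- tr$y_baseline - mean(tr$y_baseline)
    X[idx, i] <- 1
    X[idx, p_alpha + if (common_slope) 1 else i] <- bc
    X[idx, p_alpha + p_beta + 1] <- t_
    if (interaction) {
      X[idx, p_alpha + p_beta + 2] <- t_ * bc
      X[idx, p_alpha + p_beta + 3] <- t_ * (bbar_i[i] - bbar_centre)
    }
    st <- switch(resid_structure,
                 arm_study = match(paste(ids[i], tr$arm, sep = ":"), strata),
                 study = rep(i, n_i), arm = match(tr$arm, strata),
                 single = rep(1L, n_i))
    V[idx, idx] <- diag(as.numeric(sig[st])^2, n_i) + tau^2 * tcrossprod(t_)
    y[idx] <- tr$y_final
    row0 <- row0 + n_i
  }
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
                     t(r) %*% Vi %*% r + (N - p) * log(2 * pi)))
}
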