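#' Forest and funnel plots
#'
#' Standard meta-analytic displays rendered with base graphics. Alongside each
#' figure the *plot data* (coordinates of every point, interval, diamond and
#' funnel bound) are returned invisibly and, when a path is given, exported as
#' a CSV next to the figure, so downstream checks can assert numbers rather
#' than pixels.
#'
#' @name ma_plots
NULL

ci_from_effects <- function(effects, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(trial_id = effects$trial_id,
             estimate = effects$estimate, se = effects$se,
             ci_low = effects$estimate - z * effects$se,
             ci_high = effects$estimate + z * effects$se)
}

open_device <- function(path, format) {
  switch(format,
         pdf = grDevices::pdf(path, width = 8, height = 6),
         png = grDevices::png(path, width = 1200, height = 900, res = 150))
}

plot_data_path <- function(path) paste0(tools::file_path_sans_ext(path), "_data.csv")

#' Forest plot
#'
#' One row per trial (square at the estimate, whiskers at the 95% CI) and a
#' summary diamond spanning the pooled CI, annotated with the pooling model
#' (CE/RE, Hartung-Knapp, tau2, I2).
#'
#' @param effects per-trial effects (from [compute_effects()] or the `trials`
#'   element of [twostage()]).
#' @param pooled a `pooling_result` for the same effects.
#' @param path output file, or `NULL` to draw on the active device.
#' @param format `"pdf"` or `"png"` (ignored when `path` is `NULL`).
#' @return invisibly, a data frame of the plotted coordinates (rows for each
#'   trial plus one `summary` row); written as `<path>_data.csv` when `path`
#'   is given.
#' @export
forest_plot <- function(effects, pooled, path = NULL,
                        format = c("pdf", "png")) {
  format <- match.arg(format)
  stopifnot(nrow(effects) >= 1, inherits(pooled, "pooling_result"))
  dat <- ci_from_effects(effects, pooled$level)
  dat$kind <- "trial"
  dat <- rbind(dat, data.frame(trial_id = "summary", estimate = pooled$estimate,
                               se = pooled$se, ci_low = pooled$ci_low,
                               ci_high = pooled$ci_high, kind = "summary"))
  if (!is.null(path)) {
    open_device(path, format)
    on.exit(grDevices::dev.off())
  }
  k <- nrow(effects)
  ys <- c(rev(seq_len(k)) + 1, 0.2)
  xlim <- range(dat$ci_low, dat$ci_high, 0)
  graphics::plot(NA, xlim = xlim, ylim = c(-0.6, k + 2), yaxt = "n",
                 xlab = "Mean difference", ylab = "",
                 main = sprintf("%s model%s", pooled$model,
                                if (isTRUE(pooled$hk)) " + Hartung-Knapp" else ""))
  graphics::abline(v = 0, col = "grey70", lty = 2)
  graphics::segments(dat$ci_low[seq_len(k)], ys[seq_len(k)],
                     dat$ci_high[seq_len(k)], ys[seq_len(k)])
  graphics::points(dat$estimate[seq_len(k)], ys[seq_len(k)], pch = 15)
  graphics::axis(2, at = ys[seq_len(k)], labels = dat$trial_id[seq_len(k)],
                 las = 1, cex.axis = 0.8)
  ds <- dat[k + 1, ]
  graphics::polygon(c(ds$ci_low, ds$estimate, ds$ci_high, ds$estimate),
                    ys[k + 1] + c(0, 0.35, 0, -0.35), col = "grey40")
  graphics::mtext(sprintf("pooled %.3f [%.3f, %.3f]  tau2 %.3f  I2 %.1f%%",
                          ds$estimate, ds$ci_low, ds$ci_high,
                          pooled$tau2, pooled$I2),
                  side = 1, line = 3.6, cex = 0.8)
  dat$y <- ys
  if (!is.null(path)) {
    utils::write.csv(dat, plot_data_path(path), row.names = FALSE)
  }
  invisible(dat)
}

#' Funnel plot
#'
#' Estimate against standard error (SE axis inverted, most precise trials on
#' top), a vertical reference at the pooled estimate, and the 95%
#' pseudo-confidence funnel `pooled +/- 1.96 se` over the SE range.
#'
#' @inheritParams forest_plot
#' @return invisibly, a list with `points` (per-trial coordinates) and
#'   `funnel` (funnel bound coordinates); both written into `<path>_data.csv`
#'   when `path` is given.
#' @export
funnel_plot <- function(effects, pooled, path = NULL,
                        format = c("pdf", "png")) {
  format <- match.arg(format)
  stopifnot(nrow(effects) >= 2, inherits(pooled, "pooling_result"))
  z <- stats::qnorm(1 - (1 - pooled$level) / 2)
  se_grid <- seq(0, max(effects$se) * 1.05, length.out = 50)
  funnel <- data.frame(se = se_grid,
                       low = pooled$estimate - z * se_grid,
                       high = pooled$estimate + z * se_grid)
  if (!is.null(path)) {
    open_device(path, format)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(effects$estimate, effects$se,
                 ylim = rev(range(c(0, effects$se * 1.05))),
                 xlim = range(funnel$low, funnel$high, effects$estimate),
                 xlab = "Mean difference", ylab = "Standard error",
                 pch = 19, main = sprintf("Funnel plot (%s)", pooled$model))
  graphics::lines(funnel$low, funnel$se, lty = 2)
  graphics::lines(funnel$high, funnel$se, lty = 2)
  graphics::abline(v = pooled$estimate)
  out <- list(points = data.frame(trial_id = effects$trial_id,
                                  estimate = effects$estimate,
                                  se = effects$se),
              funnel = funnel, centre = pooled$estimate)
  if (!is.null(path)) {
    pts <- cbind(kind = "point", out$points)
    fn <- data.frame(kind = "funnel", trial_id = NA, estimate = NA,
                     se = funnel$se, low = funnel$low, high = funnel$high)
    pts$low <- NA; pts$high <- NA
    utils::write.csv(rbind(pts, fn), plot_data_path(path), row.names = FALSE)
  }
  invisible(out)
}
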