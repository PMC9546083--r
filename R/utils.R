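# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

# columns of the canonical long-format schema, in canonical order
CANONICAL_COLS <- c("trial_id", "arm", "n",
                    "mean_B", "sd_B", "se_B",
                    "mean_F", "sd_F", "se_F",
                    "mean_CS", "sd_CS", "se_CS",
                    "r")

NUMERIC_COLS <- setdiff(CANONICAL_COLS, c("trial_id", "arm"))
STAT_COLS    <- setdiff(NUMERIC_COLS, "n")

`%||%` <- function(x, y) if (is.null(x)) y else x

is_missing_num <- function(x) is.na(x)

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Stable 31-bit hash so that per-arm seeds depend only on the master seed and
#' the (trial, arm) identity, never on row position.
#'
#' @param master integer master seed.
#' @param key character key (e.g. "trial03/treatment").
#' @return integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, key) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master %% m)
  for (cc in utf8ToInt(paste0(key, "#"))) {
    h <- (h * 31 + cc) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

stop_prepost <- function(fmt, ..., class = "prepostMA_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "prepostMA_error")))
}

abs_or_rel_ok <- function(x, y, tol) {
  abs(x - y) <= tol * max(1, abs(x), abs(y))
}
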