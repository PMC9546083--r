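#' Long-format summary datasets for pre/post meta-analysis
#'
#' A `meta_dataset` is a data frame with one row per trial arm and the
#' canonical column set, in this order:
#' `trial_id, arm, n, mean_B, sd_B, se_B, mean_F, sd_F, se_F, mean_CS, sd_CS,
#' se_CS, r`. Suffix `B` denotes baseline, `F` follow-up and `CS` the change
#' score (follow-up minus baseline under the package sign convention). `r` is
#' the within-group baseline--follow-up correlation. Any statistic may be
#' missing (`NA`); `trial_id`, `arm` and `n` may not. Each trial must appear
#' exactly twice, once per arm (`"control"`, `"treatment"`; `0`/`1` are
#' accepted aliases on input). All SDs use the sample (n - 1) denominator.
#'
#' A *complete* dataset additionally has no missing means, SDs or
#' correlations, and satisfies the change-score identities
#' `mean_CS = mean_F - mean_B` and
#' `sd_CS^2 = sd_B^2 + sd_F^2 - 2 r sd_B sd_F`.
#'
#' @param df data frame with the canonical columns.
#' @return `meta_dataset()` returns a validated `meta_dataset`.
#' @seealso [read_dataset()], [validate_dataset()], [run_fillin()]
#' @export
meta_dataset <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CANONICAL_COLS, names(df))
  extra_cols   <- setdiff(names(df), CANONICAL_COLS)
  if (length(missing_cols) || length(extra_cols)) {
    stop_prepost(
      "dataset columns do not match the canonical schema%s%s",
      if (length(missing_cols)) paste0("; missing: ",
                                       paste(missing_cols, collapse = ", ")) else "",
      if (length(extra_cols)) paste0("; unknown: ",
                                     paste(extra_cols, collapse = ", ")) else "",
      class = "prepostMA_schema_error")
  }
  df <- df[, CANONICAL_COLS]
  df$trial_id <- as.character(df$trial_id)
  df$arm <- normalise_arm(df$arm)
  for (cl in NUMERIC_COLS) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(!is.na(df[[cl]]) & is.na(suppressWarnings(as.numeric(df[[cl]]))))
      if (length(bad)) {
        stop_prepost("non-numeric value in column '%s', row(s) %s",
                     cl, paste(bad, collapse = ", "),
                     class = "prepostMA_parse_error")
      }
      df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
    }
  }
  check_structure(df)
  rownames(df) <- NULL
  class(df) <- c("meta_dataset", "data.frame")
  df
}

normalise_arm <- function(arm) {
  a <- tolower(trimws(as.character(arm)))
  a[a %in% c("0", "c", "ctrl", "placebo")] <- "control"
  a[a %in% c("1", "t", "trt", "active")]   <- "treatment"
  bad <- which(!a %in% c("control", "treatment"))
  if (length(bad)) {
    stop_prepost("unrecognised arm label(s) in row(s) %s: %s",
                 paste(bad, collapse = ", "),
                 paste(unique(arm[bad]), collapse = ", "),
                 class = "prepostMA_parse_error")
  }
  a
}

check_structure <- function(df) {
  if (anyNA(df$n) || any(df$n < 1) || any(df$n != round(df$n))) {
    stop_prepost("sample size n must be a positive integer in every row",
                 class = "prepostMA_structure_error")
  }
  tab <- table(df$trial_id)
  bad <- names(tab)[tab != 2]
  if (length(bad)) {
    stop_prepost("each trial must contribute exactly two rows; offending trial(s): %s",
                 paste(bad, collapse = ", "),
                 class = "prepostMA_structure_error")
  }
  for (id in unique(df$trial_id)) {
    arms <- sort(df$arm[df$trial_id == id])
    if (!identical(arms, c("control", "treatment"))) {
      stop_prepost("trial '%s' must have one control and one treatment arm", id,
                   class = "prepostMA_structure_error")
    }
  }
  invisible(df)
}

#' Read a long-format summary dataset
#'
#' Reads a CSV (UTF-8, comma separated, `.` decimal) or XLSX file whose header
#' is exactly the canonical column set of [meta_dataset()]. Blank cells become
#' missing values. XLSX reading requires the `readxl` package.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`.
#' @param negate_change if `TRUE`, change-score means are multiplied by -1 on
#'   read, for files recorded under the baseline-minus-follow-up convention.
#' @return a [meta_dataset()].
#' @export
read_dataset <- function(path, format = c("auto", "csv", "xlsx"),
                         negate_change = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_prepost("file not found: %s", path, class = "prepostMA_io_error")
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", xlsx = "xlsx", xls = "xlsx",
                     stop_prepost("cannot infer format from extension of '%s'",
                                  path, class = "prepostMA_io_error"))
  }
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = c("", "NA"))
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_prepost("reading xlsx requires the 'readxl' package",
                   class = "prepostMA_io_error")
    }
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  }
  ds <- meta_dataset(df)
  if (negate_change) {
    ds$mean_CS <- -ds$mean_CS
  }
  ds
}

#' Write a summary dataset to CSV
#'
#' Missing values are written as blank cells, so `read_dataset()` restores
#' them as missing: the read/write round trip is the identity on valid
#' datasets. No XLSX writer is available, so `format = "xlsx"` is an error.
#'
#' @param ds a [meta_dataset()].
#' @param path output file path.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stop_prepost("xlsx export is not supported (no xlsx writer installed); use csv",
                 class = "prepostMA_io_error")
  }
  stopifnot(inherits(ds, "meta_dataset"))
  out <- as.data.frame(ds)
  # full precision so the round trip is exact
  for (cl in NUMERIC_COLS) out[[cl]] <- format(out[[cl]], digits = 17, trim = TRUE)
  out[out == "NA"] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Descriptive summary of a dataset
#'
#' One row per numeric column: number of present values, missingness rate,
#' mean, SD (n - 1 denominator), median, min and max over present values.
#'
#' @param ds a [meta_dataset()].
#' @return data frame with columns `column, n_present, missing_rate, mean, sd,
#'   median, min, max`. Fully missing columns report `missing_rate = 1` and
#'   `NA` statistics.
#' @export
describe_dataset <- function(ds) {
  stopifnot(inherits(ds, "meta_dataset"), nrow(ds) > 0)
  rows <- lapply(NUMERIC_COLS, function(cl) {
    x <- ds[[cl]]
    ok <- !is.na(x)
    data.frame(column = cl,
               n_present = sum(ok),
               missing_rate = mean(!ok),
               mean = if (any(ok)) mean(x[ok]) else NA_real_,
               sd = if (sum(ok) > 1) stats::sd(x[ok]) else if (sum(ok) == 1) 0 else NA_real_,
               median = if (any(ok)) stats::median(x[ok]) else NA_real_,
               min = if (any(ok)) min(x[ok]) else NA_real_,
               max = if (any(ok)) max(x[ok]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate a dataset against the schema invariants
#'
#' Checks every invariant of [meta_dataset()] and, with
#' `require_complete = TRUE`, the complete-dataset invariants (no missing
#' statistic; change-score mean and SD identities to relative tolerance
#' `tol`). An empty report means the dataset is valid.
#'
#' @param ds a [meta_dataset()].
#' @param require_complete also enforce completeness and internal consistency.
#' @param tol relative tolerance for the consistency identities.
#' @return data frame with columns `row, trial_id, arm, field, rule, message`;
#'   zero rows iff valid.
#' @export
validate_dataset <- function(ds, require_complete = FALSE, tol = 1e-6) {
  stopifnot(inherits(ds, "meta_dataset"))
  viol <- list()
  add <- function(row, field, rule, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      row = row, trial_id = ds$trial_id[row], arm = ds$arm[row],
      field = field, rule = rule, message = message)
  }
  for (i in seq_len(nrow(ds))) {
    for (f in c("sd_B", "sd_F", "sd_CS", "se_B", "se_F", "se_CS")) {
      if (!is.na(ds[[f]][i]) && ds[[f]][i] <= 0) {
        add(i, f, "positive", sprintf("%s must be > 0 (got %g)", f, ds[[f]][i]))
      }
    }
    if (!is.na(ds$r[i]) && abs(ds$r[i]) > 1) {
      add(i, "r", "range", sprintf("r outside [-1,1] (got %g)", ds$r[i]))
    }
    for (q in c("B", "F", "CS")) {
      sdv <- ds[[paste0("sd_", q)]][i]; sev <- ds[[paste0("se_", q)]][i]
      if (!is.na(sdv) && !is.na(sev) && sdv > 0 &&
          abs(sdv - sev * sqrt(ds$n[i])) > 1e-6 * sdv) {
        add(i, paste0("sd_", q), "sd_se_consistency",
            sprintf("sd_%s = %g inconsistent with se_%s * sqrt(n) = %g",
                    q, sdv, q, sev * sqrt(ds$n[i])))
      }
    }
    if (require_complete) {
      for (f in c("mean_B", "mean_F", "mean_CS", "sd_B", "sd_F", "sd_CS", "r")) {
        if (is.na(ds[[f]][i])) add(i, f, "complete", sprintf("%s is missing", f))
      }
      if (!anyNA(c(ds$mean_B[i], ds$mean_F[i], ds$mean_CS[i]))) {
        expect_cs <- ds$mean_F[i] - ds$mean_B[i]
        if (!abs_or_rel_ok(ds$mean_CS[i], expect_cs, tol)) {
          add(i, "mean_CS", "mean_consistency",
              sprintf("mean_CS = %g but mean_F - mean_B = %g",
                      ds$mean_CS[i], expect_cs))
        }
      }
      if (!anyNA(c(ds$sd_B[i], ds$sd_F[i], ds$sd_CS[i], ds$r[i]))) {
        expect_var <- ds$sd_B[i]^2 + ds$sd_F[i]^2 - 2 * ds$r[i] * ds$sd_B[i] * ds$sd_F[i]
        if (!abs_or_rel_ok(ds$sd_CS[i]^2, expect_var, tol)) {
          add(i, "sd_CS", "sd_consistency",
              sprintf("sd_CS^2 = %g but sd_B^2 + sd_F^2 - 2 r sd_B sd_F = %g",
                      ds$sd_CS[i]^2, expect_var))
        }
      }
    }
  }
  if (!length(viol)) {
    out <- data.frame(row = integer(), trial_id = character(),
                      arm = character(), field = character(),
                      rule = character(), message = character())
  } else {
    out <- do.call(rbind, viol)
    rownames(out) <- NULL
  }
  out
}

#' @export
print.meta_dataset <- function(x, ...) {
  k <- length(unique(x$trial_id))
  miss <- sum(is.na(as.matrix(x[STAT_COLS])))
  cat(sprintf("<meta_dataset>  %d trials, %d arms, %d missing cells\n",
              k, nrow(x), miss))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Number of trials in a dataset
#' @param ds a [meta_dataset()].
#' @return integer count of distinct trials.
#' @export
n_trials <- function(ds) length(unique(ds$trial_id))

#' Is the dataset analysis-ready?
#' @param ds a [meta_dataset()].
#' @param tol relative tolerance for consistency identities.
#' @return `TRUE` iff `validate_dataset(ds, require_complete = TRUE)` is empty.
#' @export
is_complete <- function(ds, tol = 1e-6) {
  nrow(validate_dataset(ds, require_complete = TRUE, tol = tol)) == 0L
}

# split into per-trial two-row data frames, control row first
split_trials <- function(ds) {
  ids <- unique(ds$trial_id)
  stats::setNames(lapply(ids, function(id) {
    tr <- ds[ds$trial_id == id, , drop = FALSE]
    tr[order(tr$arm), , drop = FALSE]  # control < treatment
  }), ids)
}

#' Write the canonical template file
#'
#' Writes an empty CSV with the canonical header plus one example trial, for
#' users preparing their own data.
#'
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_template <- function(path) {
  ex <- data.frame(trial_id = c("trial01", "trial01"),
                   arm = c("control", "treatment"),
                   n = c(25L, 25L),
                   mean_B = c(71.2, 70.1), sd_B = c(9.5, 9.8), se_B = NA_real_,
                   mean_F = c(71.5, 69.2), sd_F = c(9.7, 9.9), se_F = NA_real_,
                   mean_CS = NA_real_, sd_CS = c(3.9, 4.1), se_CS = NA_real_,
                   r = NA_real_)
  write_dataset(meta_dataset(ex), path)
}
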