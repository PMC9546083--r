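#' Run the full analysis pipeline and export results
#'
#' Executes read -> validate -> fill-in -> effects / pseudo-IPD -> models ->
#' pooling -> plots, and writes a results directory containing
#' `results.json` (all estimates, CIs, tau2, I2, H2, convergence info, at
#' full precision), per-method effect tables (CSV), forest and funnel plots
#' with their plot-data CSVs, the fill-in provenance report, and
#' `log.txt` recording the package version, seed and configuration. On any
#' stage error the partially written directory is removed.
#'
#' @param config list (or path to a `key = value` text file) with entries:
#'   `input` (path, required unless `dataset` given), `dataset` (a
#'   [meta_dataset()], alternative to `input`), `out_dir` (required),
#'   `methods` (subset of `followup`, `change`, `ancova`, `onestage`,
#'   `twostage`; default all five), `model` (`"RE"`/`"CE"`), `hk`,
#'   `interaction`, `resid_structure`, `corr_strategy`, `corr_value`,
#'   `level`, `seed`, `plot_format` (`"pdf"`/`"png"`).
#' @return invisibly, the result bundle (named list of fitted objects).
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(
    list(input = NULL, dataset = NULL, out_dir = NULL,
         methods = c("followup", "change", "ancova", "twostage", "onestage"),
         model = "RE", hk = FALSE, interaction = FALSE,
         resid_structure = "study", corr_strategy = "weighted_mean",
         corr_value = NULL, level = 0.95, seed = 1L, plot_format = "pdf"),
    config[!vapply(config, is.null, logical(1))])
  if (is.null(cfg$out_dir)) {
    stop_prepost("config must name an out_dir", class = "prepostMA_config_error")
  }
  created <- !dir.exists(cfg$out_dir)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  tryCatch({
    stage <- "read"
    ds <- if (!is.null(cfg$dataset)) cfg$dataset else read_dataset(cfg$input)
    stage <- "validate"
    issues <- validate_dataset(ds)
    if (nrow(issues)) {
      stop_prepost("input fails validation: %s",
                   paste(utils::head(issues$message, 5), collapse = "; "),
                   class = "prepostMA_domain_error")
    }
    stage <- "fillin"
    fl <- run_fillin(ds, corr_strategy = cfg$corr_strategy,
                     corr_value = cfg$corr_value)
    utils::write.csv(fl$report, file.path(cfg$out_dir, "fill_report.csv"),
                     row.names = FALSE)
    write_dataset(fl$dataset, file.path(cfg$out_dir, "complete.csv"))
    complete <- fl$dataset

    results <- list()
    pool_one <- function(eff) {
      if (cfg$model == "RE" && nrow(eff) >= 2) {
        pool_re(eff, level = cfg$level, hk = cfg$hk)
      } else {
        pool_ce(eff, level = cfg$level)
      }
    }
    for (m in intersect(cfg$methods, c("followup", "change", "ancova"))) {
      stage <- paste0("effects:", m)
      eff <- compute_effects(complete, m)
      pooled <- pool_one(eff)
      utils::write.csv(eff, file.path(cfg$out_dir, paste0("effects_", m, ".csv")),
                       row.names = FALSE)
      forest_plot(eff, pooled,
                  file.path(cfg$out_dir, paste0("forest_", m, ".", cfg$plot_format)),
                  cfg$plot_format)
      if (nrow(eff) >= 2) {
        funnel_plot(eff, pooled,
                    file.path(cfg$out_dir, paste0("funnel_", m, ".", cfg$plot_format)),
                    cfg$plot_format)
      }
      results[[m]] <- list(effects = eff, pooled = unclass(pooled))
    }
    if (any(c("onestage", "twostage") %in% cfg$methods)) {
      stage <- "pseudo_ipd"
      ipd <- generate_pseudo_ipd(complete, seed = cfg$seed)
      utils::write.csv(as.data.frame(ipd), file.path(cfg$out_dir, "pseudo_ipd.csv"),
                       row.names = FALSE)
      if ("twostage" %in% cfg$methods) {
        stage <- "twostage"
        ts <- twostage(ipd, model = cfg$model, hk = cfg$hk,
                       interaction = cfg$interaction, level = cfg$level)
        forest_plot(ts$trials, ts$theta,
                    file.path(cfg$out_dir, paste0("forest_twostage.", cfg$plot_format)),
                    cfg$plot_format)
        results$twostage <- list(theta = unclass(ts$theta),
                                 interaction = if (!is.null(ts$interaction))
                                   unclass(ts$interaction),
                                 trials = ts$trials)
      }
      if ("onestage" %in% cfg$methods) {
        stage <- "onestage"
        os <- fit_onestage(ipd, resid_structure = cfg$resid_structure,
                           model = cfg$model, interaction = cfg$interaction,
                           level = cfg$level, seed = cfg$seed)
        results$onestage <- unclass(os)
      }
    }
    stage <- "export"
    json <- list(package = "prepostMA",
                 version = as.character(utils::packageVersion("prepostMA")),
                 seed = cfg$seed,
                 config = cfg[setdiff(names(cfg), "dataset")],
                 provenance = fl$report,
                 results = results)
    jsonlite::write_json(json, file.path(cfg$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE, pretty = TRUE)
    writeLines(c(sprintf("prepostMA %s", utils::packageVersion("prepostMA")),
                 sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("seed: %d", cfg$seed),
                 "config:",
                 utils::capture.output(utils::str(cfg[setdiff(names(cfg), "dataset")]))),
               file.path(cfg$out_dir, "log.txt"))
    invisible(results)
  }, error = function(e) {
    if (created) unlink(cfg$out_dir, recursive = TRUE)
    stop_prepost("analysis failed at stage '%s': %s", stage,
                 conditionMessage(e), class = "prepostMA_pipeline_error")
  })
}

# flat key = value config file; values parsed as logical/numeric when possible
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (key == "methods") {
      val <- trimws(strsplit(val, ",")[[1]])
    } else if (toupper(val) %in% c("TRUE", "FALSE")) {
      val <- as.logical(val)
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    }
    cfg[[key]] <- val
  }
  cfg
}
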