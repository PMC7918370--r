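#' End-to-end pipeline driver
#'
#' Orchestrates the full analysis behind one configuration object: load or
#' simulate a panel, baseline-scale, fit the mixed trend model, diagnose
#' residual autocorrelation, whiten with per-subject ARIMA models (unless
#' running naive-only), compare groups per timepoint, and write
#' publication-style artifacts (fit summary, model list, ACF diagnostics,
#' comparison tables, window plots) plus a JSON manifest into an output
#' directory. The thin command-line wrapper in
#' `system.file("scripts", "tsgc.R", package = "tsgc")` exposes the same
#' entry points as shell subcommands.
#'
#' @name cli_report
NULL

#' Pipeline run configuration
#'
#' @param input path to a panel CSV, or a `tsgc_sim_config` to simulate.
#' @param out_dir output directory (created if absent).
#' @param schema optional column mapping for [read_panel()].
#' @param reference reference group label (default: first in sort order).
#' @param mode `"corrected"`, `"naive"` or `"both"`.
#' @param alpha per-timepoint family level, in (0, 1).
#' @param min_d,p_max,q_max ARIMA-stage settings.
#' @param var_equal pooled (default) vs Welch per-timepoint tests.
#' @param interval minutes per time step for CSV input.
#' @param scale apply baseline scaling after loading (default TRUE).
#' @param log_transform log-transform values on read (default FALSE).
#' @param seed RNG seed for the run (simulation replicates reseed from it).
#' @param make_plots write PNG diagnostics (default TRUE).
#' @return object of class `tsgc_run_config`.
#' @export
run_config <- function(input, out_dir, schema = NULL, reference = NULL,
                       mode = c("corrected", "naive", "both"), alpha = 0.05,
                       min_d = 1L, p_max = 5L, q_max = 5L, var_equal = TRUE,
                       interval = 2, scale = TRUE, log_transform = FALSE,
                       seed = 1L, make_plots = TRUE) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1)
  if (!(is.character(input) || inherits(input, "tsgc_sim_config")))
    stop("input must be a CSV path or a tsgc_sim_config", call. = FALSE)
  structure(list(input = input, out_dir = out_dir, schema = schema,
                 reference = reference, mode = mode, alpha = alpha,
                 min_d = min_d, p_max = p_max, q_max = q_max,
                 var_equal = var_equal, interval = interval, scale = scale,
                 log_transform = log_transform, seed = as.integer(seed),
                 make_plots = make_plots),
            class = "tsgc_run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulate` key
#' holds [sim_config()] arguments instead of an input path.
#'
#' @param path YAML (.yml/.yaml) or JSON config file.
#' @param out_dir overrides the config's output directory if given.
#' @return a `tsgc_run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$simulate)) {
    input <- do.call(sim_config, cfg$simulate)
    cfg$simulate <- NULL
  } else {
    input <- cfg$input
  }
  cfg$input <- NULL
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(cfg$schema)) cfg$schema <- unlist(cfg$schema)
  do.call(run_config, c(list(input = input), cfg))
}

.write_artifact <- function(obj, path, manifest) {
  utils::write.csv(obj, path, row.names = FALSE)
  c(manifest, path)
}

#' Run the full pipeline
#'
#' Executes load/simulate -> scale -> trend fit -> ACF diagnostics ->
#' per-subject ARIMA (unless naive-only) -> combine -> per-timepoint
#' pairwise tests, logging each stage's key statistics, and writes all
#' artifacts plus `manifest.json` under `config$out_dir`.
#'
#' @param config a `tsgc_run_config`.
#' @return invisibly, a list with every fitted object (`panel`, `lmm_fit`,
#'   `whiteness_pre`, `arima_fits`, `reports`) and the artifact `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tsgc_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  set.seed(config$seed)

  if (inherits(config$input, "tsgc_sim_config")) {
    message("stage simulate: generating panel (seed ", config$input$seed, ")")
    sim <- generate_panel(config$input)
    panel <- sim$panel
    manifest <- c(manifest, write_panel(panel, file.path(config$out_dir,
                                                         "panel.csv")))
  } else {
    message("stage load: reading ", config$input)
    panel <- read_panel(config$input, schema = config$schema,
                        interval = config$interval,
                        reference = config$reference,
                        log_transform = config$log_transform)
  }
  if (config$scale) panel <- scale_to_baseline(panel)
  ax <- time_axis(panel)
  message("stage panel: ", length(unique(panel$subject)), " subjects x ",
          ax$n_timepoints, " timepoints (", nrow(panel), " observations)")

  lmm <- fit_lmm(panel)
  message("stage lmm: logLik ", format(lmm$loglik), ", AIC ",
          format(lmm$aic), if (lmm$singular) " [singular covariance]")
  manifest <- .write_artifact(lmm_summary_table(lmm),
                              file.path(config$out_dir, "fit_summary.csv"),
                              manifest)

  wh_pre <- whiteness_report(lmm)
  message("stage diagnostics: initial residual whiteness ",
          if (wh_pre$pass) "PASS" else "FAIL",
          " (mean significant-lag fraction ",
          format(wh_pre$mean_fraction, digits = 3), ")")
  manifest <- .write_artifact(wh_pre$subjects,
                              file.path(config$out_dir, "whiteness_pre.csv"),
                              manifest)

  arima_fits <- NULL
  reports <- list()
  if (config$mode %in% c("corrected", "both")) {
    arima_fits <- fit_all_residuals(lmm, min_d = config$min_d,
                                    p_max = config$p_max,
                                    q_max = config$q_max)
    message("stage arima: whitened-residual whiteness ",
            if (arima_fits$whiteness$pass) "PASS" else "FAIL",
            " (mean significant-lag fraction ",
            format(arima_fits$whiteness$mean_fraction, digits = 3), ")")
    manifest <- .write_artifact(arima_model_table(arima_fits),
                                file.path(config$out_dir, "arima_models.csv"),
                                manifest)
    manifest <- .write_artifact(arima_fits$whiteness$subjects,
                                file.path(config$out_dir,
                                          "whiteness_post.csv"), manifest)
    comb <- combine_fits(lmm, arima_fits)
    reports$corrected <- pairwise_windows(comb, alpha = config$alpha,
                                          var_equal = config$var_equal)
  }
  if (config$mode %in% c("naive", "both")) {
    comb <- combine_fits(lmm, mode = "naive")
    reports$naive <- pairwise_windows(comb, alpha = config$alpha,
                                      var_equal = config$var_equal)
  }
  for (m in names(reports)) {
    rep <- reports[[m]]
    message("stage inference (", m, "): corrected threshold ",
            format(rep$threshold, digits = 4), "; ",
            nrow(rep$windows), " window(s)")
    manifest <- .write_artifact(rep$tests,
                                file.path(config$out_dir,
                                          paste0("report_", m, ".csv")),
                                manifest)
    manifest <- .write_artifact(rep$windows,
                                file.path(config$out_dir,
                                          paste0("windows_", m, ".csv")),
                                manifest)
  }

  if (config$make_plots) {
    meta <- panel_subjects(panel)
    titles <- sprintf("%s: %s: %s", meta$group, meta$replicate,
                      meta$experiment)
    names(titles) <- meta$subject
    p1 <- file.path(config$out_dir, "acf_pre.png")
    grDevices::png(p1, width = 1600, height = 1200)
    plot_acf_grid(wh_pre, titles = titles)
    grDevices::dev.off()
    manifest <- c(manifest, p1)
    if (!is.null(arima_fits)) {
      p2 <- file.path(config$out_dir, "acf_post.png")
      grDevices::png(p2, width = 1600, height = 1200)
      plot_acf_grid(arima_fits$whiteness, titles = titles)
      grDevices::dev.off()
      manifest <- c(manifest, p2)
    }
    if (length(reports)) {
      p3 <- file.path(config$out_dir, "windows.png")
      grDevices::png(p3, width = 1200, height = 900)
      plot(reports[[if ("corrected" %in% names(reports)) "corrected"
                    else "naive"]],
           naive = reports$naive)
      grDevices::dev.off()
      manifest <- c(manifest, p3)
    }
  }

  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(list(artifacts = manifest,
                            mode = config$mode, alpha = config$alpha,
                            threshold = if (length(reports))
                              reports[[1L]]$threshold else NULL,
                            seed = config$seed),
                       mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- c(manifest, mpath)
  invisible(list(panel = panel, lmm_fit = lmm, whiteness_pre = wh_pre,
                 arima_fits = arima_fits, reports = reports,
                 manifest = manifest))
}
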