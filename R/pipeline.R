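#' Run one stage of the fatigue-kinetics pipeline
#'
#' Ties the analysis stages together behind a single entry point with
#' file-based interchange, suitable for scripting (a thin command-line
#' wrapper ships in `inst/cli/fatkin.R`). All randomness derives from the
#' single integer `seed`; every run logs seed, package version and a
#' config hash to stderr.
#'
#' Modes:
#' \describe{
#'   \item{simulate}{generate a synthetic cohort: ground-truth parameter
#'     CSV (with `is_truth = 1`), noisy long-format series CSV, and one
#'     example neuromuscular-test trace CSV with its ground truth.}
#'   \item{extract}{extract neuromuscular metrics from trace CSVs
#'     (`config$trace_files`).}
#'   \item{fit}{fit the exponential model to every series of
#'     `config$series_file`; writes long fits CSV and a wide display
#'     table.}
#'   \item{decrement}{estimate VA / evoked torque at stated torque
#'     decrements from `config$fits_file`.}
#'   \item{stats}{paired-comparison battery, parameter correlations and
#'     cohort summary from `config$fits_file` (optionally
#'     `config$decrements_file`); writes `stats_report.json` and
#'     `correlations.csv`.}
#'   \item{reproduce}{run correlations and comparisons on the packaged
#'     reference cohort and write the computed values side by side with
#'     the published ones (`reproduction_report.json`).}
#' }
#'
#' @param mode one of `simulate`, `extract`, `fit`, `decrement`, `stats`,
#'   `reproduce`.
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param config named list of stage options, or path to a YAML file with
#'   the same structure.
#' @return invisibly, a named list of the files written.
#' @export
run_pipeline <- function(mode = c("simulate", "extract", "fit", "decrement",
                                  "stats", "reproduce"),
                         out_dir, seed = 1L, config = list()) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(seed)

  cfg_file <- file.path(out_dir, paste0(mode, "_config.yaml"))
  yaml::write_yaml(c(list(mode = mode, seed = seed), config), cfg_file)
  message(sprintf("[fatkin] mode=%s seed=%d version=%s config_md5=%s",
                  mode, seed,
                  as.character(utils::packageVersion("fatkin")),
                  unname(tools::md5sum(cfg_file))))

  stage <- function(expr, name) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  written <- list(config = cfg_file)

  if (mode == "simulate") {
    written <- c(written, stage({
      cc <- cohort_config(
        n_subjects = config$n_subjects %||% 13,
        noise_sd = config$noise_sd %||% 4,
        times = config$times %||% seq(0, 160, by = 20),
        seed = seed)
      sim <- simulate_cohort(cc)
      truth <- dplyr::mutate(
        cohort_parameters_long(sim$parameters),
        is_truth = 1L) |>
        dplyr::rename(A_pct = "A", tau_s = "tau")
      p1 <- file.path(out_dir, "true_parameters.csv")
      readr::write_csv(truth, p1)
      p2 <- file.path(out_dir, "series.csv")
      write_series_csv(sim$observations, p2)
      tr <- generate_nm_trace(trace_config(
        baseline_noise_sd = config$trace_noise_sd %||% 0, seed = seed))
      p3 <- file.path(out_dir, "example_trace.csv")
      write_trace_csv(tr, p3)
      p4 <- file.path(out_dir, "example_trace_truth.csv")
      readr::write_csv(tr$truth, p4)
      list(true_parameters = p1, series = p2, trace = p3, trace_truth = p4)
    }, "simulate"))
  } else if (mode == "extract") {
    written <- c(written, stage({
      files <- config$trace_files
      if (is.null(files)) stop("config$trace_files is required")
      metrics <- purrr::map_dfr(files, function(f)
        dplyr::mutate(extract_nm_metrics(read_trace_csv(f)),
                      source = basename(f), .before = 1))
      p <- file.path(out_dir, "nm_metrics.csv")
      readr::write_csv(metrics, p)
      list(nm_metrics = p)
    }, "extract"))
  } else if (mode == "fit") {
    written <- c(written, stage({
      if (is.null(config$series_file))
        stop("config$series_file is required")
      series <- read_series_csv(config$series_file)
      fits <- fit_cohort(series,
                         include_t0 = config$include_t0 %||% TRUE)
      p1 <- file.path(out_dir, "fits.csv")
      write_fits_csv(fits, p1)
      p2 <- file.path(out_dir, "fits_wide.csv")
      write_cohort_wide_csv(fits, p2)
      list(fits = p1, fits_wide = p2)
    }, "fit"))
  } else if (mode == "decrement") {
    written <- c(written, stage({
      if (is.null(config$fits_file)) stop("config$fits_file is required")
      fits <- read_fits_csv(config$fits_file)
      est <- estimate_decrements(fits,
                                 levels = config$levels %||% c(10, 20, 30))
      p1 <- file.path(out_dir, "decrements.csv")
      readr::write_csv(est, p1)
      p2 <- file.path(out_dir, "decrement_means.csv")
      readr::write_csv(decrement_means(est), p2)
      list(decrements = p1, decrement_means = p2)
    }, "decrement"))
  } else if (mode == "stats") {
    written <- c(written, stage({
      if (is.null(config$fits_file)) stop("config$fits_file is required")
      fits <- read_fits_csv(config$fits_file)
      dec <- if (!is.null(config$decrements_file))
        readr::read_csv(config$decrements_file, show_col_types = FALSE)
      comp <- run_condition_comparisons(fits, decrements = dec,
                                        family_size = config$family_size)
      corr <- run_parameter_correlations(fits)
      p1 <- file.path(out_dir, "stats_report.json")
      jsonlite::write_json(
        list(comparisons = comp, correlations = corr,
             summary = summarize_cohort(fits)),
        p1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      p2 <- file.path(out_dir, "correlations.csv")
      readr::write_csv(corr, p2)
      list(stats_report = p1, correlations = p2)
    }, "stats"))
  } else if (mode == "reproduce") {
    written <- c(written, stage({
      cohort <- load_reference_cohort()
      corr <- run_parameter_correlations(cohort)
      comp <- run_condition_comparisons(cohort)
      ref <- reference_reported_stats()
      corr_cmp <- dplyr::left_join(corr, ref$correlations, by = "label") |>
        dplyr::mutate(delta_r_squared = .data$r_squared -
                        .data$reported_r_squared,
                      sign_match = sign(.data$slope) == .data$reported_sign)
      comp_cmp <- dplyr::left_join(comp, ref$comparisons, by = "test") |>
        dplyr::mutate(delta_p = .data$p_raw - .data$reported_p)
      p1 <- file.path(out_dir, "reproduction_report.json")
      jsonlite::write_json(
        list(correlations = corr_cmp, comparisons = comp_cmp,
             summary = summarize_cohort(cohort)),
        p1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      p2 <- file.path(out_dir, "correlations.csv")
      readr::write_csv(corr_cmp, p2)
      list(reproduction_report = p1, correlations = p2)
    }, "reproduce"))
  }
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
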