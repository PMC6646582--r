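#' @title CSV interchange formats
#' @description Long-format CSV is the canonical interchange between
#'   pipeline stages: series files (`subject_id,condition,variable,
#'   time_s,value_pct`), trace files (`time_s,torque_nm,stim`) and
#'   fitted-parameter files (`subject_id,condition,variable,A_pct,tau_s,
#'   r_squared,p_value,converged`). Readers validate schemas and reject
#'   duplicates; writers round-trip at full float precision.
#' @name fatkin-io
NULL

series_cols <- c("subject_id", "condition", "variable", "time_s", "value_pct")
fits_cols <- c("subject_id", "condition", "variable", "A_pct", "tau_s")

check_schema <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

check_series_schema <- function(df) {
  check_schema(df, series_cols, "series table")
  bad_cond <- setdiff(unique(df$condition), c("HF", "LF"))
  if (length(bad_cond))
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  bad_var <- setdiff(unique(df$variable), c("IMVC", "VA", "QTW"))
  if (length(bad_var))
    stop("unknown variable(s): ", paste(bad_var, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

check_fits_schema <- function(df) check_schema(df, fits_cols, "fits table")

#' Read a long-format fatigue series CSV
#'
#' @param path CSV with columns `subject_id,condition,variable,time_s,
#'   value_pct` (header mandatory; `condition` in HF/LF, `variable` in
#'   IMVC/VA/QTW).
#' @return tibble sorted by subject, condition, variable and time.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_series_schema(df)
  if (anyDuplicated(df[c("subject_id", "condition", "variable", "time_s")]))
    stop("duplicate (subject, condition, variable, time) rows", call. = FALSE)
  dplyr::arrange(df, .data$subject_id, .data$condition, .data$variable,
                 .data$time_s)
}

#' @rdname read_series_csv
#' @param series series tibble to write.
#' @param path output path.
#' @export
write_series_csv <- function(series, path) {
  check_series_schema(series)
  readr::write_csv(series, path)
  invisible(path)
}

#' Read / write a raw torque trace CSV
#'
#' @param path CSV with columns `time_s,torque_nm,stim` (stim is 0/1,
#'   1 marking stimulus-onset samples).
#' @return trace tibble.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("time_s", "torque_nm", "stim"), "trace file")
  check_trace(df)
  df
}

#' @rdname read_trace_csv
#' @param trace trace tibble (or `nm_trace`) to write.
#' @export
write_trace_csv <- function(trace, path) {
  trace <- as_trace(trace)
  check_schema(trace, c("time_s", "torque_nm", "stim"), "trace table")
  readr::write_csv(trace, path)
  invisible(path)
}

#' Read / write a fitted-parameter CSV
#'
#' @param path CSV with columns `subject_id,condition,variable,A_pct,
#'   tau_s` and optionally `r_squared,p_value,converged`.
#' @return fits tibble.
#' @export
read_fits_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_fits_schema(df)
  df
}

#' @rdname read_fits_csv
#' @param fits fits tibble to write.
#' @export
write_fits_csv <- function(fits, path) {
  check_fits_schema(fits)
  readr::write_csv(fits, path)
  invisible(path)
}

#' Export a cohort parameter table in wide display layout
#'
#' Row-per-subject layout with one `A (%) / tau (s) / R^2` triplet per
#' variable and condition, the asymptotes and curvature constants rounded
#' to integers for display (internal computations are never rounded).
#'
#' @param fits long fitted-parameter table including `r_squared`.
#' @param path output CSV path.
#' @return the wide tibble, invisibly.
#' @export
write_cohort_wide_csv <- function(fits, path) {
  check_fits_schema(fits)
  wide <- fits |>
    dplyr::mutate(A_pct = round(.data$A_pct),
                  tau_s = round(.data$tau_s),
                  r_squared = round(.data$r_squared, 2)) |>
    tidyr::pivot_wider(id_cols = "subject_id",
                       names_from = c("condition", "variable"),
                       values_from = c("A_pct", "tau_s", "r_squared"),
                       names_glue = "{condition}_{variable}_{.value}")
  readr::write_csv(wide, path)
  invisible(wide)
}

#' Load the packaged 13-subject reference cohort
#'
#' Individual exponential fatigue-model parameters (asymptote, curvature
#' constant and R-squared for IMVC, voluntary activation and evoked torque
#' under both the high-force and low-force condition) for the 13 subjects
#' of a published knee-extensor fatigue study, as printed: integer-valued
#' `A` and `tau`, two-decimal R-squared. This fixture drives the desk
#' reproduction of the group-level statistics.
#'
#' @return long tibble with 78 rows: `subject_id`, `condition`,
#'   `variable`, `A_pct`, `tau_s`, `r_squared`.
#' @export
load_reference_cohort <- function() {
  path <- system.file("extdata", "reference_cohort.csv", package = "fatkin",
                      mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, col_types = "cccddd")
  check_fits_schema(df)
  df
}

#' Reported group-level statistics of the reference study
#'
#' The published regression and paired-test results that
#' [run_pipeline()]'s `reproduce` mode compares against: coefficients of
#' determination for the parameter correlations and raw p-values for the
#' HF-vs-LF paired comparisons, as printed in the source publication of
#' the reference cohort.
#'
#' @return list with tibbles `correlations` (`label`,
#'   `reported_r_squared`, `reported_sign`) and `comparisons` (`test`,
#'   `reported_p`).
#' @export
reference_reported_stats <- function() {
  list(
    correlations = tibble::tribble(
      ~label,                ~reported_r_squared, ~reported_sign,
      "A_VA~A_QTW_HF",       0.49, -1,
      "A_VA~A_QTW_LF",       0.46, -1,
      "tau_VA~tau_QTW_HF",   0.68, -1,
      "tau_VA~tau_QTW_LF",   0.33,  1,
      "A_QTW_HF~A_QTW_LF",   0.43,  1,
      "A_VA_HF~A_VA_LF",     0.11,  1,
      "A_IMVC_HF~A_IMVC_LF", 0.10,  1),
    comparisons = tibble::tribble(
      ~test,               ~reported_p,
      "A_IMVC_HFvsLF",     0.005,
      "tau_IMVC_HFvsLF",   0.044,
      "A_VA_HFvsLF",       0.001,
      "tau_VA_HFvsLF",     0.004,
      "A_QTW_HFvsLF",      0.025,
      "tau_QTW_HFvsLF",    0.544))
}
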