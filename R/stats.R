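#' Paired t-test with Bonferroni-adjusted p-value
#'
#' Classical two-sided paired t-test on matched vectors, reporting both the
#' raw p-value and a Bonferroni-corrected one for a stated family size.
#' Zero-variance differences are handled explicitly: identical vectors give
#' `t = 0, p = 1`; a constant nonzero difference is reported with infinite
#' t and `p = 0`, flagged `degenerate`.
#'
#' @param x,y equal-length numeric vectors of paired measurements.
#' @param family_size number of tests in the correction family (>= 1).
#' @return one-row tibble: `mean_diff`, `t_stat`, `df`, `p_raw`,
#'   `p_bonferroni`, `family_size`, `n`, `degenerate`.
#' @export
paired_t_test <- function(x, y, family_size = 1) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (family_size < 1) stop("`family_size` must be >= 1", call. = FALSE)
  d <- x - y
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    if (mean(d) == 0) { tval <- 0; p <- 1 } else { tval <- Inf; p <- 0 }
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    tval <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble::tibble(mean_diff = mean(d), t_stat = tval, df = n - 1L,
                 p_raw = p, p_bonferroni = min(1, p * family_size),
                 family_size = as.integer(family_size), n = n,
                 degenerate = degenerate)
}

#' Simple linear regression with signed correlation
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, intercept,
#' signed Pearson correlation `r`, coefficient of determination
#' `r_squared`, and the slope's t-test p-value on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors, `n >= 3`; `x` must have nonzero variance.
#' @return one-row tibble: `slope`, `intercept`, `r`, `r_squared`,
#'   `p_value`, `n`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("`x` has zero variance; regression undefined", call. = FALSE)
  m <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(m)) # exact fits warn harmlessly
  slope <- unname(stats::coef(m)[2])
  r2 <- s$r.squared
  r <- sign(slope) * sqrt(r2)
  p <- if (stats::sd(y) == 0) 1 else unname(s$coefficients[2, 4])
  tibble::tibble(slope = slope, intercept = unname(stats::coef(m)[1]),
                 r = r, r_squared = r2, p_value = p, n = length(x))
}

# Pivot a long cohort table (subject_id, condition, variable, A_pct,
# tau_s, ...) to one wide column per parameter_variable_condition. Internal.
cohort_wide <- function(cohort) {
  check_fits_schema(cohort)
  cohort |>
    dplyr::select("subject_id", "condition", "variable",
                  A = "A_pct", tau = "tau_s") |>
    tidyr::pivot_longer(c("A", "tau"), names_to = "parameter") |>
    tidyr::pivot_wider(names_from = c("parameter", "variable", "condition"),
                       names_sep = "_", values_from = "value")
}

#' Paired HF-versus-LF comparisons across the parameter battery
#'
#' Runs the paired t-test battery of the analysis: force-condition (HF vs
#' LF) comparisons of the asymptote and curvature constant for each of
#' IMVC, VA and evoked torque, plus — when decrement estimates are
#' supplied — VA and evoked torque estimated at each torque decrement.
#' Both raw and Bonferroni-corrected p-values are always reported; the
#' family size defaults to the number of tests actually executed in the
#' battery.
#'
#' @param cohort long fitted-parameter table (`subject_id`, `condition`,
#'   `variable`, `A_pct`, `tau_s`).
#' @param decrements optional output of [estimate_decrements()]; paired
#'   comparisons use subjects reachable in both conditions.
#' @param family_size Bonferroni family size; default = number of tests
#'   run.
#' @return tibble with one row per test: `test`, `variable`, `parameter`,
#'   plus the [paired_t_test()] columns.
#' @export
run_condition_comparisons <- function(cohort, decrements = NULL,
                                      family_size = NULL) {
  wide <- cohort_wide(cohort)
  specs <- tidyr::expand_grid(parameter = c("A", "tau"),
                              variable = c("IMVC", "VA", "QTW"))
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    p <- specs$parameter[i]; v <- specs$variable[i]
    cx <- paste(p, v, "HF", sep = "_"); cy <- paste(p, v, "LF", sep = "_")
    if (!all(c(cx, cy) %in% names(wide)) ||
        all(is.na(wide[[cx]])) || all(is.na(wide[[cy]]))) {
      warning(sprintf("no data for %s of %s; test skipped", p, v),
              call. = FALSE)
      next
    }
    res <- paired_t_test(wide[[cx]], wide[[cy]])
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(test = sprintf("%s_%s_HFvsLF", p, v),
                     variable = v, parameter = p), res)
  }
  if (!is.null(decrements)) {
    dec_wide <- decrements |>
      dplyr::filter(.data$reachable) |>
      tidyr::pivot_wider(id_cols = c("subject_id", "variable",
                                     "imvc_decrease"),
                         names_from = "condition",
                         values_from = "dv_value")
    combos <- dplyr::distinct(decrements, .data$variable,
                              .data$imvc_decrease)
    for (i in seq_len(nrow(combos))) {
      v <- combos$variable[i]; lev <- combos$imvc_decrease[i]
      dd <- dplyr::filter(dec_wide, .data$variable == v,
                          .data$imvc_decrease == lev)
      if (!all(c("HF", "LF") %in% names(dd))) next
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(test = sprintf("%s_at_%d_HFvsLF", v, lev),
                       variable = v, parameter = sprintf("dec%d", lev)),
        paired_t_test(dd$HF, dd$LF))
    }
  }
  out <- dplyr::bind_rows(rows)
  fam <- if (is.null(family_size)) nrow(out) else family_size
  out$family_size <- as.integer(fam)
  out$p_bonferroni <- pmin(1, out$p_raw * fam)
  out
}

#' Correlations between individual fatigue-model parameters
#'
#' The regression battery over individual fitted parameters: voluntary
#' activation versus evoked-torque asymptotes within each force condition,
#' their curvature constants within each condition, the evoked-torque
#' asymptotes across conditions, and the (expected non-significant)
#' across-condition checks for the VA and IMVC asymptotes.
#'
#' @param cohort long fitted-parameter table.
#' @return tibble with one row per regression: `label`, `x`, `y`, plus the
#'   [linear_regression()] columns.
#' @export
run_parameter_correlations <- function(cohort) {
  wide <- cohort_wide(cohort)
  specs <- tibble::tribble(
    ~label,                ~x,           ~y,
    "A_VA~A_QTW_HF",       "A_QTW_HF",   "A_VA_HF",
    "A_VA~A_QTW_LF",       "A_QTW_LF",   "A_VA_LF",
    "tau_VA~tau_QTW_HF",   "tau_QTW_HF", "tau_VA_HF",
    "tau_VA~tau_QTW_LF",   "tau_QTW_LF", "tau_VA_LF",
    "A_QTW_HF~A_QTW_LF",   "A_QTW_HF",   "A_QTW_LF",
    "A_VA_HF~A_VA_LF",     "A_VA_HF",    "A_VA_LF",
    "A_IMVC_HF~A_IMVC_LF", "A_IMVC_HF",  "A_IMVC_LF")
  purrr::pmap_dfr(specs, function(label, x, y) {
    dplyr::bind_cols(tibble::tibble(label = label, x = x, y = y),
                     linear_regression(wide[[x]], wide[[y]]))
  })
}

#' Column-wise cohort summary
#'
#' Arithmetic mean and sample SD of the fitted asymptote, curvature
#' constant and R-squared per condition x variable. Note that means of
#' parameters rounded for display can differ slightly from displayed
#' rounded means.
#'
#' @param cohort long fitted-parameter table (optionally with
#'   `r_squared`).
#' @return tibble: `condition`, `variable`, `mean_A`, `sd_A`, `mean_tau`,
#'   `sd_tau` (and `mean_r_squared`, `sd_r_squared` when available), `n`.
#' @export
summarize_cohort <- function(cohort) {
  check_fits_schema(cohort)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  sd_or_na <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)
  out <- cohort |>
    dplyr::group_by(.data$condition, .data$variable) |>
    dplyr::summarise(
      mean_A = mean(.data$A_pct), sd_A = sd_or_na(.data$A_pct),
      mean_tau = mean(.data$tau_s), sd_tau = sd_or_na(.data$tau_s),
      n = dplyr::n(), .groups = "drop")
  if ("r_squared" %in% names(cohort)) {
    r2 <- cohort |>
      dplyr::group_by(.data$condition, .data$variable) |>
      dplyr::summarise(mean_r_squared = mean(.data$r_squared),
                       sd_r_squared = sd_or_na(.data$r_squared),
                       .groups = "drop")
    out <- dplyr::left_join(out, r2, by = c("condition", "variable"))
  }
  out
}

#' Normality diagnostics for the paired-comparison battery
#'
#' Shapiro-Wilk tests on the HF-LF paired differences of each parameter.
#' Purely diagnostic: results never gate any computation.
#'
#' @param cohort long fitted-parameter table.
#' @return tibble: `variable`, `parameter`, `shapiro_w`, `shapiro_p`.
#' @export
normality_report <- function(cohort) {
  wide <- cohort_wide(cohort)
  specs <- tidyr::expand_grid(parameter = c("A", "tau"),
                              variable = c("IMVC", "VA", "QTW"))
  purrr::pmap_dfr(specs, function(parameter, variable) {
    d <- wide[[paste(parameter, variable, "HF", sep = "_")]] -
      wide[[paste(parameter, variable, "LF", sep = "_")]]
    s <- stats::shapiro.test(d)
    tibble::tibble(variable = variable, parameter = parameter,
                   shapiro_w = unname(s$statistic), shapiro_p = s$p.value)
  })
}
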