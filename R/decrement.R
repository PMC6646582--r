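#' Invert the fitted torque model: time at a given torque level
#'
#' Solves `IMVC(t) = level` for the fitted exponential torque model, giving
#' the accumulated contraction time at which maximal voluntary torque has
#' fallen to `level` percent of baseline:
#' \deqn{t = -\tau_{IMVC}\,\ln\!\frac{level - A_{IMVC}}{100 - A_{IMVC}}}
#' Levels at or below the asymptote are never reached and raise an error.
#'
#' @param fit_imvc fitted torque model ([exp_fit()] or list with `A`, `tau`).
#' @param imvc_level target torque, percent of baseline, with
#'   `A < imvc_level <= 100`.
#' @return accumulated contraction time in seconds.
#' @examples
#' invert_imvc(exp_fit(64, 31), 80) # ~25.1 s
#' @export
invert_imvc <- function(fit_imvc, imvc_level) {
  f <- as_exp_fit(fit_imvc)
  stopifnot(is.numeric(imvc_level), length(imvc_level) == 1)
  if (imvc_level > 100)
    stop("`imvc_level` cannot exceed 100% of baseline", call. = FALSE)
  if (f$A >= 100)
    stop("A = 100: torque does not decline, inversion undefined",
         call. = FALSE)
  if (imvc_level <= f$A)
    stop(sprintf(
      "level %.6g%% is at or below the asymptote %.6g%% (unreachable)",
      imvc_level, f$A), call. = FALSE)
  -f$tau * log((imvc_level - f$A) / (100 - f$A))
}

#' Voluntary activation or evoked torque at a given torque decline
#'
#' Closed-form re-expression of a dependent variable (voluntary activation
#' or evoked torque) as a function of the torque level instead of time,
#' obtained by substituting the inverted torque model into the variable's
#' own exponential model:
#' \deqn{DV = A_{DV} + (100 - A_{DV})
#'   \left(\frac{IMVC - A_{IMVC}}{100 - A_{IMVC}}\right)^{\tau_{IMVC}/\tau_{DV}}}
#' By construction this equals `predict(fit_dv, invert_imvc(fit_imvc,
#' level))` exactly.
#'
#' @param fit_dv fitted model of the dependent variable (VA or Q_tw).
#' @param fit_imvc fitted torque model of the same subject and condition.
#' @param imvc_level torque level in percent of baseline,
#'   `A_IMVC < imvc_level <= 100`.
#' @return the dependent variable at that torque level, percent of baseline.
#' @examples
#' dv_at_imvc(exp_fit(69, 95), exp_fit(64, 31), 80) # ~92.8
#' @export
dv_at_imvc <- function(fit_dv, fit_imvc, imvc_level) {
  fd <- as_exp_fit(fit_dv)
  fi <- as_exp_fit(fit_imvc)
  stopifnot(is.numeric(imvc_level), length(imvc_level) == 1)
  if (imvc_level > 100)
    stop("`imvc_level` cannot exceed 100% of baseline", call. = FALSE)
  if (imvc_level == 100) return(100)  # ratio term equals 1 exactly
  if (fi$A >= 100)
    stop("A_IMVC = 100: torque does not decline", call. = FALSE)
  if (imvc_level <= fi$A)
    stop(sprintf(
      "level %.6g%% is at or below the torque asymptote %.6g%% (unreachable)",
      imvc_level, fi$A), call. = FALSE)
  ratio <- (imvc_level - fi$A) / (100 - fi$A)
  if (fd$A >= 100 || fd$degenerate) return(100)
  fd$A + (100 - fd$A) * ratio^(fi$tau / fd$tau)
}

#' Estimate VA and evoked torque at stated torque decrements, per subject
#'
#' For each subject and condition, evaluates the fitted voluntary-activation
#' and evoked-torque models at torque levels corresponding to 10, 20 and
#' 30% declines of maximal voluntary torque (i.e. IMVC at 90, 80 and 70% of
#' baseline). Subjects whose fitted torque asymptote lies at or above the
#' target level can never reach that decrement; they are flagged
#' unreachable, excluded from cohort means, and counted in a message.
#'
#' @param fits long fitted-parameter table (columns `subject_id`,
#'   `condition`, `variable`, `A_pct`, `tau_s`), containing IMVC fits and
#'   at least one of VA / QTW per subject x condition.
#' @param levels torque decrements in percent points of the normalized
#'   scale; default `c(10, 20, 30)`.
#' @return tibble with columns `subject_id`, `condition`, `variable`,
#'   `imvc_decrease`, `dv_value`, `reachable`; `dv_value` is `NA` where
#'   unreachable.
#' @seealso [decrement_means()] for the per-level cohort means.
#' @export
estimate_decrements <- function(fits, levels = c(10, 20, 30)) {
  check_fits_schema(fits)
  stopifnot(is.numeric(levels), all(levels > 0 & levels < 100))
  imvc <- dplyr::filter(fits, .data$variable == "IMVC") |>
    dplyr::select("subject_id", "condition",
                  A_imvc = "A_pct", tau_imvc = "tau_s")
  dv <- dplyr::filter(fits, .data$variable %in% c("VA", "QTW"))
  if (nrow(imvc) == 0 || nrow(dv) == 0)
    stop("`fits` must contain IMVC fits and VA/QTW fits", call. = FALSE)

  grid <- tidyr::expand_grid(dv, imvc_decrease = levels) |>
    dplyr::inner_join(imvc, by = c("subject_id", "condition"))
  est <- grid |>
    dplyr::mutate(
      level = 100 - .data$imvc_decrease,
      reachable = .data$level > .data$A_imvc,
      dv_value = purrr::pmap_dbl(
        list(.data$A_pct, .data$tau_s, .data$A_imvc, .data$tau_imvc,
             .data$level, .data$reachable),
        function(a, tau, ai, taui, lev, ok) {
          if (!ok) return(NA_real_)
          dv_at_imvc(exp_fit(a, tau), exp_fit(ai, taui), lev)
        })) |>
    dplyr::select("subject_id", "condition", "variable",
                  "imvc_decrease", "dv_value", "reachable")
  n_bad <- sum(!est$reachable)
  if (n_bad > 0)
    message(sprintf(
      "%d decrement estimate(s) unreachable (target below fitted asymptote); excluded from means",
      n_bad))
  est
}

#' Cohort means of decrement estimates
#'
#' Means over reachable subjects per condition x variable x decrement.
#'
#' @param estimates output of [estimate_decrements()].
#' @return tibble with `condition`, `variable`, `imvc_decrease`,
#'   `mean_dv`, `sd_dv`, `n`.
#' @export
decrement_means <- function(estimates) {
  stopifnot(all(c("condition", "variable", "imvc_decrease",
                  "dv_value", "reachable") %in% names(estimates)))
  estimates |>
    dplyr::filter(.data$reachable) |>
    dplyr::group_by(.data$condition, .data$variable, .data$imvc_decrease) |>
    dplyr::summarise(mean_dv = mean(.data$dv_value),
                     sd_dv = stats::sd(.data$dv_value),
                     n = dplyr::n(), .groups = "drop")
}
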