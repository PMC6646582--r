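#' Exponential fatigue model
#'
#' Evaluates the two-parameter exponential decline of a neuromuscular
#' variable (maximal voluntary torque, voluntary activation or evoked
#' torque, each expressed in percent of its pre-fatigue baseline) as a
#' function of accumulated contraction time:
#' \deqn{DV(t) = A + (100 - A)\,e^{-t/\tau}}
#' where `A` is the asymptote (the stable state the variable converges to,
#' in percent of baseline) and `tau` the curvature constant in seconds.
#' The model passes through 100 at `t = 0` by construction.
#'
#' @param t accumulated contraction time in seconds (vectorised).
#' @param A asymptote, percent of baseline, in \[0, 100\].
#' @param tau curvature constant in seconds, strictly positive.
#' @return predicted value(s), percent of baseline.
#' @examples
#' fatigue_model(20, A = 64, tau = 31) # 82.9
#' @export
fatigue_model <- function(t, A, tau) {
  stopifnot(is.numeric(t), is.numeric(A), is.numeric(tau))
  if (any(A < 0 | A > 100)) stop("`A` must lie in [0, 100]", call. = FALSE)
  if (any(tau <= 0)) stop("`tau` must be > 0", call. = FALSE)
  A + (100 - A) * exp(-t / tau)
}

#' Construct an exponential-fit object
#'
#' Light constructor for an `exp_fit`, used both by [fit_exponential()] and
#' to build model objects from tabulated parameters (e.g. a published
#' parameter table) for downstream prediction and decrement estimation.
#'
#' @param A asymptote in percent of baseline, \[0, 100\].
#' @param tau curvature constant in seconds (> 0), or `NA` for the
#'   degenerate no-fatigue case `A = 100`.
#' @param r_squared,p_value,n_points,residual_sse optional goodness-of-fit
#'   metadata.
#' @param converged,degenerate,boundary logical flags.
#' @return an object of class `exp_fit`.
#' @export
exp_fit <- function(A, tau, r_squared = NA_real_, p_value = NA_real_,
                    n_points = NA_integer_, residual_sse = NA_real_,
                    converged = TRUE, degenerate = FALSE, boundary = FALSE) {
  stopifnot(length(A) == 1, length(tau) == 1)
  if (!is.finite(A) || A < 0 || A > 100)
    stop("asymptote `A` must lie in [0, 100]", call. = FALSE)
  if (!is.na(tau) && tau <= 0)
    stop("curvature constant `tau` must be > 0", call. = FALSE)
  structure(
    list(A = as.numeric(A), tau = as.numeric(tau),
         r_squared = r_squared, p_value = p_value,
         n_points = n_points, residual_sse = residual_sse,
         converged = isTRUE(converged), degenerate = isTRUE(degenerate),
         boundary = isTRUE(boundary)),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit> A =", format(x$A, digits = 4),
      "% | tau =", format(x$tau, digits = 4), "s\n")
  if (!is.na(x$r_squared))
    cat("  R^2 =", format(x$r_squared, digits = 3),
        " p =", format.pval(x$p_value, digits = 3),
        " n =", x$n_points, "\n")
  if (x$degenerate) cat("  [degenerate: no measurable decline]\n")
  if (x$boundary)   cat("  [asymptote at parameter boundary]\n")
  invisible(x)
}

# Coerce exp_fit / list / named numeric to (A, tau); internal.
as_exp_fit <- function(x) {
  if (inherits(x, "exp_fit")) return(x)
  if (is.list(x) || (is.numeric(x) && !is.null(names(x)))) {
    A <- x[["A"]]
    tau <- if (!is.null(x[["tau"]])) x[["tau"]] else x[["tau_s"]]
    if (is.null(A)) A <- x[["A_pct"]]
    if (!is.null(A) && !is.null(tau)) return(exp_fit(A, tau))
  }
  stop("cannot interpret `fit`: supply an exp_fit or a list with A and tau",
       call. = FALSE)
}

# Sum of squared errors of the model on (t, y); internal.
exp_sse <- function(par, t, y) {
  sum((y - (par[1] + (100 - par[1]) * exp(-t / par[2])))^2)
}

#' Fit the exponential fatigue model to one time course
#'
#' Estimates the asymptote `A` and curvature constant `tau` by bounded
#' nonlinear least squares (Levenberg-Marquardt, multi-start) on a single
#' subject x condition x variable series in percent of baseline. The sum of
#' squared errors between observations and
#' `A + (100 - A) exp(-t / tau)` is minimised over `A` in \[0, 100\] and
#' `tau` in (0, `tau_max`\].
#'
#' Starting values follow a deterministic protocol: `A0 = min(values)`
#' (clamped to the bounds) and `tau0` the first time at which the series
#' drops below `A0 + (100 - A0)/e` (the model's value at `t = tau`), else
#' the median positive time; five starts jitter `(A0, tau0)` by up to
#' +/-50%. Goodness of fit is reported as `r_squared = 1 - SSE/SST` (SST
#' about the series mean) and a p-value from the F-test of the fitted model
#' against the constant-mean model on (1, n - 2) degrees of freedom.
#'
#' A series that is constant at 100 carries no information about `tau`; the
#' fit is then pinned at `A = 100`, flagged `degenerate`, and `tau` is `NA`.
#' Asymptote estimates on the \[0, 100\] boundary are flagged `boundary`
#' but not rejected.
#'
#' @param times accumulated contraction times in seconds, strictly
#'   increasing and starting at 0; or a data frame with columns
#'   `time_s` and `value_pct`.
#' @param values observed percent-of-baseline values (omit when `times` is
#'   a data frame).
#' @param include_t0 include the structural `t = 0` point (exactly 100) in
#'   the least squares; it constrains nothing (the model passes through it)
#'   but stabilises the total sum of squares. Default `TRUE`.
#' @param tau_max upper bound for `tau`, seconds.
#' @param n_starts number of multi-start initialisations.
#' @return an [exp_fit()] object.
#' @examples
#' t <- seq(0, 160, by = 20)
#' fit_exponential(t, fatigue_model(t, A = 64, tau = 31))
#' @export
fit_exponential <- function(times, values = NULL, include_t0 = TRUE,
                            tau_max = 1e4, n_starts = 5) {
  if (is.data.frame(times)) {
    df <- times
    if (!all(c("time_s", "value_pct") %in% names(df)))
      stop("data-frame input needs columns `time_s` and `value_pct`",
           call. = FALSE)
    values <- df$value_pct
    times <- df$time_s
  }
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (anyNA(times) || anyNA(values) || any(!is.finite(values)))
    stop("times and values must be finite", call. = FALSE)
  if (times[1] != 0) stop("series must start at t = 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(times) < 4)
    stop("at least 4 points are required to fit the model", call. = FALSE)

  if (!include_t0) {
    keep <- times > 0
    times <- times[keep]
    values <- values[keep]
    if (length(times) < 4)
      stop("at least 4 points are required to fit the model", call. = FALSE)
  }
  n <- length(values)

  # Degenerate: no decline at all -> A pinned at the 100 boundary.
  if (all(abs(values - 100) < 1e-9)) {
    return(exp_fit(100, NA_real_, r_squared = NA_real_, p_value = NA_real_,
                   n_points = n, residual_sse = 0, converged = FALSE,
                   degenerate = TRUE, boundary = TRUE))
  }

  A0 <- min(max(min(values), 0), 100)
  thr <- A0 + (100 - A0) * exp(-1)
  below <- which(values < thr & times > 0)
  tau0 <- if (length(below)) times[below[1]] else stats::median(times[times > 0])
  tau0 <- min(max(tau0, 1e-3), tau_max)

  # Deterministic +/-50% jitter grid around (A0, tau0).
  fA <- c(1, 0.9, 1.1, 0.75, 1.25)[seq_len(n_starts)]
  ft <- c(1, 0.5, 1.5, 0.75, 1.25)[seq_len(n_starts)]
  starts <- Map(function(a, b) c(A = min(max(A0 * a, 0), 100),
                                 tau = min(max(tau0 * b, 1e-3), tau_max)),
                fA, ft)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        values ~ A + (100 - A) * exp(-times / tau),
        start = list(A = s[["A"]], tau = s[["tau"]]),
        lower = c(A = 0, tau = 1e-6), upper = c(A = 100, tau = tau_max),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = stats::coef(fit), sse = sse)
  }
  converged <- !is.null(best)
  if (!converged) {
    # fall back to box-constrained quasi-Newton on the SSE surface
    for (s in starts) {
      o <- tryCatch(
        stats::optim(s, exp_sse, t = times, y = values, method = "L-BFGS-B",
                     lower = c(0, 1e-6), upper = c(100, tau_max)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$sse))
        best <- list(par = o$par, sse = o$value)
    }
    if (is.null(best))
      return(exp_fit(A0, tau0, n_points = n, converged = FALSE))
  }

  A_hat <- unname(best$par[1]); tau_hat <- unname(best$par[2])
  sse <- best$sse
  sst <- sum((values - mean(values))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - sse / sst)) else NA_real_
  p <- if (sse <= .Machine$double.eps * sst) 0 else {
    fstat <- ((sst - sse) / 1) / (sse / (n - 2))
    stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  }
  exp_fit(A_hat, tau_hat, r_squared = r2, p_value = p, n_points = n,
          residual_sse = sse, converged = converged,
          boundary = A_hat < 1e-6 || A_hat > 100 - 1e-6)
}

#' Predict from a fitted exponential fatigue model
#'
#' @param object an [exp_fit()].
#' @param t accumulated contraction time(s) in seconds, `t >= 0`.
#' @param ... unused.
#' @return predicted percent-of-baseline value(s).
#' @export
predict.exp_fit <- function(object, t, ...) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (object$A >= 100 || object$degenerate) return(rep(100, length(t)))
  fatigue_model(t, object$A, object$tau)
}

#' Time to complete a fraction of the total decline
#'
#' Under the exponential model the fraction of the total drop `100 - A`
#' completed by time `t` is `1 - exp(-t/tau)`, independent of `A`. The time
#' at which a given fraction is reached is therefore
#' `tau * log(1 / (1 - fraction))`; 95% of the loss is completed by about
#' `3 tau` (`log 20 = 2.996`).
#'
#' @param fit an [exp_fit()] (or a single numeric `tau` in seconds).
#' @param fraction fraction of the total decline in (0, 1).
#' @return time in seconds of accumulated contraction.
#' @examples
#' time_to_fraction(exp_fit(64, 31), 0.95) # ~92.9 s
#' @export
time_to_fraction <- function(fit, fraction) {
  stopifnot(is.numeric(fraction), length(fraction) >= 1)
  if (any(fraction <= 0 | fraction >= 1))
    stop("`fraction` must lie strictly in (0, 1)", call. = FALSE)
  if (is.numeric(fit) && length(fit) == 1) {
    tau <- fit
    if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  } else {
    f <- as_exp_fit(fit)
    if (f$A >= 100)
      stop("A = 100: the series does not decline, no loss time is defined",
           call. = FALSE)
    tau <- f$tau
  }
  tau * log(1 / (1 - fraction))
}

#' Fit the fatigue model to every series in a cohort
#'
#' Maps [fit_exponential()] over every subject x condition x variable
#' series of a long-format observation table.
#'
#' @param series tibble with columns `subject_id`, `condition`, `variable`,
#'   `time_s`, `value_pct` (the long interchange format).
#' @param ... passed to [fit_exponential()].
#' @return tibble with one row per series: `subject_id`, `condition`,
#'   `variable`, `A_pct`, `tau_s`, `r_squared`, `p_value`, `n_points`,
#'   `converged`.
#' @export
fit_cohort <- function(series, ...) {
  check_series_schema(series)
  series |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$variable) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_exponential(df$time_s, df$value_pct, ...)
      tibble::tibble(A_pct = f$A, tau_s = f$tau, r_squared = f$r_squared,
                     p_value = f$p_value, n_points = f$n_points,
                     converged = f$converged)
    }) |>
    dplyr::ungroup()
}
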