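#' @title Neuromuscular metrics from raw torque traces
#' @description Feature extraction for one neuromuscular test: an isometric
#'   maximal voluntary contraction with a superimposed high-frequency
#'   doublet delivered at the torque peak, followed by a doublet on the
#'   relaxed, potentiated muscle. The trace is a uniformly sampled torque
#'   signal (typically 2 kHz) with optional stimulus-onset markers.
#' @name nm-extraction
NULL

# Validate the trace tibble: uniform time grid, finite torque. Internal.
check_trace <- function(trace) {
  if (!is.data.frame(trace) ||
      !all(c("time_s", "torque_nm") %in% names(trace)))
    stop("a trace needs columns `time_s` and `torque_nm`", call. = FALSE)
  tt <- trace$time_s
  if (length(tt) < 3 || any(diff(tt) <= 0))
    stop("trace times must be strictly increasing", call. = FALSE)
  dt <- diff(tt)
  if ((max(dt) - min(dt)) > 1e-6 * stats::median(dt))
    stop("trace must be uniformly sampled (within 1 ppm)", call. = FALSE)
  if (any(!is.finite(trace$torque_nm)))
    stop("torque values must be finite", call. = FALSE)
  invisible(trace)
}

trace_dt <- function(trace) stats::median(diff(trace$time_s))

# Pull the raw trace tibble out of an nm_trace or pass a tibble through.
as_trace <- function(x) {
  if (inherits(x, "nm_trace")) x$trace else x
}

#' Locate stimulus times in a trace
#'
#' Returns the stimulus-onset times of a neuromuscular test. When the trace
#' carries hardware markers (`stim` column with ones at onset samples) they
#' are passed through. Without markers, the two largest positive
#' torque-derivative transients separated by at least `min_separation`
#' seconds are returned, in time order — the twitch onsets are by far the
#' steepest rises in a well-formed test trace.
#'
#' @param trace trace tibble (`time_s`, `torque_nm`, optional `stim`) or an
#'   `nm_trace`.
#' @param min_separation minimum separation between the two detected
#'   transients, seconds.
#' @return numeric vector of stimulus times, increasing.
#' @export
detect_stimulus_times <- function(trace, min_separation = 1) {
  trace <- as_trace(trace)
  check_trace(trace)
  if ("stim" %in% names(trace) && any(trace$stim > 0))
    return(trace$time_s[trace$stim > 0])
  # a stimulus onset is an abrupt upward break in the torque derivative:
  # the jerk (second difference) spikes there, while the voluntary rise,
  # however steep, is smooth and contributes little
  y <- trace$torque_nm
  jerk <- diff(y, differences = 2)
  thr <- 20 * stats::quantile(abs(jerk), 0.95, names = FALSE) + 1e-12
  cand <- which(jerk > thr)
  if (!length(cand)) stop("stimuli not found", call. = FALSE)
  # onset = sample before the derivative break
  t_cand <- trace$time_s[cand + 1L]
  ord <- order(jerk[cand], decreasing = TRUE)
  first <- ord[1]
  rest <- ord[abs(t_cand[ord] - t_cand[first]) >= min_separation]
  if (!length(rest)) stop("stimuli not found", call. = FALSE)
  sort(c(t_cand[first], t_cand[rest[1]]))
}

#' Mean voluntary torque plateau before the superimposed stimulus
#'
#' The maximal-contraction plateau is quantified as the mean torque over a
#' 500-ms window ending at (and excluding) the superimposed-stimulus
#' sample.
#'
#' @param trace trace tibble or `nm_trace`.
#' @param t_stim_super superimposed-stimulus time, seconds.
#' @param window window length in seconds (default 0.5).
#' @return plateau torque in N·m.
#' @export
compute_imvc_plateau <- function(trace, t_stim_super, window = 0.5) {
  trace <- as_trace(trace)
  check_trace(trace)
  stopifnot(is.numeric(t_stim_super), length(t_stim_super) == 1)
  t0 <- t_stim_super - window
  if (t0 < trace$time_s[1] - 1e-12)
    stop("plateau window extends before the start of the trace",
         call. = FALSE)
  sel <- trace$time_s >= t0 & trace$time_s < t_stim_super
  if (!any(sel)) stop("plateau window contains no samples", call. = FALSE)
  mean(trace$torque_nm[sel])
}

#' Superimposed twitch and surrounding torque landmarks
#'
#' From the voluntary-contraction phase: `T_max`, the maximal torque
#' produced before the stimulation (searched over the current contraction
#' only, from the last crossing below 10% of the stimulation-time torque);
#' `T_stim`, the torque at the moment of stimulation; and `ST`, the
#' superimposed twitch — the difference between the maximal torque attained
#' within `window` seconds after the stimulation and `T_stim`, clamped at
#' zero (with a warning) when relaxation has already begun.
#'
#' @param trace trace tibble or `nm_trace`.
#' @param t_stim_super stimulation time, seconds.
#' @param window post-stimulus search window, seconds (default 0.3, long
#'   enough for a 100-Hz doublet twitch to peak).
#' @return named list with `T_max`, `T_stim`, `ST` (N·m) and `st_raw`, the
#'   unclamped increment retained for audit.
#' @export
extract_superimposed_twitch <- function(trace, t_stim_super, window = 0.3) {
  trace <- as_trace(trace)
  check_trace(trace)
  tt <- trace$time_s; y <- trace$torque_nm
  if (t_stim_super + window > tt[length(tt)] + 1e-12)
    stop("post-stimulus window truncated by the end of the trace",
         call. = FALSE)
  i_stim <- which(tt >= t_stim_super)[1]
  if (is.na(i_stim) || i_stim < 2)
    stop("stimulation time outside the voluntary contraction", call. = FALSE)
  T_stim <- y[i_stim]
  # current contraction: back to the last sample below 10% of T_stim
  pre <- y[seq_len(i_stim - 1)]
  low <- which(pre < 0.1 * T_stim)
  from <- if (length(low)) max(low) + 1L else 1L
  T_max <- max(pre[from:(i_stim - 1)])
  T_max <- max(T_max, T_stim)
  # the onset sample itself is pre-response (the twitch is zero at onset),
  # so the search window opens just after it; a trace already in
  # relaxation then yields a negative raw increment, which is clamped
  post <- y[tt > t_stim_super & tt <= t_stim_super + window]
  st_raw <- max(post) - T_stim
  if (st_raw < 0)
    warning("post-stimulus torque never exceeded T_stim; ST clamped to 0",
            call. = FALSE)
  list(T_max = T_max, T_stim = T_stim, ST = max(st_raw, 0), st_raw = st_raw)
}

#' Potentiated resting twitch amplitude
#'
#' Evoked torque of the relaxed, potentiated muscle: the maximal torque
#' response within `window` seconds of the resting doublet, measured above
#' the pre-stimulus baseline (mean over the 100 ms preceding the stimulus,
#' since dynamometer zero offsets drift).
#'
#' @param trace trace tibble or `nm_trace`.
#' @param t_stim_rest resting-stimulus time, seconds.
#' @param window post-stimulus search window, seconds (default 0.5).
#' @param baseline_window pre-stimulus baseline window, seconds.
#' @param rest_threshold fraction of `plateau` below which the muscle is
#'   considered relaxed.
#' @param plateau reference plateau torque for the rest check (N·m);
#'   defaults to the trace maximum.
#' @return twitch amplitude `Q_tw` in N·m.
#' @export
extract_resting_twitch <- function(trace, t_stim_rest, window = 0.5,
                                   baseline_window = 0.1,
                                   rest_threshold = 0.1, plateau = NULL) {
  trace <- as_trace(trace)
  check_trace(trace)
  tt <- trace$time_s; y <- trace$torque_nm
  if (is.null(plateau)) plateau <- max(y)
  i_stim <- which(tt >= t_stim_rest)[1]
  if (is.na(i_stim)) stop("resting stimulus beyond trace end", call. = FALSE)
  if (y[i_stim] > rest_threshold * plateau)
    stop("not at rest: torque exceeds the relaxation threshold at the resting stimulus",
         call. = FALSE)
  base_sel <- tt >= t_stim_rest - baseline_window & tt < t_stim_rest
  baseline <- if (any(base_sel)) mean(y[base_sel]) else y[i_stim]
  post <- y[tt >= t_stim_rest & tt <= t_stim_rest + window]
  if (t_stim_rest + window > tt[length(tt)] + 1e-12)
    stop("post-stimulus window truncated by the end of the trace",
         call. = FALSE)
  max(post) - baseline
}

#' Voluntary activation by corrected twitch interpolation
#'
#' \deqn{VA = \left[1 - \frac{ST \times (T_{stim}/T_{max})}{Q_{tw}}\right]
#'   \times 100}
#' The superimposed twitch is weighted by `T_stim / T_max` to correct for
#' stimuli delivered slightly off the true torque peak. The result is
#' clamped to \[0, 100\] with a warning (measurement noise can push the raw
#' ratio outside the physical range).
#'
#' @param ST superimposed twitch, N·m (>= 0).
#' @param T_stim torque at the stimulation, N·m.
#' @param T_max maximal torque before the stimulation, N·m.
#' @param Q_tw potentiated resting twitch, N·m (> 0).
#' @return voluntary activation in percent.
#' @examples
#' compute_voluntary_activation(ST = 10, T_stim = 200, T_max = 250,
#'                              Q_tw = 100) # 92
#' @export
compute_voluntary_activation <- function(ST, T_stim, T_max, Q_tw) {
  stopifnot(is.numeric(ST), is.numeric(T_stim), is.numeric(T_max),
            is.numeric(Q_tw))
  if (Q_tw <= 0) stop("`Q_tw` must be > 0", call. = FALSE)
  if (T_max <= 0) stop("`T_max` must be > 0", call. = FALSE)
  if (T_stim <= 0 || T_stim > T_max + 1e-9)
    stop("need 0 < T_stim <= T_max", call. = FALSE)
  va <- (1 - (ST * (T_stim / T_max)) / Q_tw) * 100
  if (va < 0 || va > 100) {
    warning(sprintf("VA = %.2f%% outside [0, 100]; clamped", va),
            call. = FALSE)
    va <- min(max(va, 0), 100)
  }
  va
}

#' Baseline plateau quality check
#'
#' A pre-fatigue neuromuscular test is acceptable only if its voluntary
#' plateau reaches at least 95% of the control maximal contraction recorded
#' at the end of the warm-up.
#'
#' @param plateau measured plateau torque, N·m.
#' @param control_imvc control maximal torque, N·m (> 0).
#' @param threshold acceptance ratio, default 0.95.
#' @return one-row tibble: `plateau`, `control_imvc`, `ratio`, `pass`.
#' @export
check_baseline <- function(plateau, control_imvc, threshold = 0.95) {
  if (!is.numeric(control_imvc) || control_imvc <= 0)
    stop("`control_imvc` must be > 0", call. = FALSE)
  ratio <- plateau / control_imvc
  tibble::tibble(plateau = plateau, control_imvc = control_imvc,
                 ratio = ratio,
                 pass = ratio >= threshold - sqrt(.Machine$double.eps))
}

#' Express raw values as percent of a baseline
#'
#' @param raw_values numeric vector in measurement units.
#' @param baseline_value baseline in the same units (> 0).
#' @return values in percent of baseline; the baseline itself maps to
#'   exactly 100.
#' @export
normalize_to_baseline <- function(raw_values, baseline_value) {
  stopifnot(is.numeric(raw_values), is.numeric(baseline_value),
            length(baseline_value) == 1)
  if (baseline_value <= 0) stop("`baseline_value` must be > 0", call. = FALSE)
  raw_values * 100 / baseline_value
}

#' Full neuromuscular metric extraction for one test trace
#'
#' Runs the whole extraction chain: stimulus localisation, plateau, torque
#' landmarks and superimposed twitch, resting twitch, and voluntary
#' activation.
#'
#' @param trace trace tibble (`time_s`, `torque_nm`, optional `stim`) or an
#'   `nm_trace` from [generate_nm_trace()].
#' @param stim_times optional length-2 stimulus times overriding detection.
#' @param st_window,qtw_window post-stimulus search windows, seconds.
#' @return one-row tibble: `t_stim_super`, `t_stim_rest`, `T_max`,
#'   `T_stim`, `ST`, `st_raw`, `Q_tw`, `plateau`, `VA`, `va_raw`,
#'   `va_clamped`.
#' @export
extract_nm_metrics <- function(trace, stim_times = NULL,
                               st_window = 0.3, qtw_window = 0.5) {
  trace <- as_trace(trace)
  check_trace(trace)
  if (is.null(stim_times)) stim_times <- detect_stimulus_times(trace)
  if (length(stim_times) != 2)
    stop("expected exactly 2 stimulus times (superimposed, resting)",
         call. = FALSE)
  stim_times <- sort(stim_times)
  t_sup <- stim_times[1]; t_rest <- stim_times[2]
  plateau <- compute_imvc_plateau(trace, t_sup)
  st <- extract_superimposed_twitch(trace, t_sup, window = st_window)
  qtw <- extract_resting_twitch(trace, t_rest, window = qtw_window,
                                plateau = plateau)
  va_raw <- (1 - (st$ST * (st$T_stim / st$T_max)) / qtw) * 100
  va <- withCallingHandlers(
    compute_voluntary_activation(st$ST, st$T_stim, st$T_max, qtw),
    warning = function(w) invokeRestart("muffleWarning"))
  tibble::tibble(
    t_stim_super = t_sup, t_stim_rest = t_rest,
    T_max = st$T_max, T_stim = st$T_stim, ST = st$ST, st_raw = st$st_raw,
    Q_tw = qtw, plateau = plateau, VA = va, va_raw = va_raw,
    va_clamped = !isTRUE(all.equal(va, va_raw)))
}
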