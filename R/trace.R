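#' Configure a synthetic neuromuscular-test torque trace
#'
#' Describes one simulated isometric test: a maximal voluntary contraction
#' rising to a plateau, a superimposed doublet twitch delivered on the
#' plateau, voluntary relaxation, and a potentiated resting doublet on the
#' relaxed muscle. Twitch transients use the single-peak shape
#' `amp * (t/Tc) * exp(1 - t/Tc)`, which is zero at onset and peaks with
#' value `amp` exactly at the contraction time `Tc`.
#'
#' @param sampling_rate sampling rate in Hz (default 2000).
#' @param plateau_torque voluntary plateau torque, N·m.
#' @param rise_time time to reach the plateau from rest, seconds.
#' @param twitch_amplitude superimposed-twitch amplitude, N·m.
#' @param twitch_contraction_time time-to-peak of the doublet twitch,
#'   seconds (default 0.07, typical of a 100-Hz doublet).
#' @param resting_twitch_amplitude potentiated resting-twitch amplitude,
#'   N·m.
#' @param stim_times length-2 vector: superimposed and resting stimulus
#'   times, seconds.
#' @param relax_after voluntary effort continues this long after the
#'   superimposed stimulus before relaxation begins, seconds.
#' @param relax_tau exponential relaxation time constant, seconds.
#' @param baseline_noise_sd additive Gaussian noise SD on the torque
#'   signal, N·m.
#' @param duration trace length, seconds; default covers the resting
#'   twitch plus 1 s.
#' @param seed integer seed for the noise.
#' @return object of class `trace_config`.
#' @export
trace_config <- function(sampling_rate = 2000, plateau_torque = 250,
                         rise_time = 1, twitch_amplitude = 10,
                         twitch_contraction_time = 0.07,
                         resting_twitch_amplitude = 96,
                         stim_times = c(2.5, 4.5),
                         relax_after = 0.8, relax_tau = 0.15,
                         baseline_noise_sd = 0, duration = NULL,
                         seed = 1L) {
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0", call. = FALSE)
  if (twitch_contraction_time <= 0)
    stop("`twitch_contraction_time` must be > 0", call. = FALSE)
  if (plateau_torque <= 0) stop("`plateau_torque` must be > 0", call. = FALSE)
  if (twitch_amplitude < 0 || resting_twitch_amplitude <= 0)
    stop("twitch amplitudes must be non-negative (resting > 0)", call. = FALSE)
  if (baseline_noise_sd < 0)
    stop("`baseline_noise_sd` must be >= 0", call. = FALSE)
  if (length(stim_times) != 2 || diff(stim_times) <= 0)
    stop("`stim_times` must be two increasing times", call. = FALSE)
  if (stim_times[1] < rise_time + 0.5)
    stop("superimposed stimulus must come at least 0.5 s after the plateau is reached",
         call. = FALSE)
  t_relax <- stim_times[1] + relax_after
  if (stim_times[2] <= t_relax)
    stop("stimuli overlap: resting stimulus falls within the voluntary contraction",
         call. = FALSE)
  # muscle must be relaxed (< 10% of plateau) when the resting doublet fires
  residual <- exp(-(stim_times[2] - t_relax) / relax_tau)
  if (residual >= 0.1)
    stop("overlapping transients: voluntary torque has not relaxed below 10% of the plateau at the resting stimulus",
         call. = FALSE)
  if (is.null(duration)) duration <- stim_times[2] + 1
  if (duration <= stim_times[2] + 0.5)
    stop("`duration` must extend at least 0.5 s past the resting stimulus",
         call. = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 plateau_torque = plateau_torque, rise_time = rise_time,
                 twitch_amplitude = twitch_amplitude,
                 twitch_contraction_time = twitch_contraction_time,
                 resting_twitch_amplitude = resting_twitch_amplitude,
                 stim_times = stim_times, relax_after = relax_after,
                 relax_tau = relax_tau,
                 baseline_noise_sd = baseline_noise_sd,
                 duration = duration, seed = as.integer(seed)),
            class = "trace_config")
}

# Single-peak twitch transient; zero before onset, peak = amp at t = Tc.
twitch_shape <- function(t, amp, Tc) {
  ifelse(t >= 0, amp * (t / Tc) * exp(1 - t / Tc), 0)
}

#' Generate a synthetic neuromuscular-test torque trace
#'
#' Builds the sampled torque signal described by a [trace_config()],
#' together with the exact ground-truth metrics used in its construction
#' (`T_max`, `T_stim`, `ST`, `Q_tw`, plateau, and the voluntary activation
#' they imply). The voluntary component rises smoothly (quarter-sine) to
#' the plateau, holds through the superimposed twitch, then relaxes
#' exponentially; both stimuli add the twitch transient on top.
#'
#' @param config a [trace_config()].
#' @return object of class `nm_trace`: list with `trace` (tibble `time_s`,
#'   `torque_nm`, `stim`), `truth` (one-row tibble of ground-truth
#'   metrics) and `config`.
#' @export
generate_nm_trace <- function(config) {
  stopifnot(inherits(config, "trace_config"))
  cf <- config
  dt <- 1 / cf$sampling_rate
  tt <- seq(0, cf$duration, by = dt)
  t1 <- cf$stim_times[1]; t2 <- cf$stim_times[2]
  t_relax <- t1 + cf$relax_after

  voluntary <- ifelse(
    tt < cf$rise_time,
    cf$plateau_torque * sin(pi / 2 * tt / cf$rise_time),
    ifelse(tt <= t_relax, cf$plateau_torque,
           cf$plateau_torque * exp(-(tt - t_relax) / cf$relax_tau)))
  torque <- voluntary +
    twitch_shape(tt - t1, cf$twitch_amplitude, cf$twitch_contraction_time) +
    twitch_shape(tt - t2, cf$resting_twitch_amplitude,
                 cf$twitch_contraction_time)
  if (cf$baseline_noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(cf$seed)
    torque <- torque + stats::rnorm(length(tt), 0, cf$baseline_noise_sd)
  }
  stim <- integer(length(tt))
  stim[vapply(c(t1, t2), function(s) which(tt >= s - 1e-12)[1], 1L)] <- 1L

  va <- (1 - (cf$twitch_amplitude *
                (cf$plateau_torque / cf$plateau_torque)) /
           cf$resting_twitch_amplitude) * 100
  truth <- tibble::tibble(
    t_stim_super = t1, t_stim_rest = t2,
    T_max = cf$plateau_torque, T_stim = cf$plateau_torque,
    ST = cf$twitch_amplitude, Q_tw = cf$resting_twitch_amplitude,
    plateau = cf$plateau_torque, VA = va)
  structure(list(
    trace = tibble::tibble(time_s = tt, torque_nm = torque, stim = stim),
    truth = truth, config = cf), class = "nm_trace")
}

#' @export
print.nm_trace <- function(x, ...) {
  cat("<nm_trace>", nrow(x$trace), "samples @",
      x$config$sampling_rate, "Hz |",
      "plateau", x$config$plateau_torque, "N·m | ground-truth VA",
      sprintf("%.1f%%", x$truth$VA), "\n")
  invisible(x)
}
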