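flat_trace <- function(level = 250, duration = 6, fs = 2000) {
  tt <- seq(0, duration, by = 1 / fs)
  tibble::tibble(time_s = tt, torque_nm = rep(level, length(tt)),
                 stim = integer(length(tt)))
}

test_that("stimulus detection passes markers through and falls back to derivatives", {
  tr <- flat_trace()
  tr$stim[c(which.min(abs(tr$time_s - 2.5)),
            which.min(abs(tr$time_s - 4.5)))] <- 1L
  expect_equal(detect_stimulus_times(tr), c(2.5, 4.5))

  # marker-free: inject twitch-like transients at known onsets
  tr2 <- generate_nm_trace(trace_config())
  trace <- tr2$trace
  trace$stim <- 0L
  det <- detect_stimulus_times(trace)
  dt <- 1 / tr2$config$sampling_rate
  expect_equal(length(det), 2)
  expect_lt(abs(det[1] - 2.5), 2 * dt + 1e-12)
  expect_lt(abs(det[2] - 4.5), 2 * dt + 1e-12)

  # nothing to detect on a flat zero trace
  z <- flat_trace(level = 0)
  expect_error(detect_stimulus_times(z), "stimuli not found")
})

test_that("plateau is the 500-ms pre-stimulus mean, end-exclusive", {
  tr <- flat_trace(250)
  expect_equal(compute_imvc_plateau(tr, 2.5), 250)
  expect_equal(compute_imvc_plateau(tr, 4.0), 250) # any valid position

  # linear ramp with slope 20 N·m/s ending at 250 -> window mean is the
  # midpoint value, 245
  fs <- 2000
  tt <- seq(0, 3, by = 1 / fs)
  ramp <- tibble::tibble(time_s = tt, torque_nm = 250 + 20 * (tt - 3))
  got <- compute_imvc_plateau(ramp, 3.0)
  # discrete left-closed window: mean over samples in [2.5, 3.0)
  expect_equal(got, 245, tolerance = 0.01)

  expect_error(compute_imvc_plateau(tr, 0.2), "before the start")
})

test_that("superimposed twitch is measured above T_stim and clamped at zero", {
  tr <- generate_nm_trace(trace_config(plateau_torque = 250,
                                       twitch_amplitude = 10))
  st <- extract_superimposed_twitch(tr$trace, 2.5)
  expect_equal(st$T_max, 250, tolerance = 1e-6)
  expect_equal(st$T_stim, 250, tolerance = 1e-6)
  expect_equal(st$ST, 10, tolerance = 0.05)

  # no bump: fully activated muscle
  flat <- flat_trace(250)
  st0 <- extract_superimposed_twitch(flat, 2.5)
  expect_equal(st0$ST, 0)

  # declining post-stimulus torque: clamp with warning, raw kept for audit
  tt <- seq(0, 4, by = 5e-4)
  dec <- tibble::tibble(time_s = tt,
                        torque_nm = 250 - 40 * pmax(tt - 2.5, 0))
  expect_warning(std <- extract_superimposed_twitch(dec, 2.6), "clamped")
  expect_equal(std$ST, 0)
  expect_lt(std$st_raw, 0)

  expect_error(extract_superimposed_twitch(flat_trace(duration = 2.6), 2.5),
               "truncated")
})

test_that("resting twitch subtracts the pre-stimulus baseline", {
  tr <- generate_nm_trace(trace_config(resting_twitch_amplitude = 96))
  q <- extract_resting_twitch(tr$trace, 4.5, plateau = 250)
  expect_equal(q, 96, tolerance = 0.05)

  # zero-amplitude twitch on a resting muscle
  tt <- seq(0, 6, by = 5e-4)
  rest <- tibble::tibble(time_s = tt, torque_nm = numeric(length(tt)))
  expect_equal(extract_resting_twitch(rest, 4.5, plateau = 250), 0)

  # dynamometer offset drift is removed by the baseline window
  drift <- tr$trace
  drift$torque_nm <- drift$torque_nm + 3.7
  expect_equal(extract_resting_twitch(drift, 4.5, plateau = 250), 96,
               tolerance = 0.05)

  # stimulating during the plateau is rejected
  expect_error(extract_resting_twitch(tr$trace, 2.0, plateau = 250),
               "not at rest")
})

test_that("voluntary activation follows the corrected interpolation formula", {
  expect_equal(compute_voluntary_activation(0, 250, 250, 96), 100)
  expect_equal(compute_voluntary_activation(10, 200, 250, 100), 92.0)
  expect_equal(compute_voluntary_activation(10, 250, 250, 96),
               (1 - 10 / 96) * 100)
  expect_equal(compute_voluntary_activation(10, 250, 250, 96), 89.58,
               tolerance = 1e-3)
  expect_error(compute_voluntary_activation(10, 250, 250, 0), "Q_tw")
  expect_error(compute_voluntary_activation(10, 250, 0, 10), "T_max")
  expect_error(compute_voluntary_activation(10, 260, 250, 96), "T_stim")
  expect_warning(va <- compute_voluntary_activation(120, 250, 250, 96),
                 "clamped")
  expect_equal(va, 0)
})

test_that("VA is invariant to uniform rescaling of the whole trace", {
  for (k in c(0.5, 2, 7.3)) {
    expect_equal(compute_voluntary_activation(10 * k, 200 * k, 250 * k,
                                              100 * k),
                 compute_voluntary_activation(10, 200, 250, 100))
  }
  tr <- generate_nm_trace(trace_config())
  scaled <- tr$trace
  scaled$torque_nm <- scaled$torque_nm * 3
  m1 <- extract_nm_metrics(tr$trace)
  m3 <- extract_nm_metrics(scaled)
  expect_equal(m3$VA, m1$VA, tolerance = 1e-9)
})

test_that("baseline check applies the 95% rule inclusively", {
  expect_true(check_baseline(266, 280)$pass)   # exactly 0.95
  expect_false(check_baseline(250, 280)$pass)  # 0.893
  expect_true(check_baseline(280, 280)$pass)
  expect_error(check_baseline(250, 0), "control_imvc")
})

test_that("normalization maps the baseline to exactly 100", {
  got <- normalize_to_baseline(c(285, 240, 200), 285)
  expect_identical(got[1], 100)
  expect_equal(got, c(100, 84.2, 70.2), tolerance = 0.05)
  expect_error(normalize_to_baseline(c(1, 2), 0), "baseline")
})
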