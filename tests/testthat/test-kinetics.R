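test_that("noiseless series are recovered to numerical precision", {
  tt <- seq(0, 160, by = 20)
  for (p in list(c(64, 31), c(82, 43), c(41, 28), c(95, 120))) {
    fit <- fit_exponential(tt, oracle_model(tt, p[1], p[2]))
    expect_equal(fit$A, p[1], tolerance = 1e-6)
    expect_equal(fit$tau, p[2], tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_true(fit$converged)
  }
})

test_that("refitting a model's own predictions is a fixed point", {
  tt <- seq(0, 160, by = 20)
  f1 <- fit_exponential(tt, oracle_model(tt, 64, 34))
  f2 <- fit_exponential(tt, predict(f1, tt))
  expect_equal(f2$A, f1$A, tolerance = 1e-6)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-6)
})

test_that("prediction follows the model and its limits", {
  fit <- exp_fit(64, 31)
  expect_equal(predict(fit, 20), 64 + 36 * exp(-20 / 31))
  expect_equal(predict(fit, 20), 82.9, tolerance = 1e-3)
  expect_identical(predict(fit, 0), 100)
  expect_equal(predict(fit, 1e6), 64, tolerance = 1e-9)
  expect_error(predict(fit, -1), "non-negative")
  # strictly decreasing when A < 100, constant at A = 100
  tt <- seq(0, 300, by = 10)
  expect_true(all(diff(predict(fit, tt)) < 0))
  expect_true(all(predict(exp_fit(100, 31), tt) == 100))
})

test_that("time_to_fraction inverts the completed-loss fraction", {
  expect_equal(time_to_fraction(exp_fit(64, 31), 0.95), 31 * log(20))
  expect_equal(time_to_fraction(exp_fit(64, 31), 0.95), 92.9,
               tolerance = 1e-3)
  expect_equal(time_to_fraction(50, 0.95), 149.8, tolerance = 1e-3)
  # at fraction 1 - 1/e the answer is tau itself, by definition
  for (tau in c(5, 31, 90)) {
    expect_equal(time_to_fraction(tau, 1 - exp(-1)), tau)
  }
  # completed fraction at t = 3*tau is 1 - e^-3 for every fit
  for (p in list(c(30, 12), c(64, 31), c(90, 140))) {
    fit <- exp_fit(p[1], p[2])
    frac <- (100 - predict(fit, 3 * p[2])) / (100 - p[1])
    expect_equal(frac, 1 - exp(-3), tolerance = 1e-12)
  }
  expect_error(time_to_fraction(exp_fit(64, 31), 1), "fraction")
  expect_error(time_to_fraction(exp_fit(64, 31), 0), "fraction")
  expect_error(time_to_fraction(exp_fit(100, NA), 0.5), "A = 100")
})

test_that("fits match the brute-force lattice oracle on noisy instances", {
  set.seed(101)
  tt <- seq(0, 160, by = 20)
  for (i in 1:10) {
    A <- runif(1, 40, 85)
    tau <- runif(1, 10, 100)
    y <- oracle_model(tt, A, tau) + rnorm(length(tt), 0, 4)
    y[1] <- 100
    fit <- fit_exponential(tt, y)
    grid <- oracle_grid_fit(tt, y)
    # the continuous optimiser must do at least as well as any 0.1-step
    # lattice point (the SSE surface can be valley-flat, so parameters
    # themselves are not compared)
    expect_lte(fit$residual_sse, grid$sse + 1e-6)
    # sanity on the oracle itself: wherever the continuous optimum falls
    # inside the lattice range, the lattice minimum beats the fit's
    # nearest lattice point
    if (fit$tau <= 160 && fit$A <= 100) {
      sse_at_lattice <- sum((y - oracle_model(tt, round(fit$A, 1),
                                              round(fit$tau, 1)))^2)
      expect_lte(grid$sse, sse_at_lattice + 1e-9)
    }
  }
})

test_that("dimensional consistency: rescaling time rescales tau only", {
  set.seed(7)
  tt <- seq(0, 160, by = 20)
  y <- oracle_model(tt, 60, 40) + c(0, rnorm(8, 0, 3))
  f1 <- fit_exponential(tt, y)
  f2 <- fit_exponential(tt / 60, y) # minutes instead of seconds
  expect_equal(f2$A, f1$A, tolerance = 1e-4)
  expect_equal(f2$tau * 60, f1$tau, tolerance = 1e-3)
})

test_that("goodness of fit and significance are reported", {
  set.seed(21)
  tt <- seq(0, 160, by = 20)
  y <- oracle_model(tt, 64, 31) + c(0, rnorm(8, 0, 4))
  fit <- fit_exponential(tt, y)
  expect_gt(fit$r_squared, 0.5)
  expect_lt(fit$r_squared, 1)
  # cross-check R^2 and the F-test against direct formulas
  sse <- sum((y - predict(fit, tt))^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(fit$r_squared, 1 - sse / sst, tolerance = 1e-9)
  f <- (sst - sse) / (sse / (length(y) - 2))
  expect_equal(fit$p_value, pf(f, 1, length(y) - 2, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_lt(fit$p_value, 0.05)
})

test_that("degenerate and malformed series are handled explicitly", {
  tt <- seq(0, 160, by = 20)
  fit <- fit_exponential(tt, rep(100, 9))
  expect_true(fit$degenerate)
  expect_equal(fit$A, 100)
  expect_error(fit_exponential(c(5, 20, 40, 60), rep(90, 4)), "t = 0")
  expect_error(fit_exponential(c(0, 20, 40), c(100, 90, 85)), "4 points")
  expect_error(fit_exponential(c(0, 20, 20, 40), c(100, 90, 88, 85)),
               "increasing")
})

test_that("the t = 0 point can be excluded from the fit", {
  tt <- seq(0, 160, by = 20)
  y <- oracle_model(tt, 64, 31)
  f_with <- fit_exponential(tt, y, include_t0 = TRUE)
  f_without <- fit_exponential(tt, y, include_t0 = FALSE)
  # noiseless: both recover the truth
  expect_equal(f_without$A, 64, tolerance = 1e-6)
  expect_equal(f_without$tau, 31, tolerance = 1e-6)
  expect_equal(f_without$n_points, f_with$n_points - 1L)
})

test_that("fit_cohort fits every series of a long table", {
  truth <- tidyr::expand_grid(subject_id = c("S01", "S02"),
                              condition = c("HF", "LF"),
                              variable = c("IMVC", "VA", "QTW"))
  truth$A <- seq(40, 95, length.out = nrow(truth))
  truth$tau <- seq(15, 120, length.out = nrow(truth))
  obs <- generate_observations(truth, noise_sd = 0, seed = 1)
  fits <- fit_cohort(obs)
  expect_equal(nrow(fits), 12)
  merged <- dplyr::inner_join(fits, truth,
                              by = c("subject_id", "condition", "variable"))
  expect_equal(merged$A_pct, merged$A, tolerance = 1e-5)
  expect_equal(merged$tau_s, merged$tau, tolerance = 1e-4)
})
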