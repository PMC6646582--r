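# Independent oracles used across tests. Deliberately naive: they share no
# code with the package's fitting or model-evaluation paths.

# Direct evaluation of the exponential decline, written out longhand.
oracle_model <- function(t, A, tau) A + (100 - A) * exp(-t / tau)

# Brute-force SSE minimisation over a 0.1-step (A, tau) lattice.
oracle_grid_fit <- function(times, values, A_grid = seq(0, 100, by = 0.1),
                            tau_grid = seq(0.1, 160, by = 0.1)) {
  best_sse <- Inf
  best <- c(NA_real_, NA_real_)
  # accumulate SSE over the full lattice one time point at a time
  sse <- matrix(0, nrow = length(A_grid), ncol = length(tau_grid))
  for (k in seq_along(times)) {
    e <- exp(-times[k] / tau_grid)                      # 1 x n_tau
    pred <- outer(A_grid, e, function(a, ee) a + (100 - a) * ee)
    sse <- sse + (values[k] - pred)^2
  }
  idx <- arrayInd(which.min(sse), dim(sse))
  list(A = A_grid[idx[1]], tau = tau_grid[idx[2]], sse = min(sse))
}

# Reference cohort fixture path (the packaged copy).
reference_fixture_path <- function() {
  system.file("extdata", "reference_cohort.csv", package = "fatkin")
}
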