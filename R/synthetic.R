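#' Canonical latent-parameter names
#'
#' The 12 latent parameters of a simulated cohort: asymptote `A` and
#' curvature constant `tau` for each of the three variables (IMVC, VA,
#' QTW) in each force condition (HF, LF).
#'
#' @return character vector of 12 names, e.g. `"A_IMVC_HF"`.
#' @export
latent_parameter_names <- function() {
  as.vector(vapply(c("HF", "LF"), function(cond)
    vapply(c("IMVC", "VA", "QTW"), function(v)
      paste(c("A", "tau"), v, cond, sep = "_"), character(2)),
    character(6)))
}

#' Default cohort parameter distribution
#'
#' Means and standard deviations of the 12 latent parameters, taken from
#' the summary rows of the 13-subject reference cohort (see
#' [load_reference_cohort()]): e.g. HF torque declines to an asymptote of
#' 64 +/- 9% of baseline with a curvature constant of 31 +/- 14 s.
#'
#' @return tibble with columns `condition`, `variable`, `parameter`,
#'   `mean`, `sd`.
#' @export
default_parameter_table <- function() {
  tibble::tribble(
    ~condition, ~variable, ~parameter, ~mean, ~sd,
    "HF", "IMVC", "A",   64,  9,
    "HF", "IMVC", "tau", 31, 14,
    "HF", "VA",   "A",   82, 11,
    "HF", "VA",   "tau", 43, 30,
    "HF", "QTW",  "A",   71, 10,
    "HF", "QTW",  "tau", 49, 21,
    "LF", "IMVC", "A",   53, 11,
    "LF", "IMVC", "tau", 50, 30,
    "LF", "VA",   "A",   74, 13,
    "LF", "VA",   "tau", 90, 45,
    "LF", "QTW",  "A",   63, 11,
    "LF", "QTW",  "tau", 44, 27)
}

#' Default latent correlation structure
#'
#' Identity except for the three empirically motivated couplings: the VA
#' and evoked-torque asymptotes are negatively correlated within each
#' condition (-0.70), and the evoked-torque asymptotes of the two
#' conditions are positively correlated (+0.67). This raw matrix is not
#' quite positive semi-definite; [cohort_config()] projects it to the
#' nearest correlation matrix before sampling.
#'
#' @return 12 x 12 named correlation matrix.
#' @export
default_correlation_matrix <- function() {
  nm <- latent_parameter_names()
  R <- diag(length(nm)); dimnames(R) <- list(nm, nm)
  set2 <- function(R, a, b, v) { R[a, b] <- v; R[b, a] <- v; R }
  R <- set2(R, "A_VA_HF", "A_QTW_HF", -0.70)
  R <- set2(R, "A_VA_LF", "A_QTW_LF", -0.70)
  set2(R, "A_QTW_HF", "A_QTW_LF", 0.67)
}

#' Configure a synthetic cohort
#'
#' Bundles everything needed to simulate a cohort of subjects with known
#' fatigue kinetics: the latent-parameter distribution (means/SDs), the
#' correlation structure over the 12 latent parameters, the measurement
#' schedule (accumulated contraction times of the neuromuscular tests),
#' and the observation noise.
#'
#' A correlation matrix that is symmetric with unit diagonal but not
#' positive semi-definite is repaired by projection to the nearest
#' correlation matrix ([Matrix::nearPD()]); if repair moves any entry by
#' more than `repair_tolerance` the configuration errors out.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param parameter_table tibble as [default_parameter_table()].
#' @param correlation 12 x 12 correlation matrix over the latent
#'   parameters, named as [latent_parameter_names()].
#' @param noise_sd observation noise SD in percent points (default 4,
#'   which yields individual fit R-squared around 0.9 at the default
#'   kinetics).
#' @param times measurement schedule in accumulated contraction seconds;
#'   must start at 0 and be strictly increasing. Default `0, 20, ..., 160`
#'   (a test every twenty 1-s contractions).
#' @param seed integer seed controlling all simulation randomness.
#' @param repair_tolerance maximum entry shift allowed for the PSD repair.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 13,
                          parameter_table = default_parameter_table(),
                          correlation = default_correlation_matrix(),
                          noise_sd = 4,
                          times = seq(0, 160, by = 20),
                          seed = 1L,
                          repair_tolerance = 0.1) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("`n_subjects` must be at least 2", call. = FALSE)
  stopifnot(is.data.frame(parameter_table),
            all(c("condition", "variable", "parameter", "mean", "sd") %in%
                  names(parameter_table)))
  if (any(parameter_table$sd < 0))
    stop("all SDs must be >= 0", call. = FALSE)
  if (!is.numeric(times) || times[1] != 0 || any(diff(times) <= 0))
    stop("`times` must start at 0 and be strictly increasing", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)

  nm <- latent_parameter_names()
  if (!is.matrix(correlation) || !identical(dim(correlation), c(12L, 12L)))
    stop("`correlation` must be a 12 x 12 matrix", call. = FALSE)
  if (is.null(dimnames(correlation)))
    dimnames(correlation) <- list(nm, nm)
  correlation <- correlation[nm, nm]
  if (max(abs(correlation - t(correlation))) > 1e-12 ||
      max(abs(diag(correlation) - 1)) > 1e-12)
    stop("`correlation` must be symmetric with unit diagonal", call. = FALSE)
  if (any(abs(correlation) > 1))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    repaired <- as.matrix(Matrix::nearPD(correlation, corr = TRUE,
                                         keepDiag = TRUE)$mat)
    shift <- max(abs(repaired - correlation))
    if (shift > repair_tolerance)
      stop(sprintf(
        "correlation matrix is too far from positive semi-definite (repair shift %.3f > %.3f)",
        shift, repair_tolerance), call. = FALSE)
    message(sprintf(
      "correlation matrix repaired to nearest PSD (max entry shift %.3f)",
      shift))
    correlation <- repaired
    dimnames(correlation) <- list(nm, nm)
  }

  structure(list(n_subjects = as.integer(n_subjects),
                 parameter_table = parameter_table,
                 correlation = correlation,
                 noise_sd = noise_sd, times = times,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$n_subjects, "subjects |",
      length(x$times), "tests at t =", paste(x$times, collapse = ","),
      "s | noise_sd =", x$noise_sd, "| seed =", x$seed, "\n")
  invisible(x)
}

# Means/SDs of the parameter table in canonical latent order. Internal.
latent_moments <- function(parameter_table) {
  key <- paste(parameter_table$parameter, parameter_table$variable,
               parameter_table$condition, sep = "_")
  nm <- latent_parameter_names()
  miss <- setdiff(nm, key)
  if (length(miss))
    stop("parameter_table is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  list(mean = stats::setNames(parameter_table$mean[match(nm, key)], nm),
       sd = stats::setNames(parameter_table$sd[match(nm, key)], nm))
}

#' Draw per-subject true fatigue parameters
#'
#' Samples each subject's 12 latent parameters from a truncated
#' multivariate normal: draws come from the configured Gaussian and whole
#' rows are redrawn until all asymptotes lie in (0, 100\] and all curvature
#' constants are positive. Redrawing preserves the configured correlations
#' approximately (exactly, as truncation mass goes to zero).
#'
#' @param config a [cohort_config()].
#' @return tibble of true parameters, one row per subject: `subject_id`
#'   plus the 12 latent columns.
#' @export
generate_cohort_parameters <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  mo <- latent_moments(config$parameter_table)
  D <- diag(mo$sd)
  Sigma <- D %*% config$correlation %*% D
  n <- config$n_subjects

  valid <- function(x) {
    a_cols <- grepl("^A_", latent_parameter_names())
    all(x[a_cols] > 0 & x[a_cols] <= 100) & all(x[!a_cols] > 0)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  draw <- function(k) {
    m <- MASS::mvrnorm(k, mu = mo$mean, Sigma = Sigma, tol = 1e-8)
    if (k == 1) matrix(m, nrow = 1, dimnames = list(NULL, names(mo$mean))) else m
  }
  x <- draw(n)
  bad <- !apply(x, 1, valid)
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > 10000L)
      stop("could not draw valid parameters: configured distribution places too much mass outside (0,100] x (0,Inf)",
           call. = FALSE)
    x[bad, ] <- draw(sum(bad))
    bad <- !apply(x, 1, valid)
  }
  out <- tibble::as_tibble(x)
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%02d", seq_len(n))), out)
  out
}

# Save/restore .Random.seed so generator seeds never leak into the
# caller's RNG stream. Internal.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Pivot a wide true-parameter table to long format
#'
#' @param true_params output of [generate_cohort_parameters()].
#' @return tibble `subject_id`, `condition`, `variable`, `A`, `tau`.
#' @export
cohort_parameters_long <- function(true_params) {
  stopifnot("subject_id" %in% names(true_params))
  true_params |>
    tidyr::pivot_longer(-"subject_id", names_to = c("parameter", "variable",
                                                    "condition"),
                        names_sep = "_", values_to = "value") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value") |>
    dplyr::select("subject_id", "condition", "variable", "A", "tau")
}

#' Simulate noisy fatigue observations from true parameters
#'
#' Evaluates the exponential fatigue model at each measurement time and
#' adds independent homoscedastic Gaussian noise on the percent scale. The
#' `t = 0` observation is fixed to exactly 100 regardless of noise:
#' normalization to baseline defines it.
#'
#' @param true_params wide true-parameter table
#'   ([generate_cohort_parameters()]) or its long form.
#' @param times measurement times in accumulated contraction seconds,
#'   including 0.
#' @param noise_sd observation noise SD in percent points (>= 0).
#' @param seed integer seed.
#' @return long tibble `subject_id`, `condition`, `variable`, `time_s`,
#'   `value_pct`.
#' @export
generate_observations <- function(true_params, times = seq(0, 160, by = 20),
                                  noise_sd = 4, seed = 1L) {
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!0 %in% times)
    stop("`times` must include the baseline t = 0", call. = FALSE)
  long <- if (all(c("A", "tau") %in% names(true_params))) true_params
          else cohort_parameters_long(true_params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  obs <- tidyr::expand_grid(long, time_s = sort(times)) |>
    dplyr::mutate(value_pct = fatigue_model(.data$time_s, .data$A, .data$tau))
  eps <- stats::rnorm(nrow(obs), 0, noise_sd)
  obs$value_pct <- obs$value_pct + eps
  obs$value_pct[obs$time_s == 0] <- 100
  dplyr::select(obs, "subject_id", "condition", "variable",
                "time_s", "value_pct") |>
    dplyr::arrange(.data$subject_id, .data$condition, .data$variable,
                   .data$time_s)
}

#' Simulate a full cohort: true parameters plus noisy observations
#'
#' @param config a [cohort_config()].
#' @return list with `parameters` (wide truth table) and `observations`
#'   (long series tibble).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  params <- generate_cohort_parameters(config)
  obs <- generate_observations(params, times = config$times,
                               noise_sd = config$noise_sd,
                               # derived, stays well below 2^31
                               seed = config$seed + 1000L)
  list(parameters = params, observations = obs)
}
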