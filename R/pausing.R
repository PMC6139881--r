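#' Add localisation noise to a trajectory table
#'
#' Adds i.i.d. zero-mean Gaussian offsets to every recorded position,
#' emulating the finite localisation accuracy of single-particle tracking.
#' `sigma_nm` is given in nanometres and converted to lattice sites via
#' the site length `a`.
#'
#' @param traj A trajectory tibble with a `position` column (sites).
#' @param sigma_nm Noise standard deviation (nm).
#' @param a Site length (um).
#' @param seed Optional integer seed.
#' @return The trajectory with perturbed `position`.
#' @export
add_localization_noise <- function(traj, sigma_nm, a = 0.0084, seed = NULL) {
  if (sigma_nm < 0) abort("`sigma_nm` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (sigma_nm > 0) {
    traj$position <- traj$position +
      rnorm(nrow(traj), sd = sigma_nm / (a * 1000))
  }
  traj
}

#' Detect periods of no or slow motion in frame-sampled trajectories
#'
#' Applies the frame-based displacement-threshold protocol to each motor's
#' trajectory: frame-to-frame displacements below `cfg$d_c` sites count as
#' small (backward motion included); a period starts at the frame
#' preceding the first of `cfg$onset_run` consecutive small displacements,
#' tolerates isolated large displacements, and ends at the frame preceding
#' the first of `cfg$termination_run` consecutive large displacements (or
#' at the trajectory boundary, flagged `truncated`). Only periods lasting
#' at least `cfg$cutoff` seconds are reported. The duration counts the
#' slow frames only (so the shortest detectable period is exactly
#' `onset_run` frames and the censoring correction extrapolates cleanly),
#' whereas the progression is measured up to the frame at which normal
#' motion is confirmed again, i.e. including the termination
#' displacements.
#'
#' @param traj A tibble with columns `motor_id`, `t`, `position` (sites),
#'   uniformly sampled at `cfg$frame_interval`. If `cfg$noise_sigma > 0`
#'   the noise is injected first (see [add_localization_noise()]).
#' @param cfg A [detection_config()].
#' @param a Site length (um), for the noise conversion.
#' @return A tibble of periods: `motor_id`, `start_time`, `end_time`,
#'   `duration` (s), `progression` (sites), `truncated`.
#' @export
#' @examples
#' traj <- tibble::tibble(motor_id = 1L, t = seq(0, 0.7, by = 0.1),
#'                        position = c(0, 8, 16, 17, 17, 18, 26, 34))
#' detect_periods(traj, detection_config(d_c = 5))
detect_periods <- function(traj, cfg = detection_config(), a = 0.0084) {
  stopifnot(inherits(cfg, "detection_config"))
  need <- c("motor_id", "t", "position")
  if (!all(need %in% names(traj))) {
    abort("`traj` needs columns motor_id, t, position")
  }
  if (cfg$noise_sigma > 0) {
    traj <- add_localization_noise(traj, cfg$noise_sigma, a)
  }
  traj <- dplyr::arrange(traj, .data$motor_id, .data$t)
  res <- .detect_periods_cpp(as.integer(traj$motor_id), traj$t,
                             traj$position, cfg$d_c, cfg$onset_run,
                             cfg$termination_run, cfg$cutoff)
  out <- tibble::as_tibble(res)
  out$truncated <- as.logical(out$truncated)
  dplyr::mutate(out, duration = .data$end_time - .data$start_time,
                .after = "end_time")
}

#' Censored-exponential correction of detected pause statistics
#'
#' Periods shorter than the detection cutoff exist but cannot be observed.
#' Assuming an exponential duration distribution, the tail above
#' `cfg$tail_min` is fitted by the shifted maximum-likelihood estimator
#' (binning-free by memorylessness), and the observed count is
#' extrapolated below the cutoff:
#' `corrected = n_detected / exp(-cutoff / tau_hat)`. The per-step
#' probability divides the corrected count by the number of steps taken by
#' the analysed motors.
#'
#' Durations coming from the frame-based detectors are integer multiples
#' of the frame interval; the likelihood of such grid-censored
#' observations is geometric, and the naive continuous mean-excess
#' estimator would be biased low by up to half a frame. When the supplied
#' durations are frame-quantised (detected automatically) the geometric
#' maximum-likelihood estimate
#' \eqn{\hat\tau = -\Delta/\log(m/(m+\Delta))} is used, with `m` the mean
#' excess over `tail_min` and \eqn{\Delta} the frame interval; for
#' continuous durations it reduces to `m`.
#'
#' @param periods A tibble from [detect_periods()] or [jam_periods()], or
#'   a bare numeric vector of durations (s). Truncated periods are
#'   excluded from the duration statistics.
#' @param cfg A [detection_config()] (supplies `cutoff` and `tail_min`).
#' @param total_steps Steps taken by the analysed motors in the analysis
#'   window (for the per-step probability; `NA` to skip).
#' @param min_tail Minimum number of tail durations required for the fit.
#' @return A one-row tibble: `n_detected`, `tau_hat` (s),
#'   `corrected_count`, `per_step_probability`, `total_steps`, `n_tail`.
#' @export
#' @examples
#' set.seed(1)
#' d <- rexp(500, 1 / 0.4) + 0.3   # exponential durations above the cutoff
#' correct_pause_stats(d, detection_config(), total_steps = 1e5)
correct_pause_stats <- function(periods, cfg = detection_config(),
                                total_steps = NA_real_, min_tail = 20) {
  stopifnot(inherits(cfg, "detection_config"))
  durations <- if (is.numeric(periods)) {
    periods
  } else {
    dplyr::filter(periods, !.data$truncated)$duration
  }
  tail_d <- durations[durations >= cfg$tail_min]
  if (length(tail_d) < min_tail) {
    abort(sprintf("only %d durations above tail_min = %g s (need %d)",
                  length(tail_d), cfg$tail_min, min_tail))
  }
  m <- mean(tail_d - cfg$tail_min)
  dt <- cfg$frame_interval
  quantised <- all(abs(durations / dt - round(durations / dt)) < 1e-6)
  tau_hat <- if (quantised && m > 0) -dt / log(m / (m + dt)) else m
  n_detected <- length(durations)
  corrected <- n_detected / exp(-cfg$cutoff / tau_hat)
  tibble::tibble(
    n_detected = n_detected, tau_hat = tau_hat,
    corrected_count = corrected,
    per_step_probability = corrected / total_steps,
    total_steps = total_steps, n_tail = length(tail_d)
  )
}

#' Jam-membership periods from simulation frames
#'
#' The alternative detector that bypasses displacement thresholds: at each
#' frame a motor is in a period iff it is itself inactive or its front
#' head sits exactly one site behind the back head of an in-period motor
#' (the strict-adjacency chain towards the minus end). Traffic jams
#' assembled purely stochastically, with no inactive member, are excluded
#' by construction. Maximal runs of consecutive in-state frames form
#' periods; apply [correct_pause_stats()] for the cutoff correction.
#'
#' @param frames The `frames` tibble of a pausing-enabled
#'   [simulate_lattice()] run (needs `motor_id`, `t`, `site`, `active`).
#' @param cfg A [detection_config()] (supplies `frame_interval`, `cutoff`).
#' @param L Ring length of the simulation.
#' @return A tibble of periods like [detect_periods()]'s.
#' @export
jam_periods <- function(frames, cfg = detection_config(), L) {
  need <- c("motor_id", "t", "site", "active")
  if (!all(need %in% names(frames))) {
    abort("`frames` needs columns motor_id, t, site, active (run the simulator with record_frames = TRUE and pausing enabled)")
  }
  fr <- dplyr::arrange(frames, .data$t, .data$site)
  frame_idx <- match(fr$t, sort(unique(fr$t)))
  fr$in_state <- .jam_state_cpp(frame_idx, as.integer(fr$site),
                                fr$active, as.integer(L))
  dt <- cfg$frame_interval
  empty <- tibble::tibble(motor_id = integer(), start_time = numeric(),
                          end_time = numeric(), duration = numeric(),
                          progression = numeric(), truncated = logical())
  if (!any(fr$in_state)) return(empty)
  fr <- dplyr::arrange(fr, .data$motor_id, .data$t)
  per <- fr |>
    dplyr::group_by(.data$motor_id) |>
    dplyr::mutate(
      new_run = dplyr::row_number() == 1L |
        .data$in_state != dplyr::lag(.data$in_state, default = FALSE) |
        .data$t - dplyr::lag(.data$t, default = -Inf) > 1.5 * dt,
      run_id = cumsum(.data$new_run),
      first_t = min(.data$t), last_t = max(.data$t)
    ) |>
    dplyr::filter(.data$in_state) |>
    dplyr::group_by(.data$motor_id, .data$run_id) |>
    dplyr::summarise(
      start_time = min(.data$t), end_time = max(.data$t),
      truncated = min(.data$t) <= min(.data$first_t) + 0.5 * dt |
        max(.data$t) >= max(.data$last_t) - 0.5 * dt,
      .groups = "drop"
    ) |>
    dplyr::mutate(duration = .data$end_time - .data$start_time,
                  progression = NA_real_) |>
    dplyr::filter(.data$duration >= cfg$cutoff - 1e-9) |>
    dplyr::select("motor_id", "start_time", "end_time", "duration",
                  "progression", "truncated")
  per
}

#' Total steps taken by the motors of a trajectory table
#'
#' Sums each motor's net displacement over its recorded trajectory —
#' the step count entering the per-step probability of
#' [correct_pause_stats()].
#'
#' @param frames A trajectory tibble (`motor_id`, `position`).
#' @return Total steps (numeric).
#' @export
total_steps_from_frames <- function(frames) {
  frames |>
    dplyr::summarise(steps = max(.data$position) - min(.data$position),
                     .by = "motor_id") |>
    dplyr::summarise(total = sum(round(.data$steps))) |>
    dplyr::pull("total")
}

#' Expected number of motors affected by one pausing motor
#'
#' Heuristic traffic-jam amplification: while a motor is inactive for a
#' mean time `T`, followers pile up behind it; after reactivation the jam
#' disperses slowly enough to capture further motors, and summing the
#' geometric series gives
#' \deqn{N = \frac{T V}{g - V/\nu},}
#' with `V = nu (1-2 rho)/(1-rho)` the bulk velocity in sites/s and gap
#' term `g = 1/rho - 2` when jammed motors keep their two-site footprint
#' (`spacing = "spaced"`) or `g = 1/rho - 1` when they pack onto single
#' sites (`"compact"`; larger travel distance, hence smaller N at equal
#' density).
#'
#' @param T_pause Mean pause duration (s).
#' @param params A [model_params()] (supplies `nu`).
#' @param rho Bulk density in (0, 1/2).
#' @param spacing `"spaced"` or `"compact"`.
#' @return Expected number of affected motors; `Inf` (with a warning)
#'   when the gap term does not exceed `V/nu` and the jam never clears.
#' @export
#' @examples
#' jam_size(0.12, kinesin1_params(), rho = 0.25)
jam_size <- function(T_pause, params, rho,
                     spacing = c("spaced", "compact")) {
  spacing <- match.arg(spacing)
  stopifnot(inherits(params, "model_params"))
  if (any(rho <= 0 | rho >= 0.5)) abort("`rho` must lie in (0, 1/2)")
  V <- params$nu * (1 - 2 * rho) / (1 - rho)  # sites/s
  g <- 1 / rho - if (spacing == "spaced") 2 else 1
  denom <- g - V / params$nu
  out <- ifelse(denom > 0, T_pause * V / denom, Inf)
  if (any(!is.finite(out))) {
    warn("jam never dissolves (gap term <= V/nu); returning Inf")
  }
  out
}

#' Per-step probability of entering a period of no or slow motion
#'
#' One inactivation event renders the pausing motor plus the `N` motors
#' jammed behind it visible to the detector:
#' `p = p_inactivation * (1 + N)`.
#'
#' @param p_inactivation Per-step inactivation probability.
#' @param N Expected motors affected per pause ([jam_size()]).
#' @return Per-step probability.
#' @export
period_probability <- function(p_inactivation, N) {
  if (any(p_inactivation < 0) || any(N < 0)) {
    abort("inputs must be non-negative")
  }
  p_inactivation * (1 + N)
}
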