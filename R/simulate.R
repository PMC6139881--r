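#' Simulation run configuration
#'
#' @param L Ring length in sites. The default, 2000, makes boundary effects
#'   irrelevant for motors with ~100-step runs.
#' @param t_end Total simulated time (s).
#' @param burn_in Equilibration time (s) excluded from all measurements;
#'   defaults to 20 spontaneous-detachment lifetimes, capped below `t_end`.
#' @param frame_interval Trajectory sampling interval (s).
#' @param seed Integer seed; every random draw in the run flows from it.
#' @param tracer_fraction Fraction of motors whose trajectories are written
#'   to the frame table (their bound-state kinetics are unchanged).
#' @param record_frames,record_runs Toggle the frame table / run records.
#' @param n_init Motors placed (evenly spaced, active) at `t = 0`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(L = 2000, t_end = 100,
                       burn_in = NULL,
                       frame_interval = 0.1, seed = 1,
                       tracer_fraction = 1, record_frames = TRUE,
                       record_runs = TRUE, n_init = 0) {
  structure(
    list(L = as.integer(L), t_end = t_end, burn_in = burn_in,
         frame_interval = frame_interval, seed = as.integer(seed),
         tracer_fraction = tracer_fraction, record_frames = record_frames,
         record_runs = record_runs, n_init = as.integer(n_init)),
    class = "sim_config"
  )
}

#' Gillespie simulation of the motor lattice gas
#'
#' Statistically exact simulation of the continuous-time Markov chain:
#' dimeric motors on a ring of `config$L` sites hop at `nu` (exclusion),
#' attach at `omega_A` on adjacent empty site pairs, detach spontaneously
#' at `omega_D` and at the facilitated rate `theta` when their leading head
#' abuts the trailing head of the motor in front (by default the rear motor
#' of the pair bounces off; `facilitated_variant = "kick_off"` instead
#' detaches the leading motor — the two give the same phenomenology).
#' With pausing enabled, bound active motors switch off at
#' `r_inactivation`, inactive motors cannot step (but still detach through
#' both channels and block others) and switch back on at `r_activation`.
#'
#' Trajectory positions are recorded as cumulative displacement (attachment
#' site plus steps taken), so ring wrap-around never corrupts run lengths.
#'
#' @param params A [model_params()] object.
#' @param pausing A [pausing_params()] object, or `NULL` for the original
#'   model.
#' @param config A [sim_config()] object.
#' @param facilitated_variant Which motor of an adjacent pair carries the
#'   facilitated channel.
#' @return A list of class `"lattice_sim"` with elements `frames` (tibble:
#'   `t`, `motor_id`, `position` in sites, `site` on the ring, `active`),
#'   `runs` (tibble: `motor_id`, `attach_time`, `detach_time`, `dwell`,
#'   `attach_site`, `detach_site`, `steps`, `run_length_sites`,
#'   `detach_cause`, `truncated`), `stats` (event counts and time
#'   integrals), plus the inputs.
#' @export
#' @examples
#' sim <- simulate_lattice(kinesin1_params(c = 10),
#'                         config = sim_config(L = 400, t_end = 20, seed = 2))
#' glance(sim)
simulate_lattice <- function(params, pausing = NULL, config = sim_config(),
                             facilitated_variant = c("rear_bounce_off",
                                                     "kick_off")) {
  stopifnot(inherits(params, "model_params"), inherits(config, "sim_config"))
  facilitated_variant <- match.arg(facilitated_variant)
  if (identical(params$landing_variant, "one_site")) {
    abort("the simulator implements only the two_site landing geometry")
  }
  pausing <- pausing %||% pausing_params(enabled = FALSE, nu = params$nu)
  stopifnot(inherits(pausing, "pausing_params"))
  burn_in <- config$burn_in %||%
    min(20 / max(params$omega_D, 1e-6), 0.5 * config$t_end)

  set.seed(config$seed)
  raw <- .sim_gillespie_cpp(
    L = config$L, nu = params$nu, omega_A = params$omega_A,
    omega_D = params$omega_D, theta = params$theta,
    kick_off = facilitated_variant == "kick_off",
    r_in = if (pausing$enabled) pausing$r_inactivation else 0,
    r_act = pausing$r_activation,
    t_end = config$t_end, burn_in = burn_in,
    frame_interval = config$frame_interval,
    tracer_fraction = config$tracer_fraction,
    record_frames = config$record_frames, record_runs = config$record_runs,
    n_init = config$n_init
  )
  frames <- tibble::as_tibble(raw$frames)
  frames$active <- as.logical(frames$active)
  runs <- tibble::as_tibble(raw$runs)
  runs <- dplyr::mutate(
    runs,
    dwell = .data$detach_time - .data$attach_time,
    run_length_sites = .data$steps,
    detach_cause = c("spontaneous", "facilitated", "truncated")[.data$cause + 1],
    truncated = .data$cause == 2L,
    tracked = as.logical(.data$tracked)
  )
  runs$cause <- NULL
  structure(
    list(frames = frames, runs = runs, stats = raw$stats,
         params = params, pausing = pausing, config = config,
         burn_in = burn_in, facilitated_variant = facilitated_variant),
    class = "lattice_sim"
  )
}

#' @export
print.lattice_sim <- function(x, ...) {
  cat(sprintf(
    "<lattice_sim> L = %d, c = %g nM, t = %g s (burn-in %g s), seed %d\n",
    x$config$L, x$params$c, x$config$t_end, x$burn_in, x$config$seed))
  cat(sprintf("  %d run records, %d trajectory frames%s\n",
              nrow(x$runs), nrow(x$frames),
              if (x$pausing$enabled) ", pausing enabled" else ""))
  invisible(x)
}

#' Empirical observables of a simulation run
#'
#' Time-averaged density (leading-head site fraction), current (bond
#' crossings per bond per second), mean dwell time and run length over
#' completed runs, mean velocity (displacement over dwell, in um/s), and
#' the tracer landing rate `lambda0` times the time-averaged probability
#' that a random adjacent site pair is empty. Also reports the detachment
#' split and the attachment/detachment balance from the event log.
#'
#' @param sim A [simulate_lattice()] result.
#' @param min_dwell Completed runs shorter than this (s) are excluded from
#'   the velocity average (avoids 0/0-dominated ratios).
#' @param tracers_only Restrict the run-based observables (`tau`, `V`,
#'   `l`) to the tracer subpopulation, mirroring experiments in which only
#'   sparse labelled motors are analysed.
#' @return A one-row tibble with columns `c`, `rho`, `j`, `tau`, `V`, `l`,
#'   `lam`, `n_runs`, the Monte-Carlo standard errors `rho_se`, `tau_se`,
#'   `V_se`, `l_se`, `lam_se` (run-to-run for the single-motor
#'   observables, block-averaged over 20 time blocks for `rho` and `lam`),
#'   `facilitated_share`, `attach_events`, `detach_events`.
#' @export
measure_observables <- function(sim, min_dwell = 0, tracers_only = FALSE) {
  stopifnot(inherits(sim, "lattice_sim"))
  s <- sim$stats
  p <- sim$params
  L <- sim$config$L
  done <- dplyr::filter(sim$runs, !.data$truncated,
                        .data$dwell > min_dwell)
  if (tracers_only) done <- dplyr::filter(done, .data$tracked)
  if (nrow(done) == 0) {
    abort("no completed run records; increase t_end")
  }
  block_len <- s$T_measure / length(s$int_n_blocks)
  rho_b <- s$int_n_blocks / (L * block_len)
  lam_b <- p$lambda0 * s$int_pairs_blocks / (L * block_len)
  j_b <- s$hops_blocks / (L * block_len)
  nb <- length(rho_b)
  vel <- done$steps * p$a / done$dwell
  tibble::tibble(
    c = p$c,
    rho = s$int_n / (L * s$T_measure),
    j = s$hops / (L * s$T_measure),
    tau = mean(done$dwell),
    V = mean(vel),
    l = mean(done$steps) * p$a,
    lam = p$lambda0 * s$int_pairs / (L * s$T_measure),
    n_runs = nrow(done),
    rho_se = sd(rho_b) / sqrt(nb),
    j_se = sd(j_b) / sqrt(nb),
    tau_se = sd(done$dwell) / sqrt(nrow(done)),
    V_se = sd(vel) / sqrt(nrow(done)),
    l_se = sd(done$steps * p$a) / sqrt(nrow(done)),
    lam_se = sd(lam_b) / sqrt(nb),
    lam_count = {
      # landing rate as the experiment measures it: count tracer landings
      # (attachment propensity is proportional to pair vacancy)
      n_land <- sum(sim$runs$tracked)
      if (p$omega_A > 0 && n_land > 0) {
        p$lambda0 * (n_land / (sim$config$tracer_fraction * L *
                                 s$T_measure)) / p$omega_A
      } else lam
    },
    lam_count_se = lam_count / sqrt(max(sum(sim$runs$tracked), 1)),
    facilitated_share = s$det_fac / max(s$det_fac + s$det_spont, 1),
    attach_events = s$attaches,
    detach_events = s$det_fac + s$det_spont
  )
}

#' @rdname measure_observables
#' @param x A `lattice_sim`.
#' @param ... Unused.
#' @export
glance.lattice_sim <- function(x, ...) measure_observables(x)

#' Collective observables of a run, without run records
#'
#' Density, current and landing rate (with block standard errors) from the
#' time-averaged statistics alone; usable when run recording is off.
#'
#' @param sim A [simulate_lattice()] result.
#' @return A one-row tibble with `rho`, `j`, `lam` and their `_se`s.
#' @export
collective_observables <- function(sim) {
  stopifnot(inherits(sim, "lattice_sim"))
  s <- sim$stats
  p <- sim$params
  L <- sim$config$L
  block_len <- s$T_measure / length(s$int_n_blocks)
  rho_b <- s$int_n_blocks / (L * block_len)
  j_b <- s$hops_blocks / (L * block_len)
  lam_b <- p$lambda0 * s$int_pairs_blocks / (L * block_len)
  nb <- length(rho_b)
  tibble::tibble(
    c = p$c,
    rho = s$int_n / (L * s$T_measure),
    j = s$hops / (L * s$T_measure),
    lam = p$lambda0 * s$int_pairs / (L * s$T_measure),
    rho_se = sd(rho_b) / sqrt(nb),
    j_se = sd(j_b) / sqrt(nb),
    lam_se = sd(lam_b) / sqrt(nb)
  )
}

#' @rdname simulate_lattice
#' @param x A `lattice_sim`.
#' @param ... Unused.
#' @export
tidy.lattice_sim <- function(x, ...) x$runs
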