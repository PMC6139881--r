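test_that("localisation noise has the right scale and is seeded", {
  traj <- tibble::tibble(motor_id = 1L, t = seq_len(1e5) * 0.1,
                         position = 0)
  noisy <- add_localization_noise(traj, sigma_nm = 20, a = 0.0084, seed = 4)
  expect_equal(sd(noisy$position), 20 / 8.4, tolerance = 0.02)
  again <- add_localization_noise(traj, sigma_nm = 20, a = 0.0084, seed = 4)
  expect_identical(noisy, again)
  expect_identical(add_localization_noise(traj, 0), traj)
  expect_error(add_localization_noise(traj, -1), "non-negative")
})

test_that("protocol detector follows the onset/termination anchors", {
  cfg <- detection_config(d_c = 5)
  traj <- tibble::tibble(motor_id = 1L, t = seq(0, 0.7, by = 0.1),
                         position = c(0, 8, 16, 17, 17, 18, 26, 34))
  per <- detect_periods(traj, cfg)
  expect_equal(nrow(per), 1)
  expect_equal(per$start_time, 0.2)
  expect_equal(per$end_time, 0.5)
  expect_equal(per$duration, 0.3)
  # progression runs to the frame where normal motion is confirmed
  expect_equal(per$progression, 34 - 16)
  expect_false(per$truncated)
})

test_that("immobile motors yield one truncated full-length period", {
  cfg <- detection_config(d_c = 2)
  traj <- tibble::tibble(motor_id = 1L, t = seq(0, 2, by = 0.1),
                         position = 5)
  per <- detect_periods(traj, cfg)
  expect_equal(nrow(per), 1)
  expect_true(per$truncated)
  expect_equal(per$duration, 2)
  expect_equal(per$progression, 0)
})

test_that("a steadily fast walker produces no periods", {
  cfg <- detection_config(d_c = 2)
  traj <- tibble::tibble(motor_id = 1L, t = seq(0, 2, by = 0.1),
                         position = seq(0, 2, by = 0.1) * 79)
  expect_equal(nrow(detect_periods(traj, cfg)), 0)
})

test_that("single tolerated large displacement does not end a period", {
  cfg <- detection_config(d_c = 5)
  # smalls, one large, smalls, then two larges
  pos <- cumsum(c(0, 1, 1, 1, 8, 1, 1, 8, 8, 8))
  traj <- tibble::tibble(motor_id = 1L, t = seq_along(pos) * 0.1 - 0.1,
                         position = pos)
  per <- detect_periods(traj, cfg)
  expect_equal(nrow(per), 1)
  expect_equal(per$duration, 0.6, tolerance = 1e-9)
})

test_that("censored-exponential correction matches the closed form", {
  cfg <- detection_config(d_c = 2)
  # 50 detections with a continuous tail of mean 0.2 above tail_min
  set.seed(99)
  durations <- 0.5 + rexp(50, 1 / 0.2) + runif(50) * 1e-4
  st <- correct_pause_stats(durations, cfg, total_steps = 1e4)
  expect_equal(st$corrected_count,
               50 / exp(-cfg$cutoff / st$tau_hat), tolerance = 1e-12)
  expect_equal(st$per_step_probability, st$corrected_count / 1e4)
  expect_gte(st$corrected_count, st$n_detected)
})

test_that("tail estimator recovers the generating mean (round trip)", {
  cfg <- detection_config(d_c = 2, tail_min = 0.5)
  set.seed(123)
  # continuous exponential durations observed above the 0.3 s cutoff
  d <- 0.3 + rexp(1e4, 1 / 0.12)
  st <- correct_pause_stats(d, cfg, total_steps = NA)
  expect_equal(st$tau_hat, 0.12, tolerance = 0.05)
  # frame-quantised durations: geometric MLE undoes the grid bias
  dq <- 0.1 * floor(d / 0.1)
  dq <- dq[dq >= 0.3]
  stq <- correct_pause_stats(dq, cfg, total_steps = NA)
  expect_equal(stq$tau_hat, 0.12, tolerance = 0.05)
  expect_error(correct_pause_stats(c(0.3, 0.4), cfg),
               "above tail_min")
})

test_that("jam membership follows the strict adjacency chain", {
  # inactive motor at front site 11 with three strictly adjacent
  # followers (fronts 9, 7, 5) and one detached motor further back
  frames <- tibble::tibble(
    motor_id = 1:5, t = 0.1,
    site = c(11L, 9L, 7L, 5L, 1L),
    position = c(11, 9, 7, 5, 1),
    active = c(FALSE, TRUE, TRUE, TRUE, TRUE)
  )
  cfg <- detection_config(d_c = 2)
  fr <- dplyr::arrange(frames, t, site)
  in_state <- kintraffic:::.jam_state_cpp(rep(1L, 5), fr$site, fr$active, 40L)
  got <- fr$motor_id[in_state]
  expect_setequal(got, 1:4)

  # all-active configurations are never in-state, even when adjacent
  in2 <- kintraffic:::.jam_state_cpp(rep(1L, 5), fr$site, rep(TRUE, 5), 40L)
  expect_false(any(in2))
})

test_that("jam detector returns nothing when pausing never happens", {
  s <- simulate_lattice(fitted_pars(c = 20),
                        config = sim_config(L = 400, t_end = 20,
                                            burn_in = 2, seed = 21))
  jp <- jam_periods(s$frames, detection_config(d_c = 2), L = 400)
  expect_equal(nrow(jp), 0)
})

test_that("an isolated pausing motor is counted for its inactive spell", {
  # one motor, long inactive interval, empty lattice otherwise
  frames <- tibble::tibble(
    motor_id = 1L, t = seq(0, 2, by = 0.1),
    site = 10L, position = 10,
    active = c(rep(TRUE, 5), rep(FALSE, 10), rep(TRUE, 6))
  )
  jp <- jam_periods(frames, detection_config(d_c = 2), L = 100)
  expect_equal(nrow(jp), 1)
  expect_equal(jp$duration, 0.9, tolerance = 1e-9)
})

test_that("jam-size amplification evaluates and compares spacings", {
  p <- model_params(nu = 79, omega_a = 0.054, c = 0)
  expect_equal(jam_size(0.12, p, 0.25, "spaced"), 4.74, tolerance = 5e-3)
  expect_equal(jam_size(0.12, p, 0.25, "compact"), 2.71, tolerance = 5e-3)
  # compact jams have a larger gap term, hence smaller N at equal density
  for (r in c(0.05, 0.15, 0.3, 0.45)) {
    expect_lt(jam_size(0.12, p, r, "compact"),
              jam_size(0.12, p, r, "spaced"))
  }
  # N -> 0 at vanishing density; with the mean-field velocity the gap
  # term always exceeds V/nu on (0, 1/2) (spaced N reduces to
  # T nu rho / (1 - 2 rho)), so N is finite, increasing and divergent
  # only in the full-decoration limit
  expect_lt(jam_size(0.12, p, 1e-5), 1e-3)
  grid <- seq(0.01, 0.49, by = 0.01)
  Ns <- jam_size(0.12, p, grid)
  expect_true(all(is.finite(Ns) & Ns > 0))
  expect_true(all(diff(Ns) > 0))
  expect_equal(Ns, 0.12 * p$nu * grid / (1 - 2 * grid), tolerance = 1e-12)
  expect_gt(jam_size(0.12, p, 0.4999), 1e3)
  expect_error(jam_size(0.12, p, 0.6), "1/2")
})

test_that("per-step period probability is the amplified product", {
  expect_equal(period_probability(0.004, 4.74), 0.004 * 5.74)
  expect_identical(period_probability(0.004, 0), 0.004)
  expect_identical(period_probability(0, 10), 0)
  expect_error(period_probability(-1, 1), "non-negative")
})
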