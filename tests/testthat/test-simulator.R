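test_that("channel enumeration matches hand counts on a six-site ring", {
  p <- model_params(nu = 1, omega_a = 0.1, c = 1, omega_D = 0.01,
                    theta = 0.05, a = 1)
  # motors with front heads at sites 3 and 5: one hop (motor at 5), one
  # attach pair (front site 1), two spontaneous, one facilitated (rear
  # motor at 3 abuts the back head at 4)
  ev <- enumerate_event_rates(lattice_state(6, c(3, 5)), p)
  expect_equal(sum(ev$channel == "hop"), 1)
  expect_equal(ev$site[ev$channel == "hop"], 5)
  expect_equal(sum(ev$channel == "attach"), 1)
  expect_equal(ev$site[ev$channel == "attach"], 1)
  expect_equal(sum(ev$channel == "detach_spontaneous"), 2)
  expect_equal(ev$site[ev$channel == "detach_facilitated"], 3)
  expect_equal(sum(ev$rate), 1 + 0.1 + 2 * 0.01 + 0.05)

  # empty ring: L attachment channels, nothing else
  ev0 <- enumerate_event_rates(lattice_state(8), p)
  expect_equal(nrow(ev0), 8)
  expect_true(all(ev0$channel == "attach"))
  expect_true(all(ev0$rate == p$omega_A))

  # fully decorated ring: no hops, no attachments, L/2 each detach channel
  full <- lattice_state(8, c(2, 4, 6, 8))
  evf <- enumerate_event_rates(full, p)
  expect_equal(sum(evf$channel == "hop"), 0)
  expect_equal(sum(evf$channel == "attach"), 0)
  expect_equal(sum(evf$channel == "detach_spontaneous"), 4)
  expect_equal(sum(evf$channel == "detach_facilitated"), 4)

  # kick-off variant flags the leading motor of the pair instead
  evk <- enumerate_event_rates(lattice_state(6, c(3, 5)), p,
                               facilitated_variant = "kick_off")
  expect_equal(evk$site[evk$channel == "detach_facilitated"], 5)
  expect_error(lattice_state(6, c(3, 4)), "overlap")
})

test_that("a single free motor walks at nu sites per second", {
  p <- model_params(nu = 10, omega_a = 0, c = 0, omega_D = 0, theta = 0,
                    a = 1)
  s <- simulate_lattice(p, config = sim_config(L = 100, t_end = 200,
                                               burn_in = 0, n_init = 1,
                                               seed = 3))
  # bond-crossing rate nu / L per bond
  expect_equal(s$stats$hops / (100 * 200), 10 / 100, tolerance = 0.05)
  v_emp <- (max(s$frames$position) - min(s$frames$position)) / 200
  expect_equal(v_emp, 10, tolerance = 0.05)
})

test_that("absorbing empty lattice stays empty without attachment", {
  p <- model_params(nu = 10, omega_a = 0, c = 5, omega_D = 1, theta = 1)
  s <- simulate_lattice(p, config = sim_config(L = 50, t_end = 5,
                                               burn_in = 0, seed = 1))
  expect_equal(nrow(s$frames), 0)
  expect_equal(nrow(s$runs), 0)
  expect_equal(s$stats$hops, 0)
})

test_that("identical seeds give bit-identical output", {
  cfg <- sim_config(L = 300, t_end = 15, burn_in = 2, seed = 77)
  pp <- pausing_params()
  a <- simulate_lattice(fitted_pars(c = 15), pp, config = cfg)
  b <- simulate_lattice(fitted_pars(c = 15), pp, config = cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$runs, b$runs)
  expect_identical(a$stats, b$stats)
  c2 <- simulate_lattice(fitted_pars(c = 15), pp,
                         config = sim_config(L = 300, t_end = 15,
                                             burn_in = 2, seed = 78))
  expect_false(identical(a$stats, c2$stats))
})

test_that("dimer integrity and exclusion hold in every recorded frame", {
  s <- simulate_lattice(fitted_pars(c = 40), pausing_params(),
                        config = sim_config(L = 120, t_end = 20,
                                            burn_in = 1, seed = 5))
  bad <- s$frames |>
    dplyr::summarise(
      clash = {
        st <- sort(site)
        gaps <- diff(c(st, st[1] + 120))
        any(gaps < 2) || anyDuplicated(st) > 0
      },
      .by = t
    )
  expect_false(any(bad$clash))
  # noiseless positions are monotone non-decreasing per motor
  mono <- s$frames |>
    dplyr::arrange(motor_id, t) |>
    dplyr::summarise(ok = all(diff(position) >= 0), .by = motor_id)
  expect_true(all(mono$ok))
})

test_that("attachment and detachment balance in the stationary state", {
  s <- simulate_lattice(fitted_pars(c = 20),
                        config = sim_config(L = 1000, t_end = 60,
                                            burn_in = 20, seed = 8,
                                            record_frames = FALSE))
  att <- s$stats$attaches
  det <- s$stats$det_spont + s$stats$det_fac
  expect_lt(abs(att - det), 5 * sqrt(att))
})

test_that("near-empty lattice lands tracers at the bare rate lambda0", {
  p <- model_params(nu = 79, omega_a = 1e-5, c = 1, omega_D = 2, theta = 0)
  s <- simulate_lattice(p, config = sim_config(L = 500, t_end = 50,
                                               burn_in = 5, seed = 2,
                                               record_frames = FALSE))
  lam <- p$lambda0 * s$stats$int_pairs / (500 * s$stats$T_measure)
  expect_equal(lam, p$lambda0, tolerance = 0.01)
})

test_that("facilitated variant choice does not change the bulk observables", {
  cfgv <- sim_config(L = 800, t_end = 50, burn_in = 10,
                     record_frames = FALSE, seed = 31)
  a <- glance(simulate_lattice(fitted_pars(c = 30), config = cfgv))
  b <- glance(simulate_lattice(fitted_pars(c = 30), config = cfgv,
                               facilitated_variant = "kick_off"))
  expect_equal(a$rho, b$rho, tolerance = 0.05)
  expect_equal(a$j, b$j, tolerance = 0.05)
  expect_equal(a$tau, b$tau, tolerance = 0.05)
})

test_that("detachment-cause split follows the mean-field share", {
  p <- fitted_pars(c = 20)
  s <- simulate_lattice(p, config = sim_config(L = 1000, t_end = 80,
                                               burn_in = 20, seed = 13,
                                               record_frames = FALSE))
  m <- measure_observables(s)
  rho <- m$rho
  share_mf <- p$theta * rho / (p$theta * rho + p$omega_D * (1 - rho))
  expect_equal(m$facilitated_share, share_mf, tolerance = 0.05)
})
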