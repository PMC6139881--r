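test_that("stationary density matches the closed form and zeroes the balance", {
  expect_equal(stationary_density(omega_A = 0.01, omega_D = 0.001, theta = 0),
               0.4219, tolerance = 1e-4)
  expect_equal(round(stationary_density(omega_A = 0.01, omega_D = 0.001,
                                        theta = 0.1), 4),
               0.1913)
  expect_identical(stationary_density(omega_A = 0, omega_D = 0.5, theta = 1),
                   0)
  # plug-back property: the returned density is a root of the balance
  draws <- random_rates(1000)
  rho <- stationary_density(omega_A = draws$omega_A, omega_D = draws$omega_D,
                            theta = draws$theta)
  expect_true(all(rho >= 0 & rho <= 0.5))
  res <- density_balance_residual(rho, omega_A = draws$omega_A,
                                  omega_D = draws$omega_D,
                                  theta = draws$theta)
  expect_lt(max(abs(res)), 1e-10)
  # attachment-detachment balance at the root
  lhs <- draws$omega_A * (1 - 2 * rho)^2 / (1 - rho)
  rhs <- draws$omega_D * rho + draws$theta * rho^2 / (1 - rho)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("theta = 0 reduces to the dimer Langmuir-kinetics closed form", {
  draws <- random_rates(50, seed = 7)
  rho <- stationary_density(omega_A = draws$omega_A, omega_D = draws$omega_D,
                            theta = 0)
  ref <- 2 * draws$omega_A /
    (4 * draws$omega_A + draws$omega_D +
       sqrt(4 * draws$omega_A * draws$omega_D + draws$omega_D^2))
  expect_equal(rho, ref, tolerance = 1e-12)
})

test_that("stationary density is monotone in theta and omega_A", {
  thetas <- c(0, 0.01, 0.05, 0.2, 1)
  rho_th <- stationary_density(omega_A = 0.01, omega_D = 0.001,
                               theta = thetas)
  expect_true(all(diff(rho_th) < 0))
  oAs <- c(0.001, 0.01, 0.05, 0.2)
  rho_oa <- stationary_density(omega_A = oAs, omega_D = 0.001, theta = 0.05)
  expect_true(all(diff(rho_oa) > 0))
})

test_that("one-site landing variant solves its own balance", {
  rho <- stationary_density(omega_A = 0.3, omega_D = 0.5, theta = 2,
                            landing_variant = "one_site")
  expect_gt(rho, 0); expect_lt(rho, 0.5)
  res <- density_balance_residual(rho, omega_A = 0.3, omega_D = 0.5,
                                  theta = 2, landing_variant = "one_site")
  expect_lt(abs(res), 1e-9)
  # pathological input: attachment still wins at full decoration
  expect_error(stationary_density(omega_A = 10, omega_D = 0.1, theta = 0.1,
                                  landing_variant = "one_site"),
               "no root")
})

test_that("current-density relation and its optimum", {
  expect_identical(current_density(0, 5), 0)
  expect_identical(current_density(0.5, 5), 0)
  rho_star <- optimal_density()
  expect_equal(rho_star, (2 - sqrt(2)) / 2)
  expect_equal(current_density(rho_star, 1), 3 - 2 * sqrt(2),
               tolerance = 1e-12)
  expect_equal(report_round(rho_star), 0.29)
  # brute-force maximisation oracle at 1e-6 resolution
  expect_silent(optimal_density(verify = TRUE, resolution = 1e-6))
  # monomer reference: argmax of rho (1 - rho) is 1/2
  grid <- seq(0, 1, by = 1e-4)
  expect_equal(grid[which.max(grid * (1 - grid))], 0.5, tolerance = 1e-3)
  expect_error(current_density(0.7, 1), "0, 1/2")
})

test_that("low-concentration observables reproduce the kinesin-1 anchors", {
  mf <- predict_observables(fitted_pars(), concentrations = 1e-6)
  expect_equal(mf$tau, 1 / 0.53, tolerance = 1e-3)
  expect_equal(report_round(mf$tau), 1.9)
  expect_equal(mf$V, 0.66, tolerance = 1e-3)
  expect_equal(mf$lam, 0.018, tolerance = 1e-3)
  expect_equal(mf$l, 0.66 / 0.53, tolerance = 1e-3)  # ~1.245 um
})

test_that("run length is the dwell-velocity product for random draws", {
  draws <- random_rates(200, seed = 11)
  for (i in seq_len(20)) {
    p <- model_params(nu = 50, omega_a = draws$omega_A[i], c = 1,
                      omega_D = draws$omega_D[i], theta = draws$theta[i])
    mf <- predict_observables(p, concentrations = c(0.5, 1, 20))
    expect_identical(mf$l, mf$tau * mf$V)
    expect_true(all(mf$j >= 0))
  }
})

test_that("jammed limit of the observable formulas", {
  # rho -> 1/2: V and lambda vanish, tau -> 1/(omega_D + theta)
  p <- fitted_pars()
  rho <- 0.5 - 1e-9
  expect_equal(p$V0 * (1 - 2 * rho) / (1 - rho), 0, tolerance = 1e-6)
  expect_equal(p$lambda0 * (1 - 2 * rho)^2 / (1 - rho), 0, tolerance = 1e-6)
  expect_equal(1 / (p$omega_D + p$theta * rho / (1 - rho)),
               1 / (p$omega_D + p$theta), tolerance = 1e-6)
})

test_that("detachment crossover sits near 7 nM for the fitted parameters", {
  cc <- crossover_concentration(fitted_pars())
  expect_equal(cc, 7.14, tolerance = 1e-2)
  # bisection on concentration agrees with the closed-form inversion
  p <- fitted_pars()
  rho_star <- p$omega_D / (p$omega_D + p$theta)
  f <- function(conc) {
    stationary_density(omega_A = p$omega_a * conc, omega_D = p$omega_D,
                       theta = p$theta) - rho_star
  }
  cc_bis <- uniroot(f, c(1e-6, 1e4), tol = 1e-12)$root
  expect_equal(cc, cc_bis, tolerance = 1e-8)
  # theta -> infinity pushes the crossover towards zero concentration
  huge <- model_params(nu = 79, omega_a = 0.054, c = 0, omega_D = 0.53,
                       theta = 1e6)
  expect_lt(crossover_concentration(huge), 1e-3)
  expect_error(crossover_concentration(model_params(theta = 0)), "positive")
})

test_that("facilitated fraction crosses one half at the crossover", {
  p <- fitted_pars()
  cc <- crossover_concentration(p)
  ff <- facilitated_fraction(p, concentrations = c(cc * 0.5, cc, cc * 2))
  expect_lt(ff$facilitated_fraction[1], 0.5)
  expect_equal(ff$facilitated_fraction[2], 0.5, tolerance = 1e-9)
  expect_gt(ff$facilitated_fraction[3], 0.5)
})

test_that("ring density profile relaxes to the uniform bulk value", {
  p <- fitted_pars(c = 10)
  dp <- density_profile(p, L = 60, boundary_mode = "ring")
  expect_lt(max(abs(dp$profile$rho - stationary_density(p))), 1e-8)
  expect_lt(dp$residual, 1e-10)
})

test_that("open boundaries give an entry layer of roughly 100 sites", {
  p <- fitted_pars(c = 5)
  dp <- density_profile(p, L = 400, boundary_mode = "open")
  expect_lt(dp$residual, 1e-10)
  bulk <- stationary_density(p)
  prof <- dp$profile$rho
  # bulk plateau reached within ~100 sites of the minus end
  expect_lt(abs(prof[120] - bulk) / bulk, 0.05)
  # but clearly not yet at 30 sites in
  expect_gt(abs(prof[30] - bulk) / bulk, 0.1)
  expect_error(density_profile(p, L = 5), "at least 10")
})
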