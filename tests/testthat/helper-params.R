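# shared fixtures: the fitted kinesin-1 rates and a cheap dimensionless set
fitted_pars <- function(c = 0) kinesin1_params(c = c)

dimensionless_pars <- function(omega_A = 0.01, omega_D = 0.001, theta = 0.05) {
  model_params(nu = 1, omega_a = omega_A, c = 1, omega_D = omega_D,
               theta = theta, a = 1)
}

# random rate draws used by the property-style tests
random_rates <- function(n, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    omega_A = 10^runif(n, -4, 0),
    omega_D = 10^runif(n, -4, 0),
    theta = 10^runif(n, -4, 1)
  )
}
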