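#' Stationary bulk motor density
#'
#' Solves the bulk mean-field balance between attachment, spontaneous
#' detachment, and facilitated detachment,
#' \deqn{\omega_A \frac{(1-2\rho)^2}{1-\rho} = \omega_D \rho +
#'   \theta \frac{\rho^2}{1-\rho},}
#' for the stationary dimer density (the probability that a site carries a
#' leading head), bounded to \eqn{[0, 1/2]}. For the `two_site` landing
#' variant the closed form
#' \deqn{\rho_s = \frac{2\omega_A}{4\omega_A + \omega_D +
#'   \sqrt{4\omega_A\omega_D + 4\theta\omega_A + \omega_D^2}}}
#' is used; for `one_site` the attachment term is \eqn{\omega_A(1-\rho)}
#' and the root is found numerically.
#'
#' @param params A [model_params()] object, or `NULL` when raw rates are
#'   supplied.
#' @param omega_A,omega_D,theta Raw rates (1/s), taken from `params` when
#'   given.
#' @param landing_variant `"two_site"` or `"one_site"`; taken from `params`
#'   when given.
#' @return Stationary density in \eqn{[0, 1/2]}.
#' @export
#' @examples
#' stationary_density(omega_A = 0.01, omega_D = 0.001, theta = 0)  # 0.4219
stationary_density <- function(params = NULL, omega_A = params$omega_A,
                               omega_D = params$omega_D,
                               theta = params$theta,
                               landing_variant = params$landing_variant %||%
                                 "two_site") {
  if (any(c(omega_A, omega_D, theta) < 0)) abort("rates must be non-negative")
  if (identical(landing_variant, "one_site")) {
    return(.one_site_density(omega_A, omega_D, theta))
  }
  2 * omega_A /
    (4 * omega_A + omega_D + sqrt(4 * omega_A * omega_D +
                                    4 * theta * omega_A + omega_D^2))
}

# positive root of omega_A (1 - rho) = omega_D rho + theta rho^2/(1 - rho)
# in [0, 1/2]
.one_site_density <- function(omega_A, omega_D, theta) {
  f <- Vectorize(function(oa, od, th) {
    if (oa == 0) return(0)
    g <- function(r) oa * (1 - r) - od * r - th * r^2 / (1 - r)
    if (g(0.5) > 0) {
      abort("one_site stationary density has no root in [0, 1/2]")
    }
    uniroot(g, c(0, 0.5), tol = 1e-12)$root
  })
  unname(f(omega_A, omega_D, theta))
}

#' Stationarity defect of the bulk mean-field equation
#'
#' The rate of density change at density `rho`; zero at the stationary
#' density. Useful as a plug-back check.
#'
#' @inheritParams stationary_density
#' @param rho Density.
#' @return `d rho / dt` (1/s).
#' @export
density_balance_residual <- function(rho, params = NULL,
                                     omega_A = params$omega_A,
                                     omega_D = params$omega_D,
                                     theta = params$theta,
                                     landing_variant =
                                       params$landing_variant %||% "two_site") {
  attach <- if (identical(landing_variant, "one_site")) {
    omega_A * (1 - rho)
  } else {
    omega_A * (1 - 2 * rho)^2 / (1 - rho)
  }
  attach - omega_D * rho - theta * rho^2 / (1 - rho)
}

#' Mean-field current-density relation for dimeric motors
#'
#' \deqn{j(\rho) = \nu \rho \frac{1 - 2\rho}{1 - \rho}.}
#' Compared with the monomer relation \eqn{\rho(1-\rho)} the dimer current
#' is skewed by the local correlation factor \eqn{1/(1-\rho)}.
#'
#' @param rho Density in \eqn{[0, 1/2]}.
#' @param nu Hopping rate (1/s).
#' @return Current (motors per site per s).
#' @export
#' @examples
#' current_density(0.25, 79)
current_density <- function(rho, nu = 1) {
  if (any(rho < -1e-12 | rho > 0.5 + 1e-12)) {
    abort("`rho` must lie in [0, 1/2]")
  }
  nu * rho * (1 - 2 * rho) / (1 - rho)
}

#' Density at which the dimer current is maximal
#'
#' The argmax of [current_density()] on \eqn{[0, 1/2]} is
#' \eqn{(2 - \sqrt 2)/2 \approx 0.29}, above half of the full-decoration
#' density (the monomer argmax would be 1/2 of full occupation).
#'
#' @param verify Numerically confirm the analytic argmax by grid search.
#' @param resolution Grid spacing for the verification.
#' @return The optimal density.
#' @export
optimal_density <- function(verify = FALSE, resolution = 1e-6) {
  rho_star <- (2 - sqrt(2)) / 2
  if (verify) {
    grid <- seq(0, 0.5, by = resolution)
    rho_grid <- grid[which.max(current_density(grid))]
    if (abs(rho_grid - rho_star) > resolution) {
      abort("grid search disagrees with the analytic argmax")
    }
  }
  rho_star
}

#' Mean-field predictions of the four single-motor observables
#'
#' At each concentration, computes the stationary density and from it the
#' dwell time \eqn{\tau = [\omega_D + \theta\rho/(1-\rho)]^{-1}}, velocity
#' \eqn{V = V_0 (1-2\rho)/(1-\rho)}, run length \eqn{l = \tau V}, landing
#' rate \eqn{\lambda = \lambda_0 (1-2\rho)^2/(1-\rho)} (`two_site`; for
#' `one_site`, \eqn{\lambda_0(1-\rho)}), and the current
#' \eqn{j = \nu\rho(1-2\rho)/(1-\rho)}.
#'
#' @param params A [model_params()] object (its `c` is ignored when
#'   `concentrations` is given).
#' @param concentrations Concentrations (nM) at which to predict; defaults
#'   to `params$c`.
#' @return A tibble with one row per concentration and columns `c`, `rho`,
#'   `j` (motors/site/s), `tau` (s), `V` (um/s), `l` (um), `lam` (1/um/s).
#' @export
#' @examples
#' predict_observables(kinesin1_params(), concentrations = c(0, 10, 50))
predict_observables <- function(params, concentrations = params$c) {
  stopifnot(inherits(params, "model_params"))
  omega_A <- params$omega_a * concentrations
  rho <- stationary_density(omega_A = omega_A, omega_D = params$omega_D,
                            theta = params$theta,
                            landing_variant = params$landing_variant)
  tau <- 1 / (params$omega_D + params$theta * rho / (1 - rho))
  V <- params$V0 * (1 - 2 * rho) / (1 - rho)
  lam <- if (identical(params$landing_variant, "one_site")) {
    params$lambda0 * (1 - rho)
  } else {
    params$lambda0 * (1 - 2 * rho)^2 / (1 - rho)
  }
  tibble::tibble(
    c = concentrations, rho = rho, j = current_density(rho, params$nu),
    tau = tau, V = V, l = tau * V, lam = lam
  )
}

#' Concentration at which facilitated detachment overtakes spontaneous
#'
#' Solves for the concentration where the mean-field spontaneous
#' detachment flux \eqn{\omega_D\rho} equals the facilitated flux
#' \eqn{\theta\rho^2/(1-\rho)}, i.e. where the stationary density reaches
#' \eqn{\rho^* = \omega_D/(\omega_D + \theta)}. The attachment rate is
#' obtained by inverting the stationary balance at \eqn{\rho^*} and
#' converted to concentration via `omega_a`. For the fitted kinesin-1
#' parameters this is ~7 nM, well below the half-decoration concentration.
#'
#' @param params A [model_params()] object with `theta > 0`.
#' @return Concentration (nM).
#' @export
#' @examples
#' crossover_concentration(kinesin1_params())
crossover_concentration <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$theta <= 0) abort("`theta` must be positive")
  rho_star <- params$omega_D / (params$omega_D + params$theta)
  if (rho_star >= 0.5) {
    abort("crossover density is unreachable (theta too small)")
  }
  omega_A <- (params$omega_D * rho_star * (1 - rho_star) +
                params$theta * rho_star^2) / (1 - 2 * rho_star)^2
  omega_A / params$omega_a
}

#' Fraction of detachment events that are facilitated
#'
#' \eqn{\theta\rho/(\theta\rho + \omega_D(1-\rho))}: the mean-field share
#' of unbinding events caused by a neighbouring motor, at the stationary
#' density for each concentration.
#'
#' @inheritParams predict_observables
#' @return A tibble with columns `c`, `rho`, `facilitated_fraction`.
#' @export
facilitated_fraction <- function(params, concentrations = params$c) {
  mf <- predict_observables(params, concentrations)
  dplyr::mutate(
    dplyr::select(mf, "c", "rho"),
    facilitated_fraction = params$theta * .data$rho /
      (params$theta * .data$rho + params$omega_D * (1 - .data$rho))
  )
}

#' Spatial mean-field density profile
#'
#' Relaxes the site-resolved mean-field master equation
#' \deqn{\partial_t\rho_i =
#'   \nu\Big[\frac{(1-\rho_i-\rho_{i+1})\rho_{i-1}}{1-\rho_i} -
#'   \frac{(1-\rho_{i+1}-\rho_{i+2})\rho_i}{1-\rho_{i+1}}\Big] +
#'   \omega_A\frac{(1-\rho_i-\rho_{i+1})(1-\rho_{i-1}-\rho_i)}{1-\rho_i} -
#'   \omega_D\rho_i - \theta\frac{\rho_{i+2}\rho_i}{1-\rho_{i+1}}}
#' to its fixed point by forward time-stepping. On a ring the profile is
#' uniform and equals [stationary_density()]; with open boundaries the
#' minus end receives no injected flux and motors exit freely at the plus
#' end (densities beyond the lattice treated as zero), producing the
#' antenna-like entry layer.
#'
#' @param params A [model_params()] object.
#' @param L Number of lattice sites (>= 10).
#' @param boundary_mode `"ring"` or `"open"`.
#' @param tol Convergence tolerance on the maximal density time-derivative
#'   (1/s).
#' @param max_steps Step budget.
#' @return A list of class `"density_profile"` with elements `profile` (a
#'   tibble with `site`, `rho`), `boundary_mode`, `residual` and `steps`.
#' @export
density_profile <- function(params, L = 500,
                            boundary_mode = c("ring", "open"),
                            tol = 1e-10, max_steps = 2e6) {
  stopifnot(inherits(params, "model_params"))
  boundary_mode <- match.arg(boundary_mode)
  if (L < 10) abort("`L` must be at least 10")
  nu <- params$nu; oA <- params$omega_A; oD <- params$omega_D
  th <- params$theta
  rho <- rep(min(0.95 * stationary_density(params), 0.45), L)
  dt <- 0.2 / (nu + oA + oD + th + 1e-12)
  idx <- seq_len(L)
  shift <- function(x, k) {
    # k = +1 means rho_{i+1}
    if (boundary_mode == "ring") {
      x[((idx - 1 + k) %% L) + 1]
    } else {
      out <- rep(0, L)  # outside densities are zero
      src <- idx + k
      ok <- src >= 1 & src <= L
      out[ok] <- x[src[ok]]
      out
    }
  }
  deriv <- function(r) {
    rm1 <- shift(r, -1); rp1 <- shift(r, 1); rp2 <- shift(r, 2)
    nu * ((1 - r - rp1) * rm1 / (1 - r) -
            (1 - rp1 - rp2) * r / (1 - rp1)) +
      oA * (1 - r - rp1) * (1 - rm1 - r) / (1 - r) -
      oD * r - th * rp2 * r / (1 - rp1)
  }
  steps <- 0L
  chunk <- 200L
  repeat {
    for (k in seq_len(chunk)) {
      d <- deriv(rho)
      rho <- pmin(pmax(rho + dt * d, 0), 0.5)
    }
    steps <- steps + chunk
    res <- max(abs(deriv(rho)))
    if (res < tol) break
    if (steps >= max_steps) {
      abort(sprintf("density profile did not converge (residual %.3g)", res))
    }
  }
  structure(
    list(profile = tibble::tibble(site = idx, rho = rho),
         boundary_mode = boundary_mode, residual = res, steps = steps),
    class = "density_profile"
  )
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %d sites, %s boundaries, residual %.2g\n",
              nrow(x$profile), x$boundary_mode, x$residual))
  invisible(x)
}

#' @rdname density_profile
#' @param object,x A `density_profile`.
#' @param ... Unused.
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$site, .data$rho)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "lattice site", y = expression(rho),
                  title = sprintf("Mean-field density profile (%s)",
                                  object$boundary_mode)) +
    ggplot2::ylim(0, 0.5) +
    ggplot2::theme_minimal()
}
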