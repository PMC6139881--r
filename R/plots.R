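#' Plot mean-field concentration dependence of the observables
#'
#' Faceted curves of run length, dwell time, velocity and landing rate
#' over a concentration range, optionally overlaid with a dataset and/or
#' simulation measurements.
#'
#' @param params A [model_params()].
#' @param c_max Upper end of the concentration axis (nM).
#' @param data Optional dataset tibble (internal column names) drawn as
#'   points with error bars.
#' @param sim Optional tibble of [measure_observables()] rows drawn as
#'   squares.
#' @return A ggplot object.
#' @export
plot_concentration_series <- function(params, c_max = 100, data = NULL,
                                      sim = NULL) {
  grid <- seq(0, c_max, length.out = 200)
  mf <- predict_observables(params, grid)
  labs <- c(l = "run length l (um)", tau = "dwell time tau (s)",
            V = "velocity V (um/s)", lam = "landing rate lambda (1/um/s)")
  long <- function(d, keep) {
    tidyr::pivot_longer(d[c("c", keep)], -"c", names_to = "observable")
  }
  g <- ggplot2::ggplot(long(mf, names(labs)),
                       ggplot2::aes(.data$c, .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~observable, scales = "free_y",
                        labeller = ggplot2::as_labeller(labs)) +
    ggplot2::labs(x = "motor concentration c (nM)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    pts <- long(data, intersect(names(labs), names(data)))
    g <- g + ggplot2::geom_point(data = pts, colour = "#b2182b")
  }
  if (!is.null(sim)) {
    sq <- long(sim, intersect(names(labs), names(sim)))
    g <- g + ggplot2::geom_point(data = sq, shape = 22, fill = NA,
                                 colour = "#4d4d4d", size = 2)
  }
  g
}

#' @rdname fit_global
#' @export
autoplot.motor_fit <- function(object, ...) {
  p <- model_params(nu = object$fixed$nu, omega_a = object$omega_a_hat,
                    c = 0, omega_D = object$fixed$omega_D,
                    theta = object$theta_hat,
                    lambda0 = object$fixed$lambda0)
  plot_concentration_series(p, c_max = max(object$data$c),
                            data = object$data)
}

#' Histogram of detected period durations
#'
#' @param periods A tibble from [detect_periods()] or [jam_periods()].
#' @param binwidth Histogram bin width (s).
#' @return A ggplot object.
#' @export
plot_period_durations <- function(periods, binwidth = 0.1) {
  d <- dplyr::filter(periods, !.data$truncated)
  ggplot2::ggplot(d, ggplot2::aes(.data$duration)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "#2166ac", colour = "white") +
    ggplot2::labs(x = "period duration (s)", y = "count") +
    ggplot2::theme_minimal()
}

#' Trajectory ribbon plot
#'
#' Position against time for a subset of motors, coloured by activity
#' when the pausing variant was simulated.
#'
#' @param frames A `frames` tibble from [simulate_lattice()].
#' @param n_motors Number of motors (longest trajectories first) to draw.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(frames, n_motors = 20) {
  keep <- frames |>
    dplyr::count(.data$motor_id, sort = TRUE) |>
    dplyr::slice_head(n = n_motors)
  d <- dplyr::semi_join(frames, keep, by = "motor_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$position,
                                  group = .data$motor_id,
                                  colour = .data$active)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "position (sites)") +
    ggplot2::theme_minimal()
}
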