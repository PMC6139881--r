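#' Kinetic parameters of the lattice-gas motor model
#'
#' Bundles every rate and unit constant of the model in one validated
#' object. Motors are dimers occupying two adjacent lattice sites (site
#' length `a`), hopping towards the plus end at rate `nu`, attaching from a
#' reservoir at concentration `c` at rate `omega_A = omega_a * c` wherever
#' two adjacent sites are empty, detaching spontaneously at `omega_D`, and
#' detaching at an additional facilitated rate `theta` when the site in
#' front of a motor's leading head is occupied by the trailing head of
#' another motor.
#'
#' Internally all lengths are lattice sites and all times seconds; `a`
#' converts to micrometres at the I/O boundary and `V0 = nu * a` is the
#' free-motor speed.
#'
#' @param nu Hopping rate (1/s). Defaults to the kinesin-1 value 0.66/0.0084.
#' @param omega_a Attachment rate per concentration (1/nM/s).
#' @param c Motor volume concentration (nM).
#' @param omega_D Spontaneous detachment rate (1/s).
#' @param theta Facilitated detachment rate (1/s).
#' @param lambda0 Landing-rate normalisation of the labelled tracer
#'   population on an empty lattice (1/um/s).
#' @param c0_tracer Tracer reference concentration (nM); the landing assays
#'   keep labelled motors at 5 pM = 0.005 nM.
#' @param a Lattice-site length (um); the tubulin heterodimer repeat,
#'   8.4 nm.
#' @param landing_variant `"two_site"` (a motor needs two empty adjacent
#'   sites to land; the model default) or `"one_site"` (a single empty site
#'   suffices; mean-field only).
#'
#' @return A list of class `"model_params"` with the fields above plus the
#'   derived `omega_A = omega_a * c` and `V0 = nu * a`.
#' @seealso [kinesin1_params()] for the fitted kinesin-1 parameter set.
#' @export
#' @examples
#' p <- model_params(c = 10)
#' p$omega_A  # 0.054 * 10
model_params <- function(nu = 0.66 / 0.0084,
                         omega_a = 0.054,
                         c = 0,
                         omega_D = 0.53,
                         theta = 2.4,
                         lambda0 = 0.018,
                         c0_tracer = 0.005,
                         a = 0.0084,
                         landing_variant = c("two_site", "one_site")) {
  landing_variant <- match.arg(landing_variant)
  rates <- c(nu = nu, omega_a = omega_a, c = c, omega_D = omega_D,
             theta = theta, lambda0 = lambda0, c0_tracer = c0_tracer)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("all rates and concentrations must be finite and non-negative")
  }
  if (!is.finite(a) || a <= 0) abort("site length `a` must be positive")
  structure(
    list(nu = nu, omega_a = omega_a, c = c, omega_A = omega_a * c,
         omega_D = omega_D, theta = theta, lambda0 = lambda0,
         c0_tracer = c0_tracer, a = a, V0 = nu * a,
         landing_variant = landing_variant),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  nu      = %g /s   (V0 = %g um/s, a = %g um)\n", x$nu, x$V0, x$a))
  cat(sprintf("  omega_a = %g /nM/s, c = %g nM  =>  omega_A = %g /s\n",
              x$omega_a, x$c, x$omega_A))
  cat(sprintf("  omega_D = %g /s, theta = %g /s\n", x$omega_D, x$theta))
  cat(sprintf("  lambda0 = %g /um/s at c0 = %g nM; landing: %s\n",
              x$lambda0, x$c0_tracer, x$landing_variant))
  invisible(x)
}

#' Replace the reservoir concentration of a parameter set
#'
#' Returns a copy of `params` at concentration `c`, with `omega_A`
#' recomputed.
#'
#' @param params A [model_params()] object.
#' @param c New concentration (nM).
#' @return A `model_params` object.
#' @export
set_concentration <- function(params, c) {
  stopifnot(inherits(params, "model_params"))
  params$c <- c
  params$omega_A <- params$omega_a * c
  params
}

#' Fitted kinesin-1 parameter set
#'
#' The parameter values extracted from in vitro kinesin-1 concentration
#' series: `nu = 79/s` (from the 0.66 um/s free speed), `omega_D = 0.53/s`
#' (from the 1.9 s low-concentration dwell time), `lambda0 = 0.018/um/s`,
#' and the globally fitted `omega_a = 0.054/nM/s`, `theta = 2.4/s`.
#'
#' @param c Reservoir concentration (nM).
#' @param ... Overrides passed on to [model_params()].
#' @return A `model_params` object.
#' @export
kinesin1_params <- function(c = 0, ...) {
  model_params(nu = 0.66 / 0.0084, omega_a = 0.054, c = c,
               omega_D = 0.53, theta = 2.4, lambda0 = 0.018, ...)
}

#' Stochastic-pausing (inactive state) parameters
#'
#' Motors may lapse into an inactive state in which they cannot step but
#' remain bound (and keep both detachment channels, and block others).
#' Switching is rate-based: `r_inactivation` per bound active motor and
#' `r_activation` per inactive motor. The per-step inactivation probability
#' is `p_inactivation = r_inactivation / nu` and the mean pause duration is
#' `T_pause = 1 / r_activation`. Defaults are the values read off the
#' low-concentration single-motor data: a 0.4% per-step chance of pausing
#' and a 0.12 s mean pause.
#'
#' @param r_inactivation Switch-off rate (1/s).
#' @param r_activation Switch-on rate (1/s).
#' @param nu Hopping rate (1/s) used for the per-step conversion.
#' @param enabled Logical; `FALSE` gives the original (never-pausing) model.
#' @return A list of class `"pausing_params"`.
#' @export
#' @examples
#' pausing_params()             # kinesin-1 defaults
#' pausing_params(enabled = FALSE)
pausing_params <- function(r_inactivation = 0.004 * nu,
                           r_activation = 1 / 0.12,
                           nu = 0.66 / 0.0084,
                           enabled = TRUE) {
  if (!enabled) r_inactivation <- 0
  if (r_inactivation < 0 || r_activation <= 0 || nu <= 0) {
    abort("pausing rates must be non-negative and r_activation, nu positive")
  }
  structure(
    list(r_inactivation = r_inactivation, r_activation = r_activation,
         p_inactivation = r_inactivation / nu,
         T_pause = 1 / r_activation, enabled = enabled),
    class = "pausing_params"
  )
}

#' @export
print.pausing_params <- function(x, ...) {
  cat("<pausing_params>", if (!x$enabled) "(disabled)", "\n")
  cat(sprintf("  r_inactivation = %g /s (p_inactivation = %g per step)\n",
              x$r_inactivation, x$p_inactivation))
  cat(sprintf("  r_activation   = %g /s (T_pause = %g s)\n",
              x$r_activation, x$T_pause))
  invisible(x)
}

#' Configuration of the period-of-no-or-slow-motion detector
#'
#' Parameters of the frame-based displacement-threshold protocol: positions
#' are sampled every `frame_interval` seconds; a frame-to-frame displacement
#' below `d_c` (lattice sites; backward motion counts as small) is a
#' candidate; a period starts after `onset_run` consecutive small
#' displacements and ends after `termination_run` consecutive large ones; a
#' single large displacement within a period is tolerated. Only periods at
#' least `cutoff` seconds long are detectable; `tail_min` is the lower bound
#' of the exponential tail used by the censoring correction.
#'
#' @param frame_interval Sampling interval (s).
#' @param d_c Threshold displacement (lattice sites). Use [nm_to_sites()]
#'   to convert a threshold stated in nm.
#' @param noise_sigma Localisation noise s.d. (nm) to be injected before
#'   detection; 0 for none.
#' @param onset_run Consecutive small displacements confirming a start.
#' @param termination_run Consecutive large displacements ending a period.
#' @param cutoff Minimum detectable duration (s); must equal
#'   `onset_run * frame_interval`.
#' @param tail_min Lower bound (s) of the exponential tail fit.
#' @return A list of class `"detection_config"`.
#' @export
detection_config <- function(frame_interval = 0.1,
                             d_c = 2,
                             noise_sigma = 0,
                             onset_run = 3,
                             termination_run = 2,
                             cutoff = onset_run * frame_interval,
                             tail_min = 0.5) {
  if (d_c <= 0) abort("`d_c` must be positive")
  if (noise_sigma < 0) abort("`noise_sigma` must be non-negative")
  if (abs(cutoff - onset_run * frame_interval) > 1e-12) {
    abort("`cutoff` must equal onset_run * frame_interval")
  }
  if (tail_min < cutoff) abort("`tail_min` must be >= `cutoff`")
  structure(
    list(frame_interval = frame_interval, d_c = d_c,
         noise_sigma = noise_sigma, onset_run = onset_run,
         termination_run = termination_run, cutoff = cutoff,
         tail_min = tail_min),
    class = "detection_config"
  )
}

#' Convert a displacement threshold from nm to lattice sites
#'
#' @param nm Length in nanometres.
#' @param a Site length in micrometres (8.4 nm default).
#' @return Length in lattice sites.
#' @export
#' @examples
#' nm_to_sites(40)  # the 40 nm threshold ~ 5 sites
nm_to_sites <- function(nm, a = 0.0084) nm / (a * 1000)

#' Hopping rate from free-motor speed
#'
#' `nu = V0 / a`: the stepping rate consistent with an uncrowded speed `V0`
#' and site length `a`. For kinesin-1, 0.66 um/s over 8.4 nm sites gives
#' 79/s.
#'
#' @param V0 Free speed (um/s).
#' @param a Site length (um).
#' @return Hopping rate (1/s).
#' @export
#' @examples
#' rate_from_speed(0.66, 0.0084)  # ~79
rate_from_speed <- function(V0, a) {
  if (any(a <= 0)) abort("`a` must be positive")
  if (any(V0 < 0)) abort("`V0` must be non-negative")
  V0 / a
}

#' Fraction of the step cycle spent in the weakly bound state
#'
#' Interpreting the facilitated detachment rate `theta` as dissociation
#' from the one-head-bound intermediate, the spontaneous rate satisfies
#' `omega_D = f * theta`, so `f = omega_D / theta` is the time fraction a
#' stepping motor spends weakly bound. The kinesin-1 rates give f ~ 0.22.
#'
#' @param omega_D Spontaneous detachment rate (1/s).
#' @param theta Facilitated detachment rate (1/s).
#' @return The fraction `omega_D / theta`. Values above 1 are returned
#'   as-is with a warning (the interpretation breaks down there).
#' @export
#' @examples
#' weak_state_fraction(0.53, 2.4)
weak_state_fraction <- function(omega_D, theta) {
  if (any(theta <= 0)) abort("`theta` must be positive")
  f <- omega_D / theta
  if (any(f > 1)) warn("weak-state fraction exceeds 1; omega_D > theta")
  f
}

#' Attachment rate at a given reservoir concentration
#'
#' `omega_A = omega_a * c`.
#'
#' @param omega_a Attachment rate per concentration (1/nM/s).
#' @param c Concentration (nM).
#' @return Attachment rate (1/s).
#' @export
attachment_rate <- function(omega_a, c) {
  if (any(omega_a < 0) || any(c < 0)) abort("inputs must be non-negative")
  omega_a * c
}

#' Per-site attachment rate of the labelled tracer motors
#'
#' Converts the tracer landing-rate normalisation `lambda0` (landings per
#' um of microtubule per second, at reference concentration `c0`) into a
#' per-binding-site, per-nM attachment rate, assuming the motors can reach
#' `usable_pf` of the 13 protofilaments in a TIRF geometry (half, i.e. 6.5,
#' by default). For the kinesin-1 numbers this is ~5e-3 /nM/s, about ten
#' times smaller than the unlabelled `omega_a`.
#'
#' @param lambda0 Landing-rate normalisation (1/um/s).
#' @param a Site length (um).
#' @param c0 Tracer reference concentration (nM).
#' @param usable_pf Number of reachable protofilaments.
#' @return Per-site attachment rate (1/nM/s).
#' @export
#' @examples
#' tracer_site_attachment(0.018, 0.0084, 0.005)
tracer_site_attachment <- function(lambda0, a = 0.0084, c0 = 0.005,
                                   usable_pf = 6.5) {
  if (c0 <= 0 || usable_pf <= 0) abort("`c0` and `usable_pf` must be positive")
  lambda0 * a / (usable_pf * c0)
}

#' Round to the printed precision of report-level comparisons
#'
#' Two significant figures, the precision at which the model constants are
#' quoted.
#'
#' @param x Numeric.
#' @param digits Significant digits.
#' @return Rounded numeric.
#' @export
report_round <- function(x, digits = 2) signif(x, digits)
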