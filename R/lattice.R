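#' Construct a lattice configuration
#'
#' A ring of `L` sites carrying dimeric motors identified by their leading
#' (front) head positions; each motor also occupies the site behind its
#' front head. Used by [enumerate_event_rates()] and the exact
#' small-lattice solver.
#'
#' @param L Ring length (sites).
#' @param fronts Integer sites (1-based) of the motors' front heads.
#' @param active Logical vector (recycled) of per-motor activity flags.
#' @return A list of class `"lattice_state"` with `L`, `fronts`, `active`
#'   and the derived occupancy vector (`0` empty, `1` front, `2` back).
#' @export
#' @examples
#' lattice_state(6, fronts = c(3, 5))
lattice_state <- function(L, fronts = integer(), active = TRUE) {
  fronts <- as.integer(fronts)
  if (any(fronts < 1 | fronts > L)) abort("front sites must lie in 1..L")
  active <- rep_len(as.logical(active), length(fronts))
  occ <- integer(L)
  back <- ifelse(fronts == 1L, L, fronts - 1L)
  used <- c(fronts, back)
  if (anyDuplicated(used)) abort("motors overlap")
  occ[fronts] <- 1L
  occ[back] <- 2L
  structure(list(L = as.integer(L), fronts = fronts, active = active,
                 occ = occ),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  glyph <- c("-", "F", "B")[x$occ + 1]
  inact <- x$fronts[!x$active]
  glyph[inact] <- "f"
  cat(sprintf("<lattice_state> L = %d, %d motors\n  [%s]\n",
              x$L, length(x$fronts), paste(glyph, collapse = "")))
  invisible(x)
}

#' Enumerate the reaction channels of a configuration
#'
#' Lists every possible next event and its rate: hops (`nu`, active motors
#' with an empty target site), attachments (`omega_A` per adjacent empty
#' site pair, labelled by the front site of the would-be motor),
#' spontaneous detachments (`omega_D` per motor), facilitated detachments
#' (`theta` on the rear motor of each strictly adjacent pair, or the
#' leading motor under the kick-off variant), and, when pausing is
#' enabled, inactivation (`r_inactivation` per active motor) and
#' activation (`r_activation` per inactive motor).
#'
#' This pure-R enumeration doubles as the full-recompute validation of the
#' simulator's incremental channel bookkeeping and as the generator of the
#' exact master-equation solver.
#'
#' @param state A [lattice_state()].
#' @param params A [model_params()].
#' @param pausing A [pausing_params()] or `NULL`.
#' @param facilitated_variant `"rear_bounce_off"` or `"kick_off"`.
#' @return A tibble with columns `channel`, `site` (front site of the
#'   motor concerned, or of the attaching motor) and `rate`; zero-rate
#'   channels are omitted.
#' @export
#' @examples
#' enumerate_event_rates(lattice_state(6, c(3, 5)), kinesin1_params(c = 10))
enumerate_event_rates <- function(state, params, pausing = NULL,
                                  facilitated_variant = c("rear_bounce_off",
                                                          "kick_off")) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "model_params"))
  facilitated_variant <- match.arg(facilitated_variant)
  L <- state$L
  occ <- state$occ
  nxt <- function(i) i %% L + 1L
  prv <- function(i) (i - 2L) %% L + 1L
  rows <- list()
  add <- function(channel, site, rate) {
    if (length(site) && rate > 0) {
      rows[[length(rows) + 1]] <<- tibble::tibble(channel = channel,
                                                  site = as.integer(site),
                                                  rate = rate)
    }
  }
  hoppable <- state$fronts[state$active & occ[nxt(state$fronts)] == 0L]
  add("hop", hoppable, params$nu)
  pair_front <- which(occ == 0L & occ[prv(seq_len(L))] == 0L)
  add("attach", pair_front, params$omega_A)
  add("detach_spontaneous", state$fronts, params$omega_D)
  theta_elig <- if (facilitated_variant == "kick_off") {
    state$fronts[occ[prv(prv(state$fronts))] == 1L]
  } else {
    state$fronts[occ[nxt(state$fronts)] == 2L]
  }
  add("detach_facilitated", theta_elig, params$theta)
  if (!is.null(pausing) && pausing$enabled) {
    add("inactivate", state$fronts[state$active], pausing$r_inactivation)
    add("activate", state$fronts[!state$active], pausing$r_activation)
  }
  if (length(rows) == 0) {
    return(tibble::tibble(channel = character(), site = integer(),
                          rate = numeric()))
  }
  dplyr::bind_rows(rows)
}
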