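#' Exact stationary solution of the master equation on a small ring
#'
#' Enumerates every configuration of dimers (optionally with per-motor
#' activity flags) reachable from an initial configuration, assembles the
#' full generator of the continuous-time Markov chain, and solves the
#' stationary linear system exactly. Serves as the independent oracle for
#' the Gillespie simulator on lattices small enough to enumerate.
#'
#' @param params A [model_params()].
#' @param pausing A [pausing_params()] or `NULL`.
#' @param L Ring length; the state space must stay enumerable (L <= 8 with
#'   pausing, a little more without).
#' @param initial A [lattice_state()] fixing the communicating class to
#'   explore; defaults to the empty lattice.
#' @param facilitated_variant As in [simulate_lattice()].
#' @return A list of class `"lattice_oracle"`: `states` (tibble of
#'   configuration keys, motor counts and stationary probabilities),
#'   `rho`, `j` (per bond per s), `facilitated_share` (fraction of
#'   detachment flux through the facilitated channel), `n_states`.
#' @export
#' @examples
#' or <- exact_stationary(kinesin1_params(c = 50), L = 6)
#' or$rho
exact_stationary <- function(params, pausing = NULL, L = 6,
                             initial = lattice_state(L),
                             facilitated_variant = c("rear_bounce_off",
                                                     "kick_off")) {
  stopifnot(inherits(params, "model_params"))
  facilitated_variant <- match.arg(facilitated_variant)
  pausing_on <- !is.null(pausing) && pausing$enabled
  if (L > 10 || (pausing_on && L > 8)) {
    abort("state space too large to enumerate exactly")
  }

  key_of <- function(st) {
    o <- order(st$fronts)
    paste(paste(st$fronts[o], collapse = ","),
          paste(as.integer(st$active[o]), collapse = ""), sep = ";")
  }
  apply_event <- function(st, channel, site) {
    fronts <- st$fronts; active <- st$active
    i <- match(site, fronts)
    switch(channel,
      hop = { fronts[i] <- site %% L + 1L },
      attach = { fronts <- c(fronts, site); active <- c(active, TRUE) },
      detach_spontaneous = ,
      detach_facilitated = { fronts <- fronts[-i]; active <- active[-i] },
      inactivate = { active[i] <- FALSE },
      activate = { active[i] <- TRUE }
    )
    lattice_state(L, fronts, active)
  }

  index <- new.env(parent = emptyenv())
  states <- list()
  queue <- list(initial)
  assign(key_of(initial), 1L, envir = index)
  states[[1]] <- initial
  trans <- list()
  head_i <- 1L
  while (head_i <= length(states)) {
    st <- states[[head_i]]
    ev <- enumerate_event_rates(st, params, pausing, facilitated_variant)
    if (nrow(ev)) {
      for (r in seq_len(nrow(ev))) {
        new_st <- apply_event(st, ev$channel[r], ev$site[r])
        k <- key_of(new_st)
        j <- mget(k, envir = index, ifnotfound = NA)[[1]]
        if (is.na(j)) {
          states[[length(states) + 1]] <- new_st
          j <- length(states)
          assign(k, j, envir = index)
        }
        trans[[length(trans) + 1]] <- c(head_i, j, ev$rate[r],
                                        ev$channel[r] == "hop",
                                        ev$channel[r] == "detach_facilitated",
                                        ev$channel[r] == "detach_spontaneous")
      }
    }
    head_i <- head_i + 1L
  }
  n <- length(states)
  Q <- matrix(0, n, n)
  tr <- do.call(rbind, trans)
  if (!is.null(tr)) {
    for (r in seq_len(nrow(tr))) {
      Q[tr[r, 1], tr[r, 2]] <- Q[tr[r, 1], tr[r, 2]] + tr[r, 3]
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  # stationary distribution: pi Q = 0, sum(pi) = 1 (least squares handles
  # the reducible cases restricted to the reachable class)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat <- pi_hat / sum(pi_hat)

  n_mot <- vapply(states, function(s) length(s$fronts), integer(1))
  n_hop <- vapply(states, function(s) {
    sum(s$active & s$occ[s$fronts %% L + 1L] == 0L)
  }, numeric(1))
  n_fac <- vapply(states, function(s) {
    if (facilitated_variant == "kick_off") {
      sum(s$occ[((s$fronts - 3L) %% L) + 1L] == 1L)
    } else {
      sum(s$occ[s$fronts %% L + 1L] == 2L)
    }
  }, numeric(1))
  fac_flux <- params$theta * sum(pi_hat * n_fac)
  spo_flux <- params$omega_D * sum(pi_hat * n_mot)
  structure(
    list(
      states = tibble::tibble(
        key = vapply(states, key_of, character(1)),
        n_motors = n_mot, prob = pi_hat),
      rho = sum(pi_hat * n_mot) / L,
      j = params$nu * sum(pi_hat * n_hop) / L,
      facilitated_share = if (fac_flux + spo_flux > 0) {
        fac_flux / (fac_flux + spo_flux)
      } else NA_real_,
      n_states = n, L = L),
    class = "lattice_oracle"
  )
}

#' @export
print.lattice_oracle <- function(x, ...) {
  cat(sprintf(
    "<lattice_oracle> L = %d, %d states; rho = %.6f, j = %.6f /bond/s\n",
    x$L, x$n_states, x$rho, x$j))
  invisible(x)
}
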