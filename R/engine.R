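# R interface to the event-driven dynamics core.

#' Run event-driven dynamics
#'
#' Executes discontinuity events (hard-core collisions, well crossings, bond
#' vibrations, hydrogen-bond attempts, auxiliary-wall bounces, thermostat
#' ghost collisions) in time order until the executed pair-event budget or a
#' time limit is reached. Temperature follows a linear-in-event-count cooling
#' ramp from `t_start` to `t_final` over `cool_events` events, applied
#' through Andersen-style ghost collisions that resample one sphere's
#' velocity from the Maxwell-Boltzmann distribution at the instantaneous
#' temperature. Ghost and bookkeeping events are not counted against the
#' budget. Randomness comes from R's RNG: use `set.seed()` for
#' reproducibility.
#'
#' @param state a `prime_state` (positions, velocities, box, clock)
#' @param topology a `prime_topology`, or `NULL` when `tables` is given
#' @param ff a `prime_forcefield`, or `NULL` when `tables` is given
#' @param budget number of executed pair events to run (0 = no-op)
#' @param tables precomputed [build_interaction_tables()] output
#' @param t_start,t_final,cool_events cooling schedule (reduced temperature
#'   against executed pair-event count); set `t_start = t_final` for an
#'   isothermal run
#' @param max_time stop at this internal clock time (0 = no limit)
#' @param thermostat logical; disable for exactly energy-conserving dynamics
#' @param ghost_rate thermostat ghost-collision rate per sphere per internal
#'   time unit
#' @param sample_interval,energy_interval internal-time spacing of trajectory
#'   frames and energy samples (0 disables)
#' @param registry optional two-column matrix of existing hydrogen bonds
#'   (donor NH sphere id, acceptor CO sphere id), e.g. from a checkpoint
#' @param pair_events_done events already executed (restart bookkeeping)
#' @param next_ghost_time scheduled time of the next ghost collision
#'   (restart bookkeeping; `-1` draws afresh)
#' @param record_events,record_event_velocities log every executed event
#'   (and, for small systems, full velocity snapshots) for diagnostics
#' @return a `prime_run` list: final `state`, `frames`, `energy` series,
#'   hydrogen-bond `registry`, event `counters`, and restart bookkeeping
#' @export
dmd_run <- function(state, topology = NULL, ff = NULL, budget = 1e6,
                    tables = build_interaction_tables(topology, ff),
                    t_start = NULL, t_final = NULL,
                    cool_events = 0, max_time = 0,
                    thermostat = TRUE, ghost_rate = 0.1,
                    sample_interval = 0, energy_interval = 0,
                    registry = NULL, pair_events_done = 0,
                    next_ghost_time = -1,
                    record_events = FALSE, record_event_velocities = FALSE) {
  stopifnot(inherits(state, "prime_state"))
  if (is.null(t_start)) t_start <- if (is.null(state$tstar)) 0 else state$tstar
  if (is.null(t_final)) t_final <- t_start
  rsi <- tables$rsi
  rsi[is.na(rsi)] <- 0L
  hb_init <- if (is.null(registry) || nrow(registry) == 0) {
    matrix(integer(0), 0, 2)
  } else {
    matrix(as.integer(registry[, 1:2]), ncol = 2)
  }
  res <- dmd_run_cpp(state$pos, state$vel, state$box, state$time,
                     tables$type, tables$d1, tables$d2,
                     tables$din, tables$dout, tables$ein, tables$eout,
                     tables$mass, tables$role, tables$res_global, rsi,
                     tables$res_chain,
                     tables$hb_cutoffs, tables$hb_well, hb_init,
                     t_start, t_final, cool_events, pair_events_done,
                     budget, max_time,
                     thermostat, ghost_rate, next_ghost_time,
                     sample_interval, energy_interval,
                     record_events, record_event_velocities)
  out_state <- structure(list(pos = res$pos, vel = res$vel, box = state$box,
                              time = res$time, tstar = res$tstar),
                         class = "prime_state")
  structure(list(state = out_state, frames = res$frames,
                 energy = res$energy, registry = res$registry,
                 hb_formations = res$hb_formations,
                 counters = res$counters, events = res$events,
                 pe = res$pe, ke = res$ke,
                 pair_events_total = res$pair_events_total,
                 next_ghost_time = res$next_ghost_time,
                 tables = tables),
            class = "prime_run")
}

#' Total interaction energy of a configuration
#'
#' Recomputes, from scratch, the sum of occupied side-chain well energies
#' plus minus one eps_HB per registered hydrogen bond. Pure hard-core
#' contacts contribute nothing. This is an independent bookkeeping path from
#' the engine's incremental energy and is used to cross-check it.
#'
#' @param state a `prime_state`
#' @param topology,ff system description (or pass precomputed `tables`)
#' @param registry hydrogen-bond matrix (donor NH id, acceptor CO id) or
#'   `NULL` for none
#' @param tables optional precomputed interaction tables
#' @return total interaction energy in eps_HB
#' @export
total_energy <- function(state, topology = NULL, ff = NULL, registry = NULL,
                         tables = build_interaction_tables(topology, ff)) {
  dm <- pair_min_image_dist(state$pos, state$box)
  ut <- upper.tri(dm)
  well <- tables$type == 3L & ut
  e <- 0
  if (any(well)) {
    d <- dm[well]
    e <- sum(ifelse(d < tables$din[well], tables$ein[well],
                    ifelse(d < tables$dout[well], tables$eout[well], 0)))
  }
  nhb <- if (is.null(registry)) 0 else nrow(registry)
  e - nhb
}

#' Convert internal simulation time to reduced time t*
#'
#' t* = t / sigma * sqrt(kB T / m) with sigma and m the diameter and mass of
#' the NH backbone sphere.
#'
#' @param t internal time (or vector)
#' @param tstar reduced temperature T*
#' @param ff a `prime_forcefield` (supplies sigma and the NH mass)
#' @return reduced time t*
#' @export
reduced_time <- function(t, tstar, ff) {
  stopifnot(tstar > 0)
  t / ff$sigma * sqrt(tstar / ff$m_nh)
}

#' Resample one sphere's velocity from the Maxwell-Boltzmann distribution
#'
#' The elementary thermostat move: a ghost collision replaces the sphere's
#' velocity with a fresh Maxwell-Boltzmann draw at reduced temperature
#' `tstar`, so the mean kinetic energy per sphere relaxes to (3/2) kB T*.
#'
#' @param state a `prime_state`
#' @param sphere sphere index
#' @param mass sphere mass
#' @param tstar reduced temperature (> 0)
#' @return the state with the sphere's velocity resampled
#' @export
ghost_collision <- function(state, sphere, mass, tstar) {
  if (!is.numeric(tstar) || tstar <= 0) stop("tstar must be positive")
  state$vel[sphere, ] <- rnorm(3) * sqrt(tstar / mass)
  state
}

#' Predict the next discontinuity event for an isolated pair
#'
#' Analytic two-body prediction: the earliest positive root of
#' |r + v t| = d over the pair's discontinuity surfaces, under the
#' minimum-image convention. Pure R; independent of the C++ engine's
#' root-finding (used to cross-validate it).
#'
#' @param state a `prime_state`
#' @param i,j sphere indices
#' @param surfaces data frame with columns `d` (surface distance) and
#'   `direction` (`"in"` for approaches from outside, `"out"` for escapes
#'   from inside)
#' @return a list with `time` (absolute) and `surface` (row index), or
#'   `NULL` when no surface is reached
#' @export
predict_pair_event <- function(state, i, j, surfaces) {
  dr <- state$pos[i, ] - state$pos[j, ]
  L <- state$box
  dr <- dr - L * round(dr / L)
  dv <- state$vel[i, ] - state$vel[j, ]
  r2 <- sum(dr^2); b <- sum(dr * dv); v2 <- sum(dv^2)
  if (v2 < 1e-300) return(NULL)
  best <- Inf; best_s <- NA_integer_
  for (s in seq_len(nrow(surfaces))) {
    d <- surfaces$d[s]
    disc <- b^2 - v2 * (r2 - d^2)
    t <- if (identical(surfaces$direction[s], "in")) {
      if (b < 0 && disc > 0 && r2 > d^2) (-b - sqrt(disc)) / v2 else NA
    } else {
      if (r2 < d^2) (-b + sqrt(max(disc, 0))) / v2 else NA
    }
    if (!is.na(t) && t >= 0 && t < best) { best <- t; best_s <- s }
  }
  if (!is.finite(best)) return(NULL)
  list(time = state$time + best, surface = best_s)
}

#' Apply a pair impulse at a discontinuity surface
#'
#' Standard square-well impulse rule along the line of centres: a reflection
#' (hard wall) or a crossing with potential-energy step `delta_u`. A
#' crossing succeeds only when the radial kinetic energy exceeds `delta_u`;
#' otherwise the pair reflects. Momentum is conserved exactly; kinetic
#' energy changes by exactly `-delta_u` on a successful crossing.
#'
#' @param state a `prime_state`
#' @param i,j sphere indices
#' @param mi,mj masses
#' @param delta_u potential-energy step across the surface (0 = hard wall)
#' @param reflect force a reflection regardless of `delta_u`
#' @return list with the updated `state` and `crossed` flag
#' @export
apply_pair_impulse <- function(state, i, j, mi, mj, delta_u = 0,
                               reflect = FALSE) {
  dr <- state$pos[i, ] - state$pos[j, ]
  dr <- dr - state$box * round(dr / state$box)
  nh <- dr / sqrt(sum(dr^2))
  vr <- sum((state$vel[i, ] - state$vel[j, ]) * nh)
  mu <- mi * mj / (mi + mj)
  if (reflect || 0.5 * mu * vr^2 <= delta_u) {
    vr_new <- -vr; crossed <- FALSE
  } else {
    vr_new <- sign(vr) * sqrt(vr^2 - 2 * delta_u / mu); crossed <- TRUE
  }
  dp <- mu * (vr_new - vr)
  state$vel[i, ] <- state$vel[i, ] + dp * nh / mi
  state$vel[j, ] <- state$vel[j, ] - dp * nh / mj
  list(state = state, crossed = crossed)
}

#' @export
print.prime_run <- function(x, ...) {
  cat("<prime_run> ", format(x$counters[["pair_events"]], big.mark = ","),
      " pair events to t = ", signif(x$state$time, 6),
      ", T* = ", signif(x$state$tstar, 4),
      ", E = ", signif(x$pe, 6), " eps_HB, ",
      nrow(x$registry), " H-bond(s), ", length(x$frames), " frame(s)\n",
      sep = "")
  invisible(x)
}
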