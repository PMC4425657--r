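# Programmatic test systems: toy sphere pairs with hand-set interactions,
# idealized beta-sheets, and non-contacting random-coil boxes.

#' Hand-built interaction tables for toy sphere systems
#'
#' Builds the same table structure as [build_interaction_tables()] for a
#' small set of free spheres with explicitly chosen pair interactions;
#' used for engine validation against analytic two-body results.
#'
#' @param mass,radius per-sphere vectors
#' @param type,d1,d2,din,dout,ein,eout pair matrices (defaults: pure hard
#'   spheres at contact)
#' @return an interaction-table list
#' @export
toy_tables <- function(mass, radius = rep(1, length(mass)),
                       type = NULL, d1 = NULL, d2 = NULL,
                       din = NULL, dout = NULL, ein = NULL, eout = NULL) {
  n <- length(mass)
  zero <- matrix(0, n, n)
  if (is.null(type)) { type <- matrix(2L, n, n); diag(type) <- 0L }
  if (is.null(d1)) d1 <- outer(radius, radius, "+")
  if (is.null(d2)) d2 <- zero
  if (is.null(din)) din <- zero
  if (is.null(dout)) dout <- zero
  if (is.null(ein)) ein <- zero
  if (is.null(eout)) eout <- zero
  list(type = type, d1 = d1, d2 = d2, din = din, dout = dout,
       ein = ein, eout = eout, radius = radius, mass = mass,
       role = rep(4L, n), chain = seq_len(n), res_global = seq_len(n),
       res_local = seq_len(n),
       rsi = matrix(0L, n, 4), res_chain = seq_len(n),
       res_local_of = seq_len(n),
       hb_cutoffs = c(5.10, 4.54, 4.96, 4.58), hb_well = 4.2,
       max_interaction = max(d1, d2, din, dout))
}

#' Two-sphere square-well system
#'
#' A pair of spheres interacting through a single square well (represented
#' as a double well with equal shell energies), the elementary system for
#' checking event kinematics, energy conservation and the bound-state
#' Boltzmann statistics.
#'
#' @param d_core hard-core contact distance
#' @param d_well well diameter
#' @param eps well depth (positive = attractive)
#' @param mass length-2 masses
#' @param box box edge
#' @param r0 initial separation (along x)
#' @param v0 initial relative speed (closing when positive)
#' @return list with `state` and `tables`
#' @export
fixture_well_pair <- function(d_core = 3, d_well = 5, eps = 1,
                              mass = c(1, 1), box = 30, r0 = 8, v0 = 1) {
  two <- function(v) matrix(c(v, v), 2, 2) - diag(2) * v
  tab <- toy_tables(mass, radius = rep(d_core / 2, 2),
                    type = matrix(c(0L, 3L, 3L, 0L), 2, 2),
                    d1 = two(d_core),
                    din = two((d_core + d_well) / 2), dout = two(d_well),
                    ein = two(-eps), eout = two(-eps))
  pos <- rbind(c(box / 2 - r0 / 2, box / 2, box / 2),
               c(box / 2 + r0 / 2, box / 2, box / 2))
  vel <- rbind(c(v0 / 2, 0, 0), c(-v0 / 2, 0, 0))
  state <- structure(list(pos = pos, vel = vel, box = box, time = 0,
                          tstar = NULL), class = "prime_state")
  list(state = state, tables = tab)
}

#' Two-sphere bonded dimer
#'
#' A pair held in a hard distance window; all its events are elastic wall
#' reflections, so total energy is exactly conserved.
#'
#' @param len nominal bond length; `tol` fractional window half-width
#' @inheritParams fixture_well_pair
#' @export
fixture_bonded_dimer <- function(len = 1.5, tol = 0.02375, mass = c(1, 2),
                                 box = 30, v0 = 0.7) {
  two <- function(v) matrix(c(v, v), 2, 2) - diag(2) * v
  tab <- toy_tables(mass, radius = rep(len / 2, 2),
                    type = matrix(c(0L, 1L, 1L, 0L), 2, 2),
                    d1 = two(len * (1 - tol)), d2 = two(len * (1 + tol)))
  pos <- rbind(c(box / 2 - len / 2, box / 2, box / 2),
               c(box / 2 + len / 2, box / 2, box / 2))
  vel <- rbind(c(v0, 0.1, 0), c(-v0 / 2, -0.05, 0.2))
  state <- structure(list(pos = pos, vel = vel, box = box, time = 0,
                          tstar = NULL), class = "prime_state")
  list(state = state, tables = tab)
}

#' Idealized in-register parallel beta-sheet
#'
#' Builds `n_strands` copies of a chain in uniform beta-region dihedrals
#' and finds, by deterministic optimisation, the inter-strand translation
#' that satisfies the hydrogen-bond well distance and all four auxiliary
#' parallel-preference cutoffs for every interior in-register NH-CO pair
#' while keeping hard cores untouched. Returns the system together with the
#' in-register hydrogen-bond list of interior residues.
#'
#' @param sequence one-letter string
#' @param ff a `prime_forcefield`
#' @param n_strands number of strands
#' @param phi,psi uniform backbone dihedrals (degrees, beta region)
#' @param box box edge for the returned state
#' @param register acceptor offset: donor residue i bonds acceptor residue
#'   i + register on the neighbouring strand
#' @return list with `state`, `topology` (replicated), `bonds` (donor NH
#'   id, acceptor CO id), `violation` (residual constraint violation, ~0)
#' @export
fixture_parallel_sheet <- function(sequence, ff, n_strands = 2,
                                   phi = -120, psi = 130, box = 200,
                                   register = 0) {
  topo1 <- build_chain(sequence, ff)
  nres <- topo1$n_residues
  stopifnot(nres >= 4)
  systop <- replicate_topology(topo1, n_strands)
  tab <- build_interaction_tables(systop, ff)
  rsi1 <- residue_sphere_index(topo1)
  ns <- nrow(topo1$spheres)
  cut <- hbond_cutoffs(ff, "parallel_preference")$cutoffs
  well <- ff$hbond$well_diameter
  margin <- 0.97
  donors <- seq(max(2, 1 - register), min(nres, nres - register - 1))

  build <- function(ph, ps) chain_coordinates(sequence, rep(ph, nres),
                                              rep(ps, nres), ff$geometry)
  penalty <- function(par) {
    ph <- par[4]; ps <- par[5]
    # keep the dihedrals strictly inside the beta region (off the +/-180 seam)
    p <- 10 * sum(pmax(0, c(ph + 50, -178 - ph, 50 - ps, ps - 178))^2)
    xyz1 <- build(ph, ps)
    xb <- sweep(xyz1, 2, par[1:3], "+")
    for (i in donors) {
      j <- i + register
      lim <- c(well, cut) * margin
      d <- c(
        dist3(xb[rsi1[i, "NH"], ], xyz1[rsi1[j, "CO"], ]),
        dist3(xb[rsi1[i, "NH"], ], xyz1[rsi1[j, "CA"], ]),
        dist3(xb[rsi1[i, "NH"], ], xyz1[rsi1[j + 1, "NH"], ]),
        dist3(xyz1[rsi1[j, "CO"], ], xb[rsi1[i, "CA"], ]),
        dist3(xyz1[rsi1[j, "CO"], ], xb[rsi1[i - 1, "CO"], ]))
      p <- p + sum(pmax(0, d - lim)^2)
    }
    # hard-core / squeeze clearance between the strands
    for (a in seq_len(ns)) {
      d <- sqrt(colSums((t(xyz1) - (xb[a, ]))^2))
      lim <- tab$d1[ns + a, seq_len(ns)]
      p <- p + sum(pmax(0, lim - d)^2)
    }
    p
  }
  best <- list(value = Inf)
  for (start in list(c(0, 4.8, 0, phi, psi), c(0, 0, 4.8, phi, psi),
                     c(4.8, 0, 0, phi, psi), c(0, -4.8, 0, phi, psi))) {
    o <- optim(start, penalty, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, penalty, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (o$value < best$value) best <- o
    if (best$value < 1e-12) break
  }
  t_vec <- best$par[1:3]
  xyz1 <- build(best$par[4], best$par[5])

  coords <- lapply(seq_len(n_strands) - 1, function(k)
    sweep(xyz1, 2, k * t_vec, "+"))
  pos <- do.call(rbind, coords)
  pos <- sweep(pos, 2, colMeans(pos) - box / 2, "-")
  state <- structure(list(pos = pos, vel = matrix(0, nrow(pos), 3),
                          box = box, time = 0, tstar = NULL),
                     class = "prime_state")
  bonds <- NULL
  for (s in seq_len(n_strands - 1)) {
    off_d <- s * ns; off_a <- (s - 1) * ns
    for (i in donors) {
      bonds <- rbind(bonds, c(rsi1[i, "NH"] + off_d,
                              rsi1[i + register, "CO"] + off_a))
    }
  }
  list(state = state, topology = systop, bonds = bonds,
       violation = best$value, translation = t_vec)
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Non-contacting random-coil box (the simulation's initial condition)
#'
#' Convenience wrapper: builds the chain, generates the self-avoiding
#' random-coil configuration and returns state, topology and tables.
#'
#' @param sequence one-letter string
#' @param ff a `prime_forcefield`
#' @param config a `prime_config`
#' @export
fixture_random_coils <- function(sequence = AB17_42, ff = load_forcefield(),
                                 config = simulation_config()) {
  topo1 <- build_chain(sequence, ff)
  gen <- generate_initial_configuration(topo1, ff, config)
  gen$tables <- build_interaction_tables(gen$topology, ff)
  gen
}
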