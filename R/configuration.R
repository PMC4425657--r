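# Initial configurations: self-avoiding random coils in a periodic box,
# chirality checks, geometry validation.

#' Simulation configuration
#'
#' Bundles the run conditions: chain count, cubic box edge, temperature
#' schedule and event budget. The molar concentration implied by `n_chains`
#' and `box_length` is derived, never asserted.
#'
#' @param n_chains number of peptide chains
#' @param box_length cubic box edge (Angstrom)
#' @param t_start starting reduced temperature of the cooling stage
#' @param t_final reduced temperature after cooling
#' @param cool_events number of executed pair events over which temperature
#'   is ramped linearly from `t_start` to `t_final`
#' @param budget total executed pair-event budget of a run
#' @param seed master seed (integer) used for placement, thermostat and
#'   sampling streams
#' @return a `prime_config` list
#' @export
simulation_config <- function(n_chains = 8L, box_length = 160,
                              t_start = 0.5, t_final = 0.20,
                              cool_events = 1e6, budget = 1e7,
                              seed = 1L) {
  stopifnot(n_chains >= 1, box_length > 0, t_start >= t_final, t_final > 0)
  structure(list(n_chains = as.integer(n_chains), box_length = box_length,
                 t_start = t_start, t_final = t_final,
                 cool_events = cool_events, budget = budget,
                 seed = as.integer(seed)),
            class = "prime_config")
}

#' Molar concentration implied by a configuration
#' @param config a `prime_config`
#' @return concentration in mM
#' @export
concentration_mM <- function(config) {
  avogadro <- 6.02214076e23
  v_litre <- (config$box_length * 1e-9)^3  # 1 A = 1e-9 dm; dm^3 = L
  config$n_chains / avogadro / v_litre * 1000  # mol/L -> mM
}

#' Generate an overlap-free random-coil configuration
#'
#' Grows each chain as a self-avoiding random coil (randomized backbone
#' dihedrals, rejection against hard-core and squeeze violations, whole-chain
#' restart on persistent failure), then places the chains in the periodic box
#' with random orientations so that no inter-chain sphere pair is closer than
#' the largest interaction diameter: the initial state has no inter-peptide
#' contacts. Velocities are drawn from the Maxwell-Boltzmann distribution at
#' the schedule's starting temperature and the centre-of-mass drift removed.
#' Deterministic for a fixed seed.
#'
#' @param topology single-chain `prime_topology`
#' @param ff a `prime_forcefield`
#' @param config a `prime_config`
#' @param clearance extra inter-chain clearance (Angstrom) beyond the largest
#'   interaction diameter
#' @param max_chain_restarts,max_place_attempts retry bounds
#' @return a list with `state` (a `prime_state`) and `topology` (the
#'   replicated system topology)
#' @export
generate_initial_configuration <- function(topology, ff, config,
                                           clearance = 1.0,
                                           max_chain_restarts = 200,
                                           max_place_attempts = 2000) {
  stopifnot(inherits(topology, "prime_topology"), topology$n_chains == 1)
  set.seed(config$seed)
  systop <- replicate_topology(topology, config$n_chains)
  tab1 <- build_interaction_tables(topology, ff)
  L <- config$box_length

  coords <- lapply(seq_len(config$n_chains), function(c)
    grow_chain(topology, ff, tab1, max_chain_restarts))

  min_sep <- tab1$max_interaction + clearance
  extent <- vapply(coords, function(x) max(dist_range(x)), numeric(1))
  if (min(L / 2) < max(extent) / 2 + min_sep)
    warning("box is small relative to chain extent; placement may fail")

  placed <- list()
  for (c in seq_along(coords)) {
    ok <- FALSE
    for (try in seq_len(max_place_attempts)) {
      x <- sweep(coords[[c]], 2, colMeans(coords[[c]]))
      x <- x %*% random_rotation()
      x <- sweep(x, 2, runif(3, 0, L), "+")
      if (all_clear(x, placed, L, min_sep)) { ok <- TRUE; break }
    }
    if (!ok) stop("placement failed: could not find a position for chain ", c,
                  " with inter-chain separation > ", round(min_sep, 2),
                  " A in a box of ", L, " A")
    placed[[c]] <- x
  }
  pos <- do.call(rbind, placed)
  n <- nrow(pos)
  mass <- systop$spheres$mass
  vel <- matrix(rnorm(3 * n), n, 3) * sqrt(config$t_start / mass)
  vel <- sweep(vel, 2, colSums(vel * mass) / sum(mass))
  state <- structure(list(pos = pos, vel = vel, box = L, time = 0,
                          tstar = config$t_start),
                     class = "prime_state")
  list(state = state, topology = systop)
}

dist_range <- function(x) {
  apply(x, 2, function(col) diff(range(col)))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

all_clear <- function(x, placed, L, min_sep) {
  for (p in placed) {
    if (min_image_min_dist(x, p, L) <= min_sep) return(FALSE)
  }
  TRUE
}

min_image_min_dist <- function(a, b, L) {
  md <- Inf
  for (k in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[k, ])
    d <- d - L * round(d / L)
    md <- min(md, sqrt(min(rowSums(d^2))))
    if (md == 0) return(0)
  }
  md
}

#' Grow one self-avoiding random coil
#' @keywords internal
grow_chain <- function(topology, ff, tab, max_restarts,
                       per_residue_retries = 80) {
  nres <- topology$n_residues
  seq_letters <- strsplit(topology$sequence, "")[[1]]
  for (restart in seq_len(max_restarts)) {
    phi <- runif(nres, -180, 180)
    psi <- runif(nres, -180, 180)
    x <- try_grow(topology, ff, tab, phi, psi, per_residue_retries)
    if (!is.null(x)) return(x)
  }
  stop("random-coil growth failed after ", max_restarts,
       " whole-chain restarts (persistent hard-core or squeeze violations)")
}

try_grow <- function(topology, ff, tab, phi, psi, retries) {
  nres <- topology$n_residues
  rsi <- residue_sphere_index(topology)
  for (k in seq_len(nres)) {
    ok <- FALSE
    for (r in seq_len(retries)) {
      x <- chain_coordinates(topology$sequence, phi, psi, ff$geometry)
      ids_new <- stats::na.omit(as.integer(rsi[k, ]))
      ids_old <- if (k == 1) integer(0) else stats::na.omit(as.integer(rsi[seq_len(k - 1), ]))
      if (residues_clear(x, ids_new, ids_old, tab)) { ok <- TRUE; break }
      # residue k's spheres are set by phi[k] and psi[k-1]; resample both
      phi[k] <- runif(1, -180, 180)
      if (k > 1) psi[k - 1] <- runif(1, -180, 180)
    }
    if (!ok) return(NULL)
  }
  chain_coordinates(topology$sequence, phi, psi, ff$geometry)
}

residues_clear <- function(x, ids_new, ids_old, tab) {
  for (i in ids_new) {
    for (j in c(ids_old, ids_new[ids_new < i])) {
      tt <- tab$type[i, j]
      if (tt == 0L || tt == 1L) next
      d <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (d < tab$d1[i, j]) return(FALSE)
    }
  }
  TRUE
}

#' Handedness of one residue's side-sphere arrangement
#'
#' Sign of the scalar triple product of the vectors from CaH to NH, CO and
#' the side sphere: positive is the package's L convention, negative D;
#' glycine (no side sphere) is achiral. Negating all coordinates flips the
#' label.
#'
#' @param state a `prime_state`
#' @param topology a `prime_topology`
#' @param residue global residue index
#' @return `"L"`, `"D"` or `"achiral"`
#' @export
chirality_sign <- function(state, topology, residue) {
  rsi <- residue_sphere_index(topology)
  ids <- rsi[residue, ]
  if (is.na(ids[["R"]])) return("achiral")
  p <- state$pos
  a <- p[ids[["NH"]], ] - p[ids[["CA"]], ]
  b <- p[ids[["CO"]], ] - p[ids[["CA"]], ]
  r <- p[ids[["R"]], ] - p[ids[["CA"]], ]
  s <- sum(pracma_cross(a, b) * r)
  if (s > 0) "L" else "D"
}

#' Validate a configuration against the model's geometric constraints
#'
#' Report-only check of every bond window, squeeze distance, hard core and
#' residue chirality. Distances use the minimum-image convention.
#'
#' @param state a `prime_state`
#' @param topology a `prime_topology`
#' @param ff a `prime_forcefield`
#' @param tables optional precomputed [build_interaction_tables()] result
#' @return a data frame of violations (zero rows on a valid state) with
#'   columns `kind`, `i`, `j`, `value`, `limit`
#' @export
validate_geometry <- function(state, topology, ff,
                              tables = build_interaction_tables(topology, ff)) {
  pos <- state$pos; L <- state$box
  n <- nrow(pos)
  dm <- pair_min_image_dist(pos, L)
  viol <- list()
  add <- function(kind, i, j, value, limit) {
    viol[[length(viol) + 1]] <<- data.frame(kind = kind, i = i, j = j,
                                            value = value, limit = limit)
  }
  ut <- upper.tri(dm)
  bnd <- tables$type == 1L & ut
  if (any(bnd)) {
    idx <- which(bnd, arr.ind = TRUE)
    d <- dm[bnd]
    low <- d < tables$d1[bnd] - 1e-9
    high <- d > tables$d2[bnd] + 1e-9
    if (any(low)) add("bond_short", idx[low, 1], idx[low, 2], d[low], tables$d1[bnd][low])
    if (any(high)) add("bond_long", idx[high, 1], idx[high, 2], d[high], tables$d2[bnd][high])
  }
  hard <- (tables$type %in% c(2L, 3L, 4L)) & ut
  dim(hard) <- dim(ut)
  if (any(hard)) {
    idx <- which(hard, arr.ind = TRUE)
    d <- dm[hard]
    bad <- d < tables$d1[hard] - 1e-9
    if (any(bad)) add("overlap", idx[bad, 1], idx[bad, 2], d[bad], tables$d1[hard][bad])
  }
  for (g in seq_len(max(topology$spheres$residue))) {
    if (chirality_sign(state, topology, g) == "D")
      add("chirality_D", g, NA_integer_, NA_real_, NA_real_)
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(kind = character(0), i = integer(0), j = integer(0),
                  value = numeric(0), limit = numeric(0))
}

#' All-pairs minimum-image distance matrix
#' @keywords internal
pair_min_image_dist <- function(pos, L) {
  n <- nrow(pos)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(pos[, k], pos[, k], "-")
    dk <- dk - L * round(dk / L)
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}
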