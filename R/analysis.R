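# Trajectory statistics: dihedrals, secondary structure, strand-content
# profiles, solvent accessibility, maximum-population energy statistics,
# salt bridges and chain-shape classification.

frame_pos <- function(frame) {
  if (is.matrix(frame)) frame else frame$pos
}

frame_bonds <- function(frame) {
  if (is.matrix(frame)) NULL else frame$bonds
}

#' Backbone dihedral angles
#'
#' phi(k) is the torsion CO(k-1)-NH(k)-CaH(k)-CO(k), psi(k) the torsion
#' NH(k)-CaH(k)-CO(k)-NH(k+1); both in degrees, `NA` at chain termini.
#'
#' @param frame a trajectory frame (or a bare position matrix)
#' @param topology a `prime_topology`
#' @return data frame with `residue` (global), `chain`, `phi`, `psi`
#' @export
phi_psi <- function(frame, topology) {
  pos <- frame_pos(frame)
  sp <- topology$spheres
  rsi <- residue_sphere_index(topology)
  nres_tot <- nrow(rsi)
  chain_of_res <- sp$chain[match(seq_len(nres_tot), sp$residue)]
  phi <- psi <- rep(NA_real_, nres_tot)
  for (g in seq_len(nres_tot)) {
    ok_prev <- g > 1 && chain_of_res[g - 1] == chain_of_res[g]
    ok_next <- g < nres_tot && chain_of_res[g + 1] == chain_of_res[g]
    if (ok_prev)
      phi[g] <- dihedral_angle(pos[rsi[g - 1, "CO"], ], pos[rsi[g, "NH"], ],
                               pos[rsi[g, "CA"], ], pos[rsi[g, "CO"], ])
    if (ok_next)
      psi[g] <- dihedral_angle(pos[rsi[g, "NH"], ], pos[rsi[g, "CA"], ],
                               pos[rsi[g, "CO"], ], pos[rsi[g + 1, "NH"], ])
  }
  data.frame(residue = seq_len(nres_tot), chain = chain_of_res,
             phi = phi, psi = psi)
}

wrap180 <- function(x) ((x + 180) %% 360) - 180  # to [-180, 180)

in_beta_region <- function(phi, psi) {
  phi <- wrap180(phi); psi <- wrap180(psi)
  !is.na(phi) & !is.na(psi) &
    phi >= -180 & phi <= -45 &
    ((psi >= 45 & psi < 180) | (psi >= -180 & psi <= -150))
}

in_alpha_region <- function(phi, psi) {
  phi <- wrap180(phi); psi <- wrap180(psi)
  !is.na(phi) & !is.na(psi) & phi >= -90 & phi <= -30 & psi >= -77 & psi <= -17
}

runs_at_least <- function(flag, k) {
  r <- rle(flag)
  keep <- r$values & r$lengths >= k
  inverse.rle(list(values = keep, lengths = r$lengths))
}

#' Assign secondary structure per residue
#'
#' Dihedral-plus-hydrogen-bond assignment: a residue is labelled `strand`
#' when its (phi, psi) fall in the beta region *and* it belongs to a
#' hydrogen-bond ladder (at least two consecutive residues whose NH or CO is
#' bonded to a partner strand); `helix` requires alpha-region dihedrals over
#' at least four consecutive residues supported by an intra-chain bond at
#' short range; everything else (including termini) is `coil`. A chain in
#' beta-like dihedrals with no hydrogen bonds is coil by construction, so a
#' freshly generated non-contacting random-coil system scores 0% strand.
#'
#' @param frame a trajectory frame (or bare position matrix)
#' @param topology a `prime_topology`
#' @param bonds hydrogen-bond matrix (donor NH id, acceptor CO id); if
#'   omitted, taken from the frame (empty when absent)
#' @return data frame with `residue`, `chain`, `phi`, `psi`, `ss`
#' @export
assign_secondary_structure <- function(frame, topology, bonds = NULL) {
  if (is.null(bonds)) bonds <- frame_bonds(frame)
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  dh <- phi_psi(frame, topology)
  sp <- topology$spheres
  nres_tot <- nrow(dh)
  chain_of_res <- dh$chain

  bonded <- rep(FALSE, nres_tot)       # bonded to a partner strand
  intra_short <- rep(FALSE, nres_tot)  # helix-like intra-chain bond
  if (nrow(bonds) > 0) {
    gi <- sp$residue[bonds[, 1]]
    gj <- sp$residue[bonds[, 2]]
    same <- sp$chain[bonds[, 1]] == sp$chain[bonds[, 2]]
    ladder <- !same | abs(gi - gj) >= 3
    bonded[gi[ladder]] <- TRUE
    bonded[gj[ladder]] <- TRUE
    helixish <- same & abs(gi - gj) >= 3 & abs(gi - gj) <= 5
    intra_short[gi[helixish]] <- TRUE
    intra_short[gj[helixish]] <- TRUE
  }

  ss <- rep("coil", nres_tot)
  for (ch in unique(chain_of_res)) {
    idx <- which(chain_of_res == ch)
    beta <- in_beta_region(dh$phi[idx], dh$psi[idx])
    ladder_ok <- runs_at_least(bonded[idx], 2)
    ss[idx][beta & ladder_ok] <- "strand"
    alpha <- in_alpha_region(dh$phi[idx], dh$psi[idx])
    helix_run <- runs_at_least(alpha, 4)
    # a helix run must be supported by at least one short intra-chain bond
    r <- rle(helix_run)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (s in which(r$values)) {
      seg <- idx[starts[s]:ends[s]]
      if (any(intra_short[seg])) ss[seg] <- "helix"
    }
  }
  dh$ss <- ss
  dh
}

#' Fraction of residues in beta-strand conformation
#' @param frame,topology,bonds as in [assign_secondary_structure()]
#' @return fraction in `[0, 1]`
#' @export
strand_fraction <- function(frame, topology, bonds = NULL) {
  ss <- assign_secondary_structure(frame, topology, bonds)
  mean(ss$ss == "strand")
}

#' Per-residue strand probability over a set of frames
#'
#' For each residue position along the chain, the fraction of
#' (frame, chain) observations labelled strand.
#'
#' @param frames list of trajectory frames
#' @param topology a `prime_topology`
#' @param window optional `c(tmin, tmax)` internal-time filter
#' @param first_residue number assigned to the first residue in the output
#'   (17 for the Abeta fragment)
#' @return data frame with `residue` (reported numbering) and `p_strand`
#' @export
strand_content_profile <- function(frames, topology, window = NULL,
                                   first_residue = AB_FIRST_RESIDUE) {
  if (!is.null(window)) {
    times <- vapply(frames, function(f) f$time, numeric(1))
    frames <- frames[times >= window[1] & times <= window[2]]
  }
  if (length(frames) == 0) stop("no frames in the requested window")
  nres1 <- topology$n_residues
  hits <- total <- rep(0, nres1)
  for (f in frames) {
    ss <- assign_secondary_structure(f, topology)
    posn <- ((ss$residue - 1) %% nres1) + 1
    for (k in seq_len(nres1)) {
      sel <- posn == k
      hits[k] <- hits[k] + sum(ss$ss[sel] == "strand")
      total[k] <- total[k] + sum(sel)
    }
  }
  data.frame(residue = seq_len(nres1) + first_residue - 1,
             p_strand = hits / total)
}

#' Per-residue solvent-accessible surface area
#'
#' Numerical sphere-point (Shrake-Rupley style) accessibility on the
#' four-sphere geometry: each sphere carries a fixed deterministic point set
#' on its probe-expanded surface; a point is buried when it falls inside any
#' other sphere's probe-expanded radius. Per-residue areas sum the residue's
#' spheres.
#'
#' @param frame a trajectory frame (or bare position matrix)
#' @param topology a `prime_topology`
#' @param radii per-sphere radii (default: the hard-core radii)
#' @param probe probe radius (Angstrom)
#' @param n_points points per sphere
#' @param box periodic box edge, or `NULL` for open boundaries
#' @return data frame with `residue`, `chain`, `area` (Angstrom^2)
#' @export
sasa_profile <- function(frame, topology, radii = topology$spheres$radius,
                         probe = 1.4, n_points = 960, box = NULL) {
  pos <- frame_pos(frame)
  n <- nrow(pos)
  stopifnot(length(radii) == n)
  pts <- fibonacci_sphere(n_points)
  rr <- radii + probe
  area_sphere <- numeric(n)
  cut <- outer(rr, rr, "+")
  for (i in seq_len(n)) {
    d <- sweep(pos, 2, pos[i, ])
    if (!is.null(box)) d <- d - box * round(d / box)
    nb <- which(sqrt(rowSums(d^2)) < cut[i, ] & seq_len(n) != i)
    p <- pts * rr[i]          # points about the origin (sphere i frame)
    exposed <- rep(TRUE, nrow(p))
    for (j in nb) {
      dj <- sweep(p, 2, d[j, ])
      exposed <- exposed & rowSums(dj^2) > rr[j]^2
      if (!any(exposed)) break
    }
    area_sphere[i] <- 4 * pi * rr[i]^2 * mean(exposed)
  }
  sp <- topology$spheres
  agg <- tapply(area_sphere, sp$residue, sum)
  rsi <- residue_sphere_index(topology)
  nres_tot <- nrow(rsi)
  data.frame(residue = seq_len(nres_tot),
             chain = sp$chain[match(seq_len(nres_tot), sp$residue)],
             area = as.numeric(agg[as.character(seq_len(nres_tot))]))
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Spiral points; for even `n` the set is antipodally symmetric (half the
#' points plus their negatives), so mirror-symmetric sphere arrangements
#' get exactly equal areas.
#' @keywords internal
fibonacci_sphere <- function(n) {
  half <- n %/% 2
  m <- if (2 * half == n) half else n
  k <- seq_len(m) - 0.5
  z <- 1 - 2 * k / m
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(m) - 1)
  pts <- cbind(r * cos(th), r * sin(th), z)
  if (2 * half == n) rbind(pts, -pts) else pts
}

#' Maximum-population statistic of an energy series
#'
#' Splits the reduced-time axis into windows of width `dt`; within each
#' window, `e_max` is the sampled total interaction energy whose band
#' `[e_max - halfwidth, e_max + halfwidth]` contains the most samples, and
#' `p_max` is that count divided by the window's sample count. The
#' free-energy-like transform is `-tstar * log(p_max)`. Ties in the band
#' count resolve to the lowest energy.
#'
#' @param series data frame with columns `t` (strictly increasing) and `e`
#' @param dt window width (same units as `t`; 5000 in reduced time)
#' @param halfwidth half-width of the energy band (eps_HB; default 4)
#' @param tstar reduced temperature used in the transform
#' @return data frame with `t_lo`, `t_hi`, `n`, `e_max`, `p_max`,
#'   `free_energy`
#' @export
pmax_series <- function(series, dt = 5000, halfwidth = 4, tstar = 0.20) {
  stopifnot(nrow(series) > 0, dt > 0, halfwidth > 0)
  if (is.unsorted(series$t, strictly = TRUE))
    stop("series times must be strictly increasing")
  t0 <- floor(min(series$t) / dt) * dt
  win <- floor((series$t - t0) / dt)
  out <- lapply(sort(unique(win)), function(w) {
    e <- series$e[win == w]
    n <- length(e)
    es <- sort(e)
    # two-pointer band count centred on each sample
    lo <- findInterval(es - halfwidth, es, left.open = TRUE) + 1L
    hi <- findInterval(es + halfwidth, es)
    cnt <- hi - lo + 1L
    best <- which(cnt == max(cnt))[1]     # ties -> lowest energy
    data.frame(t_lo = t0 + w * dt, t_hi = t0 + (w + 1) * dt, n = n,
               e_max = es[best], p_max = cnt[best] / n,
               free_energy = -tstar * log(cnt[best] / n))
  })
  do.call(rbind, out)
}

#' Count lysine-aspartate salt bridges in a frame
#'
#' A salt bridge is a K side sphere and a D side sphere within their outer
#' well diameter (the force field's own notion of contact), classified
#' intra- or inter-chain by the chain identities.
#'
#' @param frame a trajectory frame (or bare position matrix)
#' @param topology a `prime_topology`
#' @param ff a `prime_forcefield`
#' @param box periodic box edge for minimum-image distances, or `NULL`
#' @return named vector `c(intra = ..., inter = ...)`
#' @export
count_salt_bridges <- function(frame, topology, ff, box = NULL) {
  pos <- frame_pos(frame)
  sp <- topology$spheres
  ks <- which(sp$role == ROLE_R & sp$letter == "K")
  ds <- which(sp$role == ROLE_R & sp$letter == "D")
  if (length(ks) == 0 || length(ds) == 0) return(c(intra = 0L, inter = 0L))
  dmax <- ff$d_outer["K", "D"]
  intra <- inter <- 0L
  for (i in ks) for (j in ds) {
    d <- pos[i, ] - pos[j, ]
    if (!is.null(box)) d <- d - box * round(d / box)
    d <- sqrt(sum(d^2))
    if (d < dmax) {
      if (sp$chain[i] == sp$chain[j]) intra <- intra + 1L else inter <- inter + 1L
    }
  }
  c(intra = intra, inter = inter)
}

#' Classify the fold of one chain as U, S, triangular or disordered
#'
#' Detects turns as local reversals of the CaH-trace direction (angle
#' between the incoming and outgoing trace directions above
#' `turn_angle`), then matches the turn pattern expected for the Abeta
#' fragment: a central turn in the V24-S26 region folds the chain into a U
#' (confirmed by side-sphere contact between the two strands); an
#' additional C-terminal turn at G37-G38 gives the S shape; an additional
#' turn near G33 gives the triangular shape.
#'
#' @param frame a trajectory frame (or bare position matrix)
#' @param topology a `prime_topology`
#' @param chain chain index
#' @param ff a `prime_forcefield` (outer well diameters define contact)
#' @param turn_angle direction-reversal threshold (degrees)
#' @param first_residue reported number of the first residue (17 for Abeta)
#' @return one of `"U"`, `"S"`, `"triangular"`, `"disordered"`,
#'   `"unclassified"`
#' @export
classify_chain_shape <- function(frame, topology, chain, ff,
                                 turn_angle = 120,
                                 first_residue = AB_FIRST_RESIDUE) {
  pos <- frame_pos(frame)
  sp <- topology$spheres
  rsi <- residue_sphere_index(topology)
  res_ids <- which(sp$chain[match(seq_len(nrow(rsi)), sp$residue)] == chain)
  nres <- length(res_ids)
  if (nres < 10) return("unclassified")
  ca <- pos[rsi[res_ids, "CA"], , drop = FALSE]
  w <- 3
  turn <- rep(FALSE, nres)
  for (k in (w + 1):(nres - w)) {
    a <- ca[k, ] - ca[k - w, ]
    b <- ca[k + w, ] - ca[k, ]
    cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    turn[k] <- cosang < cos(deg2rad(turn_angle))
  }
  centers <- which(turn)
  num <- seq_len(nres) + first_residue - 1    # reported residue numbers
  in_region <- function(lo, hi) any(num[centers] >= lo & num[centers] <= hi)
  central <- in_region(23, 27)                 # V24-S26 (+/- 1)
  cterm <- in_region(36, 39)                   # G37-G38 (+/- 1)
  g33 <- in_region(32, 34)                     # near G33
  if (!central) return("disordered")
  if (g33) return("triangular")
  if (cterm) return("S")
  # U requires the C-terminal strand folded back onto the N-terminal strand
  mid <- centers[num[centers] >= 23 & num[centers] <= 27][1]
  rs <- rsi[res_ids, "R"]
  nterm_r <- rs[seq_len(mid - 2)]
  cterm_r <- rs[(mid + 2):nres]
  nterm_r <- nterm_r[!is.na(nterm_r)]
  cterm_r <- cterm_r[!is.na(cterm_r)]
  contact <- FALSE
  for (i in nterm_r) {
    for (j in cterm_r) {
      dmax <- ff$d_outer[sp$letter[i], sp$letter[j]]
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < dmax) { contact <- TRUE; break }
    }
    if (contact) break
  }
  if (contact) "U" else "disordered"
}
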