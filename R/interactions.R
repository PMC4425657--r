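# Dense per-pair interaction classification shared by the configuration
# generator, the geometry validator and the event-driven engine.
#
# Pair type codes:
#   0 none (self), 1 bonded distance window, 2 hard core,
#   3 side-chain double well, 4 hydrogen-bond capable NH-CO pair

#' Build dense pair-interaction tables for a system topology
#'
#' Classifies every sphere pair and tabulates its geometric parameters:
#' bonded pairs get a distance window, local non-bonded neighbours get
#' squeeze or reduced hard cores, side-sphere pairs get the double-well
#' parameters and donor/acceptor NH-CO pairs are marked hydrogen-bond
#' capable. The same tables drive the R-side validator and the C++ engine.
#'
#' @param topology a `prime_topology` (possibly multi-chain)
#' @param ff a `prime_forcefield`
#' @param intra_hbond_min_sep minimum sequence separation for intra-chain
#'   hydrogen bonds (default 3; `Inf` restricts hydrogen bonding to
#'   inter-chain pairs, which isolates strand-pairing statistics)
#' @return a list of matrices/vectors consumed by the engine
#' @export
build_interaction_tables <- function(topology, ff, intra_hbond_min_sep = 3) {
  sp <- topology$spheres
  n <- nrow(sp)
  role <- sp$role
  chain <- sp$chain
  resg <- sp$residue                    # global residue index
  nres1 <- topology$n_residues
  resl <- ((resg - 1L) %% nres1) + 1L   # residue index within its chain
  letter <- sp$letter
  radius <- sp$radius

  type <- matrix(2L, n, n)
  diag(type) <- 0L
  d1 <- outer(radius, radius, "+")      # default: hard core at contact
  d2 <- matrix(0, n, n)
  din <- dout <- ein <- eout <- matrix(0, n, n)

  set_sym <- function(M, i, j, v) { M[cbind(i, j)] <- v; M[cbind(j, i)] <- v; M }

  near <- ff$backbone$near_factor
  same_chain <- outer(chain, chain, "==")
  dres <- abs(outer(resl, resl, "-"))

  ## local non-bonded reductions (square masks; bonds overwrite below)
  is_bb <- role != ROLE_R
  local_bb <- same_chain & (dres <= 1) & outer(is_bb, is_bb, "&")
  d1[local_bb] <- d1[local_bb] * near
  is_r <- role == ROLE_R
  local_rbb <- same_chain & (dres <= 1) & (outer(is_r, is_bb, "&") | outer(is_bb, is_r, "&"))
  d1[local_rbb] <- d1[local_rbb] * near
  local_rr <- same_chain & (dres < 3) & outer(is_r, is_r, "&")
  d1[local_rr] <- d1[local_rr] * near

  ## squeeze distances override the local R-backbone cores
  rsi <- residue_sphere_index(topology)
  nres_tot <- nrow(rsi)
  sq <- ff$squeeze
  sq_row <- match(letter, sq$residue)   # per sphere; NA for G backbone rows ok
  res_chain <- chain[match(seq_len(nres_tot), resg)]
  res_local <- resl[match(seq_len(nres_tot), resg)]
  for (g in seq_len(nres_tot)) {
    r_id <- rsi[g, "R"]
    if (is.na(r_id)) next
    svals <- sq[match(letter[r_id], sq$residue), ]
    nb <- function(offset, col) {
      gg <- g + offset
      if (gg < 1 || gg > nres_tot) return(NULL)
      if (res_chain[gg] != res_chain[g]) return(NULL)
      id <- rsi[gg, col]
      if (is.na(id)) NULL else id
    }
    pairs <- list(
      c(nb(-1L, "CA"), svals$ca_prev), c(nb(-1L, "CO"), svals$co_prev),
      c(nb(+1L, "NH"), svals$nh_next), c(nb(+1L, "CA"), svals$ca_next))
    co_m1 <- nb(-2L, "CO")  # CO(i-1) to R(i+1) == CO two residues back
    if (!is.null(co_m1)) pairs <- c(pairs, list(c(co_m1, svals$co_prev2)))
    for (p in pairs) {
      if (length(p) == 2 && !is.na(p[1])) {
        d1 <- set_sym(d1, p[1], r_id, p[2])
      }
    }
  }

  ## side-chain double wells (different chain, or sequence separation >= 3)
  allow_well <- outer(is_r, is_r, "&") & (!same_chain | dres >= 3)
  if (any(allow_well)) {
    li <- match(letter, rownames(ff$eps))  # NA for backbone spheres
    idx <- which(allow_well & upper.tri(allow_well), arr.ind = TRUE)
    a <- li[idx[, 1]]; b <- li[idx[, 2]]
    key <- cbind(a, b)
    e <- ff$eps[key]
    kd <- (rownames(ff$eps)[a] == "K" & rownames(ff$eps)[b] == "D") |
          (rownames(ff$eps)[a] == "D" & rownames(ff$eps)[b] == "K")
    if (ff$salt_bridge$enhanced) e[kd] <- ff$salt_bridge$eps_enhanced
    type <- set_sym(type, idx[, 1], idx[, 2], 3L)
    din <- set_sym(din, idx[, 1], idx[, 2], ff$d_inner[key])
    dout <- set_sym(dout, idx[, 1], idx[, 2], ff$d_outer[key])
    ein <- set_sym(ein, idx[, 1], idx[, 2], -ff$mult_inner * e)
    eout <- set_sym(eout, idx[, 1], idx[, 2], -ff$mult_outer * e)
  }

  ## hydrogen-bond capable NH-CO pairs
  is_nh <- role == ROLE_NH
  is_co <- role == ROLE_CO
  sep_ok <- !same_chain | dres >= intra_hbond_min_sep
  # the donor residue needs a CO one back, the acceptor an NH one ahead
  has_prev_co <- rep(FALSE, n); has_next_nh <- rep(FALSE, n)
  for (g in seq_len(nres_tot)) {
    gm <- g - 1L; gp <- g + 1L
    prev_ok <- gm >= 1 && res_chain[gm] == res_chain[g] && !is.na(rsi[gm, "CO"])
    next_ok <- gp <= nres_tot && res_chain[gp] == res_chain[g] && !is.na(rsi[gp, "NH"])
    if (prev_ok) has_prev_co[rsi[g, "NH"]] <- TRUE
    if (next_ok) has_next_nh[rsi[g, "CO"]] <- TRUE
  }
  hb_mask <- (outer(is_nh & has_prev_co, is_co & has_next_nh, "&") |
              outer(is_co & has_next_nh, is_nh & has_prev_co, "&")) & sep_ok
  type[hb_mask & type == 2L] <- 4L

  ## bonded windows overwrite everything
  bd <- topology$bonds
  type <- set_sym(type, bd$i, bd$j, 1L)
  d1 <- set_sym(d1, bd$i, bd$j, bd$length * (1 - bd$tol))
  d2 <- set_sym(d2, bd$i, bd$j, bd$length * (1 + bd$tol))

  hbc <- hbond_cutoffs(ff)
  list(type = type, d1 = d1, d2 = d2,
       din = din, dout = dout, ein = ein, eout = eout,
       radius = radius, mass = sp$mass,
       role = match(role, c("NH", "CA", "CO", "R")),
       chain = chain, res_global = resg, res_local = resl,
       rsi = rsi, res_chain = res_chain, res_local_of = res_local,
       hb_cutoffs = unname(hbc$cutoffs), hb_well = hbc$well_diameter,
       max_interaction = max(dout, d2, hbc$well_diameter))
}
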