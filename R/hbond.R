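# Directional backbone hydrogen bonds: eligibility, bookkeeping,
# orientation classification. The event-time mechanics live in the engine;
# these R-side routines implement the same rules for analysis and testing.

#' Can an NH-CO pair form a hydrogen bond?
#'
#' A bond can form when the donor NH and acceptor CO are both free, the
#' sequence-separation rule passes (intra-chain bonds require at least three
#' residues between donor and acceptor; inter-chain bonds are unrestricted),
#' both auxiliary neighbour spheres exist, and all four auxiliary distances
#' (N_i-Ca_j, N_i-N_(j+1), C_j-Ca_i, C_j-C_(i-1)) are inside the active
#' cutoff set. Distances are evaluated at the moment of the call with the
#' minimum-image convention.
#'
#' @param state a `prime_state`
#' @param topology a `prime_topology`
#' @param ff a `prime_forcefield`
#' @param nh_id donor NH sphere id
#' @param co_id acceptor CO sphere id
#' @param registry hydrogen-bond matrix (donor, acceptor) or `NULL`
#' @return list with `ok` (logical) and `reason` (`"ok"` or the first
#'   failing constraint: `"donor_role"`, `"acceptor_role"`,
#'   `"donor_occupied"`, `"acceptor_occupied"`, `"separation"`,
#'   `"missing_neighbor"`, `"n_ca"`, `"n_n"`, `"c_ca"`, `"c_c"`)
#' @export
hb_can_form <- function(state, topology, ff, nh_id, co_id, registry = NULL) {
  sp <- topology$spheres
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (sp$role[nh_id] != ROLE_NH) return(fail("donor_role"))
  if (sp$role[co_id] != ROLE_CO) return(fail("acceptor_role"))
  if (!is.null(registry) && nrow(registry) > 0) {
    if (nh_id %in% registry[, 1]) return(fail("donor_occupied"))
    if (co_id %in% registry[, 2]) return(fail("acceptor_occupied"))
  }
  gi <- sp$residue[nh_id]; gj <- sp$residue[co_id]
  same_chain <- sp$chain[nh_id] == sp$chain[co_id]
  if (same_chain && abs(gi - gj) < 3) return(fail("separation"))
  rsi <- residue_sphere_index(topology)
  nres_tot <- nrow(rsi)
  chain_of_res <- sp$chain[match(seq_len(nres_tot), sp$residue)]
  ok_prev <- gi > 1 && chain_of_res[gi - 1] == chain_of_res[gi]
  ok_next <- gj < nres_tot && chain_of_res[gj + 1] == chain_of_res[gj]
  if (!ok_prev || !ok_next) return(fail("missing_neighbor"))
  cut <- hbond_cutoffs(ff)$cutoffs
  p <- state$pos; L <- state$box
  dist <- function(a, b) {
    d <- p[a, ] - p[b, ]
    d <- d - L * round(d / L)
    sqrt(sum(d^2))
  }
  checks <- list(
    n_ca = c(nh_id, rsi[gj, "CA"]),
    n_n  = c(nh_id, rsi[gj + 1, "NH"]),
    c_ca = c(co_id, rsi[gi, "CA"]),
    c_c  = c(co_id, rsi[gi - 1, "CO"]))
  for (nm in names(checks)) {
    ids <- checks[[nm]]
    if (dist(ids[1], ids[2]) >= cut[[nm]]) return(fail(nm))
  }
  list(ok = TRUE, reason = "ok")
}

#' Classify a hydrogen bond as parallel or antiparallel
#'
#' Compares the local backbone directions of the donor and acceptor
#' residues: the vector from CaH(k-1) to CaH(k+1) on each chain. A positive
#' dot product labels the bond parallel, a negative one antiparallel.
#' Terminal residues, which lack a neighbour on one side, are unclassified.
#'
#' @param state a `prime_state`
#' @param topology a `prime_topology`
#' @param bond length-2 vector (donor NH sphere id, acceptor CO sphere id)
#' @return `"parallel"`, `"antiparallel"` or `NA` (unclassifiable)
#' @export
classify_bond_orientation <- function(state, topology, bond) {
  sp <- topology$spheres
  rsi <- residue_sphere_index(topology)
  nres_tot <- nrow(rsi)
  chain_of_res <- sp$chain[match(seq_len(nres_tot), sp$residue)]
  dir_of <- function(g) {
    if (g <= 1 || g >= nres_tot) return(NULL)
    if (chain_of_res[g - 1] != chain_of_res[g] ||
        chain_of_res[g + 1] != chain_of_res[g]) return(NULL)
    state$pos[rsi[g + 1, "CA"], ] - state$pos[rsi[g - 1, "CA"], ]
  }
  d1 <- dir_of(sp$residue[bond[1]])
  d2 <- dir_of(sp$residue[bond[2]])
  if (is.null(d1) || is.null(d2)) return(NA_character_)
  if (sum(d1 * d2) > 0) "parallel" else "antiparallel"
}

#' Orientation summary of a hydrogen-bond registry
#'
#' @param state a `prime_state`
#' @param topology a `prime_topology`
#' @param registry matrix (donor NH id, acceptor CO id)
#' @return data frame with donor/acceptor residues, chains and orientation
#' @export
hb_orientation_table <- function(state, topology, registry) {
  if (is.null(registry) || nrow(registry) == 0) {
    return(data.frame(donor_res = integer(0), acceptor_res = integer(0),
                      donor_chain = integer(0), acceptor_chain = integer(0),
                      orientation = character(0)))
  }
  sp <- topology$spheres
  data.frame(
    donor_res = sp$residue[registry[, 1]],
    acceptor_res = sp$residue[registry[, 2]],
    donor_chain = sp$chain[registry[, 1]],
    acceptor_chain = sp$chain[registry[, 2]],
    orientation = vapply(seq_len(nrow(registry)), function(r)
      classify_bond_orientation(state, topology, registry[r, 1:2]),
      character(1)))
}
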