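# Chain topology: the sphere/bond graph of the 4-sphere-per-residue model.

#' Build the sphere/bond topology of one peptide chain
#'
#' Each residue contributes an NH, a CaH and a CO backbone sphere plus one
#' side sphere (glycine has none). Covalent bonds, backbone pseudo-bonds
#' and the three side-sphere (pseudo-)bonds that pin the L arrangement are
#' enumerated with their nominal lengths and a symmetric fractional
#' tolerance window.
#'
#' @param sequence one-letter amino-acid string (or a length-1 FASTA-free
#'   character vector)
#' @param ff a `prime_forcefield` (supplies geometry and the tolerance)
#' @return an object of class `prime_topology` with elements `sequence`,
#'   `spheres` (data frame: `id`, `role`, `residue`, `chain`, `letter`,
#'   `mass`, `radius`) and `bonds` (data frame: `i`, `j`, `length`, `tol`,
#'   `kind`)
#' @export
build_chain <- function(sequence, ff) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  letters_vec <- strsplit(sequence, "")[[1]]
  if (length(letters_vec) == 0) stop("empty sequence")
  bad <- setdiff(letters_vec, AA_LETTERS)
  if (length(bad)) stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))

  bb <- ff$backbone
  geo <- ff$geometry
  sm <- side_mass_vec(ff)
  sd <- side_diameter_vec(ff)

  role <- character(0); res <- integer(0); mass <- numeric(0); rad <- numeric(0)
  for (k in seq_along(letters_vec)) {
    aa <- letters_vec[k]
    role <- c(role, ROLE_NH, ROLE_CA, ROLE_CO)
    res <- c(res, k, k, k)
    mass <- c(mass, bb$mass_nh, bb$mass_ca, bb$mass_co)
    rad <- c(rad, bb$diam_nh / 2, bb$diam_ca / 2, bb$diam_co / 2)
    if (aa != "G") {
      role <- c(role, ROLE_R); res <- c(res, k)
      mass <- c(mass, sm[[aa]]); rad <- c(rad, sd[[aa]] / 2)
    }
  }
  spheres <- data.frame(id = seq_along(role), role = role, residue = res,
                        chain = 1L, letter = letters_vec[res], mass = mass,
                        radius = rad, stringsAsFactors = FALSE)

  idx <- function(k, r) spheres$id[spheres$residue == k & spheres$role == r]
  tol <- ff$bond_tolerance
  # tighter windows pin the side sphere so only the L arrangement is reachable
  tol_side <- if (is.null(ff$side_bond_tolerance)) tol else ff$side_bond_tolerance
  bbg <- backbone_geometry()
  bnd <- list()
  add <- function(i, j, len, kind, tl = tol) {
    bnd[[length(bnd) + 1]] <<- data.frame(i = i, j = j, length = len,
                                          tol = tl, kind = kind)
  }
  nres <- length(letters_vec)
  for (k in seq_len(nres)) {
    add(idx(k, ROLE_NH), idx(k, ROLE_CA), bbg$len_n_ca, "bond")
    add(idx(k, ROLE_CA), idx(k, ROLE_CO), bbg$len_ca_co, "bond")
    add(idx(k, ROLE_NH), idx(k, ROLE_CO), bbg$pse_n_co, "pseudo")
    if (k < nres) {
      add(idx(k, ROLE_CO), idx(k + 1, ROLE_NH), bbg$len_co_n, "bond")
      add(idx(k, ROLE_CA), idx(k + 1, ROLE_NH), bbg$pse_ca_n, "pseudo")
      add(idx(k, ROLE_CO), idx(k + 1, ROLE_CA), bbg$pse_co_ca, "pseudo")
    }
    aa <- letters_vec[k]
    if (aa != "G") {
      g <- geo[match(aa, geo$residue), ]
      add(idx(k, ROLE_CA), idx(k, ROLE_R), g$dr_ca, "bond", tol_side)
      add(idx(k, ROLE_NH), idx(k, ROLE_R), g$dr_nh, "pseudo", tol_side)
      add(idx(k, ROLE_CO), idx(k, ROLE_R), g$dr_co, "pseudo", tol_side)
    }
  }
  structure(list(sequence = sequence, n_residues = nres,
                 spheres = spheres, bonds = do.call(rbind, bnd),
                 n_chains = 1L),
            class = "prime_topology")
}

#' Replicate a single-chain topology into a multi-chain system topology
#'
#' @param topology a `prime_topology` built by [build_chain()]
#' @param n_chains number of identical chains
#' @return a `prime_topology` whose sphere and bond tables cover all chains;
#'   residue indices are global (chain-major)
#' @export
replicate_topology <- function(topology, n_chains) {
  stopifnot(inherits(topology, "prime_topology"), n_chains >= 1)
  if (n_chains == 1) return(topology)
  ns <- nrow(topology$spheres)
  nr <- topology$n_residues
  sp <- do.call(rbind, lapply(seq_len(n_chains), function(c) {
    s <- topology$spheres
    s$id <- s$id + (c - 1L) * ns
    s$residue <- s$residue + (c - 1L) * nr
    s$chain <- c
    s
  }))
  bd <- do.call(rbind, lapply(seq_len(n_chains), function(c) {
    b <- topology$bonds
    b$i <- b$i + (c - 1L) * ns
    b$j <- b$j + (c - 1L) * ns
    b
  }))
  structure(list(sequence = topology$sequence, n_residues = nr,
                 spheres = sp, bonds = bd, n_chains = as.integer(n_chains)),
            class = "prime_topology")
}

#' Per-residue sphere index lookup
#'
#' @return an (n global residues) x 4 integer matrix with columns `NH`,
#'   `CA`, `CO`, `R` (`NA` where glycine has no side sphere)
#' @keywords internal
residue_sphere_index <- function(topology) {
  sp <- topology$spheres
  nres <- max(sp$residue)
  m <- matrix(NA_integer_, nres, 4, dimnames = list(NULL, c("NH", "CA", "CO", "R")))
  m[cbind(sp$residue, match(sp$role, c("NH", "CA", "CO", "R")))] <- sp$id
  m
}

#' @export
print.prime_topology <- function(x, ...) {
  cat("<prime_topology> ", x$n_chains, " chain(s) x ", x$n_residues,
      " residues (", x$sequence, "), ", nrow(x$spheres), " spheres, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}
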