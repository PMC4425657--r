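# Ideal backbone geometry and coordinate construction for the 4-sphere model.
#
# Internal coordinate conventions:
#   - lengths in Angstrom, angles in degrees
#   - backbone spheres per residue: NH, CaH, CO; side sphere R (none for G)
#   - L-chirality convention: det[NH-Ca, CO-Ca, R-Ca] > 0

#' Sphere roles used throughout the package
#' @keywords internal
ROLE_NH <- "NH"; ROLE_CA <- "CA"; ROLE_CO <- "CO"; ROLE_R <- "R"

#' One-letter codes of the 20 standard amino acids
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The Abeta17-42 peptide sequence (one-letter codes)
#'
#' The 26-residue C-terminal fragment of the amyloid-beta peptide, numbered
#' 17..42 by convention. This is the default sequence for simulations.
#' @export
AB17_42 <- "LVFFAEDVGSNKGAIIGLMVGGVVIA"

#' First residue number used when reporting Abeta fragments
#' @keywords internal
AB_FIRST_RESIDUE <- 17L

three_letter <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
                  G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
                  M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
                  S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

deg2rad <- function(x) x * pi / 180

#' Place an atom from three reference positions (internal coordinates)
#'
#' Natural-extension-reference-frame placement: the new position is at
#' distance `len` from `c`, with angle `ang` (degrees) at `c` relative to
#' `b`, and dihedral `dih` (degrees) about the b-c axis relative to `a`.
#' @keywords internal
place_atom <- function(a, b, c, len, ang, dih) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("colinear reference atoms in place_atom()")
  n <- n / nn
  m <- pracma_cross(n, bc)
  ang <- deg2rad(ang); dih <- deg2rad(-dih)  # sign matches dihedral_angle()
  d <- c(-len * cos(ang),
         len * sin(ang) * cos(dih),
         len * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dihedral angle (degrees) defined by four points
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Backbone bond/pseudo-bond lengths and bend angles
#'
#' Fixed internal coordinates of the peptide backbone in the 4-sphere
#' representation: covalent NH-CaH, CaH-CO and CO-NH(next) bond lengths and
#' the three pseudo-bond lengths that fix the backbone bend angles. The
#' peptide bond (omega) is held trans.
#' @return a list of lengths (Angstrom) and derived angles (degrees)
#' @export
backbone_geometry <- function() {
  b <- list(
    len_n_ca  = 1.460,  # NH - CaH
    len_ca_co = 1.510,  # CaH - CO
    len_co_n  = 1.330,  # CO - NH(next)
    pse_n_co  = 2.450,  # NH - CO   (same residue)
    pse_ca_n  = 2.410,  # CaH - NH(next)
    pse_co_ca = 2.450,  # CO - CaH(next)
    omega     = 180     # trans peptide bond
  )
  ang <- function(l1, l2, opp) acos((l1^2 + l2^2 - opp^2) / (2 * l1 * l2)) * 180 / pi
  b$ang_n_ca_co <- ang(b$len_n_ca, b$len_ca_co, b$pse_n_co)   # ~111.2
  b$ang_ca_co_n <- ang(b$len_ca_co, b$len_co_n, b$pse_ca_n)   # ~116.0
  b$ang_co_n_ca <- ang(b$len_co_n, b$len_n_ca, b$pse_co_ca)   # ~122.8
  # side-sphere bend angles at CaH (tetrahedral-like, applied to all residues)
  b$ang_n_ca_r  <- 110.5
  b$ang_co_ca_r <- 110.1
  b
}

#' Side-sphere position for a residue, with L-chirality
#'
#' Places the side-chain sphere at distance `dr_ca` from CaH such that the
#' angles NH-CaH-R and CO-CaH-R take their ideal values and the scalar triple
#' product det(NH-Ca, CO-Ca, R-Ca) is positive (the package's L convention).
#' @keywords internal
place_side_sphere <- function(nh, ca, co, dr_ca, bb = backbone_geometry()) {
  a <- nh - ca; a <- a / sqrt(sum(a^2))
  b <- co - ca; b <- b / sqrt(sum(b^2))
  ca_dot <- sum(a * b)
  t1 <- cos(deg2rad(bb$ang_n_ca_r))
  t2 <- cos(deg2rad(bb$ang_co_ca_r))
  # solve d = la*a + mu*b + nu*nhat with d.a = t1, d.b = t2, |d| = 1, nu > 0
  det <- 1 - ca_dot^2
  la <- (t1 - t2 * ca_dot) / det
  mu <- (t2 - t1 * ca_dot) / det
  inplane <- la^2 + mu^2 + 2 * la * mu * ca_dot
  if (inplane > 1) stop("side-sphere bend angles are inconsistent")
  nu <- sqrt(1 - inplane)
  nhat <- pracma_cross(a, b)
  nhat <- nhat / sqrt(sum(nhat^2))
  d <- la * a + mu * b + nu * nhat
  ca + dr_ca * d
}

#' Side-sphere pseudo-bond lengths implied by the ideal geometry
#'
#' Given the CaH-to-side-sphere distance of a residue, returns the implied
#' NH-R and CO-R pseudo-bond lengths under the ideal bend angles. These,
#' together with `dr_ca`, pin the side sphere in the L arrangement: the two
#' mirror solutions of the three distance constraints are disjoint under the
#' fractional bond tolerance, so handedness cannot flip during dynamics.
#' @param dr_ca CaH-to-side-sphere distance (Angstrom)
#' @return named vector with `dr_nh` and `dr_co`
#' @export
side_pseudo_bonds <- function(dr_ca, bb = backbone_geometry()) {
  law <- function(l1, l2, ang) sqrt(l1^2 + l2^2 - 2 * l1 * l2 * cos(deg2rad(ang)))
  c(dr_nh = law(dr_ca, bb$len_n_ca, bb$ang_n_ca_r),
    dr_co = law(dr_ca, bb$len_ca_co, bb$ang_co_ca_r))
}

#' Build chain coordinates from backbone dihedrals
#'
#' Constructs 4-sphere coordinates for a sequence given per-residue (phi,
#' psi) dihedrals (degrees). phi of the first and psi of the last residue are
#' ignored (undefined). Returns an n_spheres x 3 matrix in the order produced
#' by [build_chain()]: NH, CaH, CO, (R) per residue.
#'
#' @param sequence one-letter amino-acid string
#' @param phi,psi numeric vectors, one entry per residue
#' @param geometry per-residue geometry table (see [load_forcefield()]);
#'   only `dr_ca` is used here
#' @export
chain_coordinates <- function(sequence, phi, psi, geometry) {
  letters_vec <- strsplit(sequence, "")[[1]]
  nres <- length(letters_vec)
  stopifnot(length(phi) == nres, length(psi) == nres)
  bb <- backbone_geometry()
  # backbone trace
  nh <- ca <- co <- vector("list", nres)
  nh[[1]] <- c(0, 0, 0)
  ca[[1]] <- c(bb$len_n_ca, 0, 0)
  # the torsion about NH1-CaH1 only sets the global orientation; fix it at 0
  co[[1]] <- place_atom(c(0, -1, 0), nh[[1]], ca[[1]],
                        bb$len_ca_co, bb$ang_n_ca_co, 0)
  for (k in seq_len(nres - 1)) {
    nh[[k + 1]] <- place_atom(nh[[k]], ca[[k]], co[[k]],
                              bb$len_co_n, bb$ang_ca_co_n, psi[k])
    ca[[k + 1]] <- place_atom(ca[[k]], co[[k]], nh[[k + 1]],
                              bb$len_n_ca, bb$ang_co_n_ca, bb$omega)
    co[[k + 1]] <- place_atom(co[[k]], nh[[k + 1]], ca[[k + 1]],
                              bb$len_ca_co, bb$ang_n_ca_co, phi[k + 1])
  }
  rows <- list()
  for (k in seq_len(nres)) {
    rows[[length(rows) + 1]] <- nh[[k]]
    rows[[length(rows) + 1]] <- ca[[k]]
    rows[[length(rows) + 1]] <- co[[k]]
    aa <- letters_vec[k]
    if (aa != "G") {
      dr <- geometry$dr_ca[match(aa, geometry$residue)]
      rows[[length(rows) + 1]] <- place_side_sphere(nh[[k]], ca[[k]], co[[k]], dr, bb)
    }
  }
  do.call(rbind, rows)
}
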