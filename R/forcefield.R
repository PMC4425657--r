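# Force-field container: masses, hard cores, double wells, hydrogen-bond
# cutoff sets, salt-bridge configuration. All energies in units of the
# hydrogen-bond well depth eps_HB = 1; kB = 1; lengths in Angstrom.

#' Load the coarse-grained force field
#'
#' Reads the parameter tables (tab-separated text, shipped in
#' `inst/extdata/prime20/`) and assembles a validated `prime_forcefield`
#' object. The backbone masses, the hydrogen-bond cutoff sets, the 1.3/0.7
#' double-well multipliers and the salt-bridge strengths are published
#' constants; the per-residue side-chain geometry, squeeze distances, well
#' diameters and the full pairwise energy matrix shipped as defaults are
#' synthetic estimates (see the files' headers) and can be overridden with
#' user-supplied tables of the same layout.
#'
#' @param dir directory holding the parameter tables; default: the tables
#'   shipped with the package
#' @param hbond_mode `"parallel_preference"` (default) or `"original"`:
#'   which auxiliary hydrogen-bond distance-cutoff set is active
#' @param salt_bridge_enhanced logical; if `TRUE` (default) the K-D side
#'   sphere pair uses the enhanced base strength 0.4 eps_HB instead of the
#'   original 0.136 eps_HB
#' @param bond_tolerance symmetric fractional half-width of backbone bond
#'   and pseudo-bond distance windows
#' @param side_bond_tolerance fractional half-width of the three side-sphere
#'   (pseudo-)bond windows (CaH-R, NH-R, CO-R). These are deliberately
#'   tighter than the backbone windows: below about 2% the L and D
#'   arrangements of every residue are disconnected in configuration space
#'   (reaching the mirror image would require a coplanar transition state
#'   that violates at least one window), so handedness is conserved by the
#'   exact dynamics alone
#' @param hbond_well_diameter NH-CO association well diameter (Angstrom)
#' @return an object of class `prime_forcefield`
#' @export
load_forcefield <- function(dir = system.file("extdata", "prime20", package = "primedmd"),
                            hbond_mode = c("parallel_preference", "original"),
                            salt_bridge_enhanced = TRUE,
                            bond_tolerance = 0.02375,
                            side_bond_tolerance = 0.0125,
                            hbond_well_diameter = 4.2) {
  hbond_mode <- match.arg(hbond_mode)
  read_tab <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing parameter table: ", path)
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               check.names = FALSE)
  }
  backbone <- read_tab("backbone.tsv")
  geometry <- read_tab("sidechain_geometry_synthetic.tsv")
  squeeze  <- read_tab("squeeze_synthetic.tsv")
  energies <- read_tab("pair_energies_synthetic.tsv")
  d_inner  <- read_tab("well_inner_synthetic.tsv")
  d_outer  <- read_tab("well_outer_synthetic.tsv")
  hbonds   <- read_tab("hbond_cutoffs.tsv")

  bbv <- function(key) {
    i <- match(key, backbone$parameter)
    if (is.na(i)) stop("backbone.tsv is missing parameter '", key, "'")
    backbone$value[i]
  }
  bb <- list(
    diam_nh = bbv("diam_nh"), diam_ca = bbv("diam_ca"), diam_co = bbv("diam_co"),
    mass_nh = bbv("mass_nh"), mass_ca = bbv("mass_ca"), mass_co = bbv("mass_co"),
    near_factor = bbv("near_factor")
  )

  need <- setdiff(AA_LETTERS, "G")
  for (tab in list(geometry = geometry, squeeze = squeeze)) {
    miss <- setdiff(need, tab$residue)
    if (length(miss)) stop("parameter table missing residues: ",
                           paste(miss, collapse = ", "))
  }

  as_pair_matrix <- function(df, what) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m <- m[need, need, drop = FALSE]
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-9)
      stop(what, " table is not symmetric under pair exchange")
    m
  }
  eps   <- as_pair_matrix(energies, "pair energy")
  din   <- as_pair_matrix(d_inner, "inner well diameter")
  dout  <- as_pair_matrix(d_outer, "outer well diameter")
  if (any(din >= dout)) stop("inner well diameters must be below outer well diameters")

  cut_row <- function(mode) {
    i <- match(mode, hbonds$mode)
    if (is.na(i)) stop("hbond_cutoffs.tsv is missing mode '", mode, "'")
    unlist(hbonds[i, c("n_ca", "n_n", "c_ca", "c_c")])
  }
  ff <- structure(list(
    backbone = bb,
    geometry = geometry,
    squeeze = squeeze,
    eps = eps,
    d_inner = din,
    d_outer = dout,
    mult_inner = 1.3,
    mult_outer = 0.7,
    hbond = list(mode = hbond_mode,
                 cutoffs = cut_row(hbond_mode),
                 cutoff_sets = list(
                   parallel_preference = cut_row("parallel_preference"),
                   original = cut_row("original")),
                 well_diameter = hbond_well_diameter),
    salt_bridge = list(enhanced = isTRUE(salt_bridge_enhanced),
                       eps_enhanced = 0.4, eps_original = 0.136),
    bond_tolerance = bond_tolerance,
    side_bond_tolerance = side_bond_tolerance,
    sigma = bbv("diam_nh"),   # NH sphere diameter: the length unit of t*
    m_nh = bbv("mass_nh")
  ), class = "prime_forcefield")
  validate_forcefield(ff)
  ff
}

validate_forcefield <- function(ff) {
  need <- setdiff(AA_LETTERS, "G")
  stopifnot(all(ff$geometry$dr_ca > 0), all(ff$geometry$side_mass > 0),
            all(ff$geometry$side_diameter > 0))
  sq <- as.matrix(ff$squeeze[, -1])
  if (any(sq <= 0)) stop("squeeze distances must be positive")
  core <- outer(side_diameter_vec(ff)[need], side_diameter_vec(ff)[need], "+") / 2
  if (any(ff$d_inner <= core))
    stop("inner well diameters must exceed hard-core contact distances")
  invisible(ff)
}

side_diameter_vec <- function(ff) {
  d <- ff$geometry$side_diameter
  names(d) <- ff$geometry$residue
  d
}

side_mass_vec <- function(ff) {
  m <- ff$geometry$side_mass
  names(m) <- ff$geometry$residue
  m
}

#' Base pair interaction strength, with the salt-bridge rule applied
#' @keywords internal
pair_eps <- function(ff, a, b) {
  e <- ff$eps[a, b]
  if (ff$salt_bridge$enhanced &&
      ((a == "K" && b == "D") || (a == "D" && b == "K")))
    e <- ff$salt_bridge$eps_enhanced
  e
}

#' Double-well potential for a side-chain sphere pair
#'
#' Returns the hard-core contact distance, the inner and outer well
#' diameters, and the base/inner/outer energies (eps_HB units) for two
#' residues' side spheres. The inner well depth is 1.3 x base and the outer
#' 0.7 x base; positive base values are attractive (energy is minus the
#' depth inside the well), negative values give a repulsive shoulder.
#'
#' @param ff a `prime_forcefield`
#' @param a,b one-letter residue codes (must have side spheres, i.e. not G)
#' @return a list with `d_core`, `d_inner`, `d_outer`, `e_base`, `e_inner`,
#'   `e_outer`
#' @export
pair_potential <- function(ff, a, b) {
  for (x in c(a, b)) {
    if (!x %in% AA_LETTERS) stop("unknown residue letter: ", x)
    if (x == "G") stop("glycine has no side sphere; no pair potential defined")
  }
  d <- side_diameter_vec(ff)
  e <- pair_eps(ff, a, b)
  list(d_core = (d[[a]] + d[[b]]) / 2,
       d_inner = ff$d_inner[a, b],
       d_outer = ff$d_outer[a, b],
       e_base = e,
       e_inner = ff$mult_inner * e,
       e_outer = ff$mult_outer * e)
}

#' Auxiliary hydrogen-bond distance cutoffs
#'
#' The four auxiliary distances gate NH-CO association: for donor residue i
#' and acceptor residue j they constrain N_i-Ca_j, N_i-N_(j+1), C_j-Ca_i and
#' C_j-C_(i-1). The `parallel_preference` set biases hydrogen bonding toward
#' parallel in-register beta-sheets; `original` is the unbiased set.
#'
#' @param ff a `prime_forcefield`
#' @param mode `"parallel_preference"` or `"original"`; default: the set the
#'   force field was loaded with
#' @return a list with `mode`, the four `cutoffs` (Angstrom, named `n_ca`,
#'   `n_n`, `c_ca`, `c_c`) and the NH-CO `well_diameter`
#' @export
hbond_cutoffs <- function(ff, mode = ff$hbond$mode) {
  if (!mode %in% names(ff$hbond$cutoff_sets))
    stop("unknown hydrogen-bond cutoff mode: ", mode)
  list(mode = mode,
       cutoffs = ff$hbond$cutoff_sets[[mode]],
       well_diameter = ff$hbond$well_diameter)
}

#' Derive a square-well diameter from contact distance samples
#'
#' Implements the heavy-atom criterion used to size side-chain wells from
#' structural surveys: a sampled side-chain pair qualifies as a contact when
#' strictly more than half of its heavy-atom pair distances fall below the
#' cutoff (4.5 A for the inner well, 5.5 A for the outer well); the well
#' diameter is then a summary statistic of the qualifying centroid-centroid
#' distances. The default statistic is the maximum, so that the well
#' encloses every observed contact geometry; a quantile can be used instead.
#'
#' @param centroid_distances numeric vector: side-chain centroid separation
#'   of each sample
#' @param heavy_atom_distances list of numeric vectors: inter-side-chain
#'   heavy-atom distances of each sample
#' @param cutoff heavy-atom distance criterion (Angstrom)
#' @param statistic `"max"` or a probability in (0, 1] for a quantile
#' @return the derived well diameter (Angstrom)
#' @export
derive_well_diameter <- function(centroid_distances, heavy_atom_distances,
                                 cutoff, statistic = "max") {
  stopifnot(length(centroid_distances) == length(heavy_atom_distances),
            length(centroid_distances) > 0, cutoff > 0)
  qualifies <- vapply(heavy_atom_distances, function(d) {
    mean(d < cutoff) > 0.5
  }, logical(1))
  if (!any(qualifies))
    stop("no sample qualifies under the ", cutoff, " A heavy-atom criterion")
  x <- centroid_distances[qualifies]
  if (identical(statistic, "max")) return(max(x))
  p <- as.numeric(statistic)
  if (!is.finite(p) || p <= 0 || p > 1) stop("statistic must be 'max' or a probability")
  unname(quantile(x, p, type = 7))
}

#' Write a force field back to parameter tables
#'
#' Writes the same tab-separated layout read by [load_forcefield()], so that
#' writing and reloading reproduces the tables exactly.
#' @param ff a `prime_forcefield`
#' @param dir output directory (created if needed)
#' @export
write_forcefield <- function(ff, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  bbdf <- data.frame(parameter = c("diam_nh", "diam_ca", "diam_co",
                                   "mass_nh", "mass_ca", "mass_co",
                                   "near_factor"),
                     value = c(ff$backbone$diam_nh, ff$backbone$diam_ca,
                               ff$backbone$diam_co, ff$backbone$mass_nh,
                               ff$backbone$mass_ca, ff$backbone$mass_co,
                               ff$backbone$near_factor))
  wt(bbdf, "backbone.tsv")
  wt(ff$geometry, "sidechain_geometry_synthetic.tsv")
  wt(ff$squeeze, "squeeze_synthetic.tsv")
  as_df <- function(m) cbind(data.frame(residue = rownames(m)), as.data.frame(m))
  wt(as_df(ff$eps), "pair_energies_synthetic.tsv")
  wt(as_df(ff$d_inner), "well_inner_synthetic.tsv")
  wt(as_df(ff$d_outer), "well_outer_synthetic.tsv")
  hb <- do.call(rbind, lapply(names(ff$hbond$cutoff_sets), function(m) {
    v <- ff$hbond$cutoff_sets[[m]]
    data.frame(mode = m, n_ca = v[["n_ca"]], n_n = v[["n_n"]],
               c_ca = v[["c_ca"]], c_c = v[["c_c"]])
  }))
  wt(hb, "hbond_cutoffs.tsv")
  invisible(dir)
}

#' @export
print.prime_forcefield <- function(x, ...) {
  cat("<prime_forcefield>\n")
  cat("  hydrogen bonds:", x$hbond$mode,
      sprintf("(well %.2f A)", x$hbond$well_diameter), "\n")
  cat("  salt bridge K-D:",
      if (x$salt_bridge$enhanced) sprintf("enhanced (%.3g eps_HB)", x$salt_bridge$eps_enhanced)
      else sprintf("original (%.3g eps_HB)", x$salt_bridge$eps_original), "\n")
  cat("  double well multipliers:", x$mult_inner, "/", x$mult_outer, "\n")
  cat("  bond tolerance: +/-", 100 * x$bond_tolerance, "% (side spheres +/-",
      100 * x$side_bond_tolerance, "%)\n")
  invisible(x)
}
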