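# Trajectory statistics: dihedrals, secondary structure, SASA, P_max,
# salt bridges, chain shapes.

test_that("backbone dihedrals are recovered from constructed geometry", {
  topo <- build_chain("VQIVYK", FF)
  phi <- c(NA, -100, -130, -70, -115, -60)
  psi <- c(140, 120, 150, 100, 130, NA)
  x <- chain_coordinates("VQIVYK", ifelse(is.na(phi), -120, phi),
                         ifelse(is.na(psi), 130, psi), FF$geometry)
  dh <- phi_psi(x, topo)
  expect_true(is.na(dh$phi[1]))
  expect_true(is.na(dh$psi[6]))
  expect_equal(dh$phi[2:6], phi[2:6], tolerance = 1e-3)
  expect_equal(dh$psi[1:5], psi[1:5], tolerance = 1e-3)
  # mirror image flips both signs
  dh_m <- phi_psi(-x, topo)
  expect_equal(dh_m$phi[2:6], -phi[2:6], tolerance = 1e-3)
  expect_equal(dh_m$psi[1:5], -psi[1:5], tolerance = 1e-3)
})

test_that("strand labels require both beta dihedrals and a bond ladder", {
  # an isolated chain in beta conformation has no ladder: all coil
  topo <- build_chain("VQIVYKQQ", FF)
  x <- chain_coordinates("VQIVYKQQ", rep(-120, 8), rep(130, 8), FF$geometry)
  ss <- assign_secondary_structure(x, topo, bonds = matrix(integer(0), 0, 2))
  expect_true(all(ss$ss == "coil"))
  # the idealized sheet labels interior residues strand
  sheet <- fixture_parallel_sheet("VQIVYKQQ", FF)
  ss <- assign_secondary_structure(sheet$state$pos, sheet$topology,
                                   sheet$bonds)
  expect_true(all(ss$ss[c(3:6, 11:14)] == "strand"))
  expect_true(all(ss$ss[c(1, 9)] == "coil"))  # termini stay coil
  # mirroring never creates strand without a ladder
  ss_m <- assign_secondary_structure(-sheet$state$pos, sheet$topology,
                                     bonds = matrix(integer(0), 0, 2))
  expect_true(all(ss_m$ss != "strand"))
})

test_that("strand probabilities count frames and chains", {
  sheet <- fixture_parallel_sheet("VQIVYKQQ", FF)
  f_sheet <- list(time = 0, pos = sheet$state$pos, bonds = sheet$bonds)
  f_coil <- list(time = 1, pos = sheet$state$pos,
                 bonds = matrix(integer(0), 0, 2))
  prof <- strand_content_profile(list(f_sheet, f_coil), sheet$topology,
                                 first_residue = 1)
  expect_true(all(prof$p_strand >= 0 & prof$p_strand <= 1))
  expect_equal(prof$p_strand[3:6], rep(0.5, 4))  # strand in half the frames
  expect_equal(prof$p_strand[1], 0)
  prof2 <- strand_content_profile(list(f_coil), sheet$topology)
  expect_true(all(prof2$p_strand == 0))
  expect_error(strand_content_profile(list(f_sheet), sheet$topology,
                                      window = c(5, 6)), "no frames")
})

test_that("solvent accessibility matches closed-form sphere geometry", {
  topo <- build_chain("A", FF)
  # a lone sphere: area of the probe-expanded sphere
  pos <- matrix(c(0, 0, 0), 1, 3)
  r <- 1.85; p <- 1.4
  one <- primedmd:::fibonacci_sphere(960)
  expect_equal(nrow(one), 960)
  st_top <- list(spheres = data.frame(residue = 1L, chain = 1L),
                 n_residues = 1L)
  # use sasa_profile on a custom one-sphere "topology"
  fake_topo <- structure(list(sequence = "A", n_residues = 1L,
                              spheres = data.frame(id = 1L, role = "R",
                                                   residue = 1L, chain = 1L,
                                                   letter = "A", mass = 1,
                                                   radius = r),
                              bonds = data.frame(), n_chains = 1L),
                         class = "prime_topology")
  area <- sasa_profile(pos, fake_topo, radii = r, probe = p)$area
  expect_equal(area, 4 * pi * (r + p)^2, tolerance = 1e-9)

  # two equal overlapping spheres: equal areas, below isolated, and equal
  # to the closed-form spherical-cap result
  d <- 2.5
  fake2 <- structure(list(sequence = "AA", n_residues = 2L,
                          spheres = data.frame(id = 1:2, role = "R",
                                               residue = 1:2, chain = 1L,
                                               letter = "A", mass = 1,
                                               radius = r),
                          bonds = data.frame(), n_chains = 1L),
                     class = "prime_topology")
  pos2 <- rbind(c(0, 0, 0), c(d, 0, 0))
  a2 <- sasa_profile(pos2, fake2, radii = c(r, r), probe = p)$area
  expect_equal(a2[1], a2[2], tolerance = 1e-9)
  expect_lt(a2[1], 4 * pi * (r + p)^2)
  rr <- r + p
  cap_frac <- (1 - d / (2 * rr)) / 2       # buried cap fraction of a sphere
  expect_equal(a2[1], 4 * pi * rr^2 * (1 - cap_frac), tolerance = 0.02)

  # a sphere enclosed in a tight blocker shell is fully buried
  shell <- primedmd:::fibonacci_sphere(40) * 2.2
  fake_n <- structure(list(sequence = "A", n_residues = 41L,
                           spheres = data.frame(id = 1:41, role = "R",
                                                residue = 1:41, chain = 1L,
                                                letter = "A", mass = 1,
                                                radius = c(r, rep(2, 40))),
                           bonds = data.frame(), n_chains = 1L),
                      class = "prime_topology")
  a_in <- sasa_profile(rbind(c(0, 0, 0), shell), fake_n,
                       radii = c(r, rep(2, 40)), probe = p)$area[1]
  expect_equal(a_in, 0)
})

test_that("P_max finds the most populated energy band", {
  # constant energy: P_max = 1 and zero free energy in every window
  s <- data.frame(t = seq(0, 19999, by = 10), e = -5)
  pm <- pmax_series(s, dt = 5000, halfwidth = 4, tstar = 0.2)
  expect_equal(nrow(pm), 4)
  expect_true(all(pm$p_max == 1))
  expect_true(all(pm$free_energy == 0))

  # bimodal 60/40 split separated by 20 eps_HB
  set.seed(8)
  n <- 1000
  lev <- ifelse(runif(n) < 0.6, -30, -10)
  s <- data.frame(t = seq_len(n), e = lev)
  pm <- pmax_series(s, dt = n + 1, halfwidth = 4, tstar = 0.2)
  expect_equal(pm$p_max, mean(lev == -30))
  expect_equal(pm$e_max, -30)
  expect_equal(pm$free_energy, -0.2 * log(pm$p_max))

  expect_error(pmax_series(data.frame(t = c(2, 1), e = c(0, 0))),
               "strictly increasing")
})

test_that("P_max equals an exhaustive band search on random series", {
  brute_pmax <- function(e, h) {
    cnt <- vapply(e, function(c0) sum(abs(e - c0) <= h), numeric(1))
    best <- which(cnt == max(cnt))
    list(p = max(cnt) / length(e), e_max = min(e[best]))
  }
  set.seed(14)
  for (k in 1:25) {
    n <- sample(50:300, 1)
    e <- round(cumsum(rnorm(n, sd = 2)) - 20, 2)
    s <- data.frame(t = seq_len(n), e = e)
    pm <- pmax_series(s, dt = n + 1, halfwidth = 4, tstar = 0.2)
    bf <- brute_pmax(e, 4)
    expect_equal(pm$p_max, bf$p)
    expect_equal(pm$e_max, bf$e_max)
  }
})

test_that("salt bridges are counted within the K-D outer well", {
  topo1 <- build_chain("KAAD", FF)
  topo <- replicate_topology(topo1, 2)
  rsi <- primedmd:::residue_sphere_index(topo)
  ns <- nrow(topo1$spheres)
  pos <- matrix(rep(seq(0, 400, length.out = nrow(topo$spheres))), ncol = 3,
                nrow = nrow(topo$spheres))   # spread far apart
  expect_equal(count_salt_bridges(pos, topo, FF),
               c(intra = 0L, inter = 0L))
  dmax <- FF$d_outer["K", "D"]
  # one intra-chain contact
  pos1 <- pos
  pos1[rsi[1, "R"], ] <- c(0, 0, 0)
  pos1[rsi[4, "R"], ] <- c(dmax - 0.2, 0, 0)
  expect_equal(count_salt_bridges(pos1, topo, FF),
               c(intra = 1L, inter = 0L))
  # the same contact across chains
  pos2 <- pos
  pos2[rsi[1, "R"], ] <- c(0, 0, 0)
  pos2[rsi[8, "R"], ] <- c(dmax - 0.2, 0, 0)   # D of chain 2
  expect_equal(count_salt_bridges(pos2, topo, FF),
               c(intra = 0L, inter = 1L))
  # just outside the outer well: no bridge
  pos3 <- pos
  pos3[rsi[1, "R"], ] <- c(0, 0, 0)
  pos3[rsi[8, "R"], ] <- c(dmax + 0.2, 0, 0)
  expect_equal(sum(count_salt_bridges(pos3, topo, FF)), 0)
})

test_that("chain shapes classify U, S, triangular and extended traces", {
  topo <- build_chain(AB17_42, FF)
  for (case in list(c("U", "U"), c("S", "S"),
                    c("triangular", "triangular"),
                    c("extended", "disordered"))) {
    pos <- synthetic_shape_positions(topo, case[1])
    got <- classify_chain_shape(pos, topo, chain = 1, FF)
    expect_equal(got, case[2])
  }
  short <- build_chain("VQIVYK", FF)
  x <- chain_coordinates("VQIVYK", rep(-120, 6), rep(130, 6), FF$geometry)
  expect_equal(classify_chain_shape(x, short, 1, FF), "unclassified")
})
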