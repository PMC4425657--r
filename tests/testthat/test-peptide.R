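# Chain building, random-coil generation, chirality and geometry checks.

test_that("sphere counts follow the 4-per-residue rule with 3 for glycine", {
  topo <- build_chain(AB17_42, FF)
  expect_equal(nrow(topo$spheres), 99)   # 26 x 4 - 5 glycines
  expect_equal(topo$n_residues, 26)
  set.seed(11)
  for (k in 1:8) {
    n <- sample(2:30, 1)
    s <- paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
    topo <- build_chain(s, FF)
    g <- sum(strsplit(s, "")[[1]] == "G")
    expect_equal(nrow(topo$spheres), 4 * n - g)
    # backbone connectivity: a path of covalent bonds spans all residues
    co <- topo$bonds[topo$bonds$kind == "bond", ]
    expect_gte(nrow(co), 3 * n - 1)
  }
})

test_that("single alanine has four spheres and side mass 1", {
  topo <- build_chain("A", FF)
  expect_equal(nrow(topo$spheres), 4)
  expect_equal(topo$spheres$mass[topo$spheres$role == "R"], 1.000)
})

test_that("invalid sequences are rejected", {
  expect_error(build_chain("X", FF), "unknown residue")
  expect_error(build_chain("", FF), "empty")
  expect_error(build_chain("AXC", FF), "X")
})

test_that("random-coil configurations are overlap-free, separated, and seeded", {
  topo <- build_chain(AB17_42, FF)
  cfg <- simulation_config(n_chains = 2, box_length = 90, seed = 42)
  gen <- generate_initial_configuration(topo, FF, cfg)
  expect_equal(nrow(gen$state$pos), 2 * 99)
  expect_equal(nrow(validate_geometry(gen$state, gen$topology, FF)), 0)

  # no inter-chain pair within the largest interaction diameter
  tab <- build_interaction_tables(gen$topology, FF)
  dm <- primedmd:::pair_min_image_dist(gen$state$pos, gen$state$box)
  inter <- outer(gen$topology$spheres$chain, gen$topology$spheres$chain, "!=")
  expect_gt(min(dm[inter]), tab$max_interaction)

  # identical seed, identical configuration
  gen2 <- generate_initial_configuration(topo, FF, cfg)
  expect_identical(gen$state$pos, gen2$state$pos)
  expect_identical(gen$state$vel, gen2$state$vel)

  # Maxwell-Boltzmann start: kinetic temperature near the schedule start
  ke <- total_kinetic(gen$state, gen$topology$spheres$mass)
  expect_equal(ke / (1.5 * nrow(gen$state$pos)), cfg$t_start, tolerance = 0.15)
})

test_that("a box too small for placement raises a resource error", {
  topo <- build_chain(AB17_42, FF)
  cfg <- simulation_config(n_chains = 8, box_length = 20, seed = 1)
  expect_error(
    suppressWarnings(generate_initial_configuration(
      topo, FF, cfg, max_chain_restarts = 20, max_place_attempts = 20)),
    "placement failed|growth failed")
})

test_that("chirality is L for built chains, D after mirroring, none for G", {
  topo <- build_chain(AB17_42, FF)
  cfg <- simulation_config(n_chains = 1, box_length = 90, seed = 7)
  gen <- generate_initial_configuration(topo, FF, cfg)
  letters_vec <- strsplit(AB17_42, "")[[1]]
  for (g in seq_len(26)) {
    expected <- if (letters_vec[g] == "G") "achiral" else "L"
    expect_equal(chirality_sign(gen$state, gen$topology, g), expected)
  }
  mirrored <- gen$state
  mirrored$pos <- -mirrored$pos
  labs <- vapply(seq_len(26), function(g)
    chirality_sign(mirrored, gen$topology, g), character(1))
  expect_equal(sum(labs == "D"), sum(letters_vec != "G"))

  # the validator reports one chirality violation per non-glycine residue
  v <- validate_geometry(mirrored, gen$topology, FF)
  expect_equal(sum(v$kind == "chirality_D"), 26 - 5)
})

test_that("the validator localises a stretched bond", {
  topo <- build_chain("AV", FF)
  cfg <- simulation_config(n_chains = 1, box_length = 60, seed = 2)
  gen <- generate_initial_configuration(topo, FF, cfg)
  expect_equal(nrow(validate_geometry(gen$state, gen$topology, FF)), 0)
  b <- gen$topology$bonds[1, ]   # NH1-CaH1
  bad <- gen$state
  dir <- bad$pos[b$j, ] - bad$pos[b$i, ]
  bad$pos[b$j, ] <- bad$pos[b$i, ] + dir * 1.10
  v <- validate_geometry(bad, gen$topology, FF)
  stretch <- v[v$kind == "bond_long", ]
  expect_true(any(stretch$i == b$i & stretch$j == b$j))
})

test_that("derived concentration follows box and chain count", {
  cfg <- simulation_config(n_chains = 8, box_length = 160)
  expect_equal(concentration_mM(cfg), 3.24, tolerance = 0.01)
  expect_equal(concentration_mM(simulation_config(n_chains = 4, box_length = 160)),
               concentration_mM(cfg) / 2)
})
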