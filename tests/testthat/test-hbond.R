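# Hydrogen-bond eligibility, bookkeeping and orientation classification.

sheet <- fixture_parallel_sheet("VQIVYKQQ", FF)

test_that("an idealized parallel sheet satisfies all formation constraints", {
  expect_gt(nrow(sheet$bonds), 3)
  for (r in seq_len(nrow(sheet$bonds))) {
    res <- hb_can_form(sheet$state, sheet$topology, FF,
                       sheet$bonds[r, 1], sheet$bonds[r, 2])
    expect_true(res$ok)
  }
})

test_that("one inflated auxiliary distance blocks formation and is named", {
  st <- sheet$state
  topo <- sheet$topology
  b <- sheet$bonds[2, ]
  sp <- topo$spheres
  rsi <- primedmd:::residue_sphere_index(topo)
  gj <- sp$residue[b[2]]
  nid <- rsi[gj + 1, "NH"]             # the N_(j+1) auxiliary sphere
  donor <- st$pos[b[1], ]
  dir <- st$pos[nid, ] - donor
  cut <- hbond_cutoffs(FF)$cutoffs[["n_n"]]
  st$pos[nid, ] <- donor + dir / sqrt(sum(dir^2)) * (cut + 0.1)
  res <- hb_can_form(st, topo, FF, b[1], b[2])
  expect_false(res$ok)
  expect_equal(res$reason, "n_n")
})

test_that("occupied partners and bad roles are rejected", {
  b <- sheet$bonds
  reg <- b[1, , drop = FALSE]
  res <- hb_can_form(sheet$state, sheet$topology, FF, b[1, 1], b[2, 2],
                     registry = reg)
  expect_equal(res$reason, "donor_occupied")
  res <- hb_can_form(sheet$state, sheet$topology, FF, b[1, 2], b[1, 1])
  expect_equal(res$reason, "donor_role")
  # intra-chain short-range pairs fail the separation rule
  topo <- sheet$topology
  rsi <- primedmd:::residue_sphere_index(topo)
  res <- hb_can_form(sheet$state, topo, FF, rsi[3, "NH"], rsi[4, "CO"])
  expect_equal(res$reason, "separation")
})

test_that("bond orientation tracks strand directionality", {
  for (r in seq_len(nrow(sheet$bonds))) {
    expect_equal(classify_bond_orientation(sheet$state, sheet$topology,
                                           sheet$bonds[r, 1:2]), "parallel")
  }
  # rotate the second strand end-over-end: bonds become antiparallel
  st <- sheet$state
  ns <- nrow(st$pos) / 2
  idx <- (ns + 1):(2 * ns)
  ctr <- colMeans(st$pos[idx, ])
  rot <- diag(c(-1, -1, 1))            # proper rotation (det +1)
  st$pos[idx, ] <- sweep(sweep(st$pos[idx, ], 2, ctr) %*% rot, 2, ctr, "+")
  lab <- classify_bond_orientation(st, sheet$topology, sheet$bonds[2, 1:2])
  expect_equal(lab, "antiparallel")
  # terminal residues are unclassifiable
  topo <- sheet$topology
  rsi <- primedmd:::residue_sphere_index(topo)
  last_res <- nrow(rsi)
  expect_true(is.na(classify_bond_orientation(
    sheet$state, topo, c(rsi[1, "NH"], rsi[last_res, "CO"]))))
})

test_that("engine registries stay single-bond consistent with exact energy", {
  topo <- build_chain("VQIVYK", FF)
  cfg <- simulation_config(n_chains = 2, box_length = 35, seed = 1)
  gen <- generate_initial_configuration(topo, FF, cfg)
  set.seed(1)
  run <- dmd_run(gen$state, gen$topology, FF, budget = 8e5,
                 t_start = 0.5, t_final = 0.2, cool_events = 2e5,
                 sample_interval = 50)
  for (f in run$frames) {
    if (nrow(f$bonds) == 0) next
    expect_equal(anyDuplicated(f$bonds[, 1]), 0)  # one bond per NH
    expect_equal(anyDuplicated(f$bonds[, 2]), 0)  # one bond per CO
    roles <- gen$topology$spheres$role
    expect_true(all(roles[f$bonds[, 1]] == "NH"))
    expect_true(all(roles[f$bonds[, 2]] == "CO"))
    # the hydrogen-bond term of the energy equals -1 per registered bond
    st <- make_state(f$pos, box = gen$state$box)
    e_with <- total_energy(st, registry = f$bonds, tables = run$tables)
    e_without <- total_energy(st, registry = NULL, tables = run$tables)
    expect_equal(e_with - e_without, -nrow(f$bonds))
  }
  expect_gte(run$counters[["hb_formed"]], run$counters[["hb_broken"]])
  expect_equal(run$counters[["hb_formed"]] - run$counters[["hb_broken"]],
               nrow(run$registry))
})
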