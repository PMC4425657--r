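# Force-field loading, pair potentials, hydrogen-bond cutoff sets and the
# well-diameter derivation rule.

test_that("published interaction constants load exactly", {
  expect_identical(pair_potential(FF, "F", "F")$e_base, 0.205)
  expect_identical(pair_potential(FF, "K", "D")$e_base, 0.4)
  expect_identical(pair_potential(FF_ORIG, "K", "D")$e_base, 0.136)
  expect_identical(FF$mult_inner, 1.3)
  expect_identical(FF$mult_outer, 0.7)
  expect_identical(unname(hbond_cutoffs(FF, "parallel_preference")$cutoffs[["n_ca"]]), 5.10)
  expect_identical(unname(hbond_cutoffs(FF, "original")$cutoffs[["n_ca"]]), 5.00)
  expect_identical(FF$backbone$mass_co, 1.863)
  expect_identical(FF$backbone$mass_nh, 0.999)
  expect_identical(FF$backbone$mass_ca, 0.866)
})

test_that("published side-chain masses are in the geometry table", {
  m <- side_mass_vec(FF)
  expect_equal(m[["A"]], 1.000)
  expect_equal(m[["R"]], 6.728)
  expect_equal(m[["Y"]], 7.126)
  expect_equal(m[["S"]], 2.064)
  expect_equal(m[["V"]], 2.866)
})

test_that("pair table is symmetric with ordered, scaled double wells", {
  aa <- setdiff(AA_LETTERS, "G")
  for (a in aa) for (b in aa) {
    p <- pair_potential(FF, a, b)
    q <- pair_potential(FF, b, a)
    expect_identical(p, q)
    expect_lt(p$d_core, p$d_inner)
    expect_lt(p$d_inner, p$d_outer)
    expect_equal(p$e_inner, 1.3 * p$e_base)
    expect_equal(p$e_outer, 0.7 * p$e_base)
  }
})

test_that("salt-bridge enhancement changes only the K-D pair", {
  aa <- setdiff(AA_LETTERS, "G")
  for (a in aa) for (b in aa) {
    p1 <- pair_potential(FF, a, b)$e_base
    p0 <- pair_potential(load_forcefield(salt_bridge_enhanced = FALSE), a, b)$e_base
    if ((a == "K" && b == "D") || (a == "D" && b == "K")) {
      expect_identical(c(p1, p0), c(0.4, 0.136))
    } else {
      expect_identical(p1, p0)
    }
  }
})

test_that("invalid force-field queries are rejected", {
  expect_error(pair_potential(FF, "G", "A"), "glycine")
  expect_error(pair_potential(FF, "X", "A"), "unknown residue")
  expect_error(hbond_cutoffs(FF, "antiparallel"), "unknown hydrogen-bond")
})

test_that("well diameters derive from the strict heavy-atom majority rule", {
  # all centroids qualify: the default statistic is the maximum
  centroids <- c(5.0, 5.5, 6.0)
  heavy <- list(c(4, 4.2), c(4.1, 4.4), c(4, 4.3))
  expect_equal(derive_well_diameter(centroids, heavy, cutoff = 4.5), 6.0)
  # exactly half below the cutoff does not qualify ('over half' is strict)
  heavy2 <- list(c(4, 5), c(4.1, 4.4), c(4, 4.3))
  expect_equal(derive_well_diameter(centroids, heavy2, cutoff = 4.5), 6.0)
  heavy3 <- list(c(4, 5), c(4, 5), c(4.6, 5))
  expect_error(derive_well_diameter(centroids, heavy3, cutoff = 4.5),
               "no sample qualifies")
  # quantile statistic
  expect_equal(derive_well_diameter(centroids, heavy, 4.5, statistic = 0.5), 5.5)
})

test_that("a force field writes and reloads identically", {
  dir <- withr::local_tempdir()
  write_forcefield(FF, dir)
  ff2 <- load_forcefield(dir)
  expect_equal(ff2$eps, FF$eps)
  expect_equal(ff2$d_inner, FF$d_inner)
  expect_equal(ff2$d_outer, FF$d_outer)
  expect_equal(ff2$geometry, FF$geometry)
  expect_equal(ff2$squeeze, FF$squeeze)
  expect_equal(ff2$hbond$cutoff_sets, FF$hbond$cutoff_sets)
  expect_equal(ff2$backbone, FF$backbone)
})
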