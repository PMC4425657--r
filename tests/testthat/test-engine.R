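# Event-driven engine: kinematics, impulse rules, conservation laws,
# thermostat, schedules, restart.

test_that("two-body event prediction is analytic", {
  fx <- fixture_well_pair(d_core = 3, d_well = 5, r0 = 8, v0 = 1)
  # head-on: the outer well is reached at t = (r0 - d_well) / v
  surf <- data.frame(d = c(3, 5), direction = c("in", "in"))
  ev <- predict_pair_event(fx$state, 1, 2, surf)
  expect_equal(ev$time, 3, tolerance = 1e-12)
  expect_equal(ev$surface, 2)
  # the engine agrees
  run <- dmd_run(fx$state, tables = fx$tables, budget = 1,
                 thermostat = FALSE, record_events = TRUE)
  expect_equal(run$events$time[1], 3, tolerance = 1e-12)

  # receding pair outside the well: no event
  fx$state$vel <- -fx$state$vel
  expect_null(predict_pair_event(fx$state, 1, 2, surf))
})

test_that("equal-mass head-on core collision exchanges velocities", {
  st <- make_state(rbind(c(10, 10, 10), c(13, 10, 10)),
                   rbind(c(1, 0, 0), c(-0.25, 0, 0)), box = 40)
  out <- apply_pair_impulse(st, 1, 2, 1, 1, reflect = TRUE)
  expect_equal(out$state$vel[1, ], c(-0.25, 0, 0))
  expect_equal(out$state$vel[2, ], c(1, 0, 0))
})

test_that("well capture converts well depth into kinetic energy", {
  # double well with the strongest hydrophobic pair depths
  e <- 0.205
  two <- function(v) matrix(c(0, v, v, 0), 2, 2)
  tab <- toy_tables(c(1, 1), radius = c(1.5, 1.5),
                    type = matrix(c(0L, 3L, 3L, 0L), 2, 2),
                    d1 = two(3), din = two(4), dout = two(5),
                    ein = two(-1.3 * e), eout = two(-0.7 * e))
  st <- make_state(rbind(c(10, 10, 10), c(16, 10, 10)),
                   rbind(c(0.5, 0, 0), c(0, 0, 0)), box = 40)
  run <- dmd_run(st, tables = tab, budget = 2, thermostat = FALSE,
                 record_events = TRUE, record_event_velocities = TRUE)
  ke0 <- 0.5 * 0.5^2
  ke_after_outer <- total_kinetic(
    make_state(st$pos, run$events$velocities[[1]]), tab$mass)
  ke_after_inner <- total_kinetic(
    make_state(st$pos, run$events$velocities[[2]]), tab$mass)
  expect_equal(ke_after_outer - ke0, 0.7 * e, tolerance = 1e-12)
  # inner capture from the outer shell releases (1.3 - 0.7) * eps
  expect_equal(ke_after_inner - ke_after_outer, 0.6 * e, tolerance = 1e-12)
})

test_that("an escape attempt without enough radial energy reflects", {
  st <- make_state(rbind(c(10, 10, 10), c(14, 10, 10)),
                   rbind(c(-0.1, 0.2, 0), c(0.1, 0, 0)), box = 40)
  out <- apply_pair_impulse(st, 1, 2, 1, 1, delta_u = 1)  # barrier 1 eps_HB
  expect_false(out$crossed)
  # radial component reversed, tangential untouched
  expect_equal(out$state$vel[1, ], c(0.1, 0.2, 0))
  expect_equal(out$state$vel[2, ], c(-0.1, 0, 0))
})

test_that("event sequences match a brute-force time-driven integrator", {
  e <- 0.4
  two <- function(v) matrix(c(0, v, v, 0), 2, 2)
  tab <- toy_tables(c(1, 2), radius = c(1.5, 1.5),
                    type = matrix(c(0L, 3L, 3L, 0L), 2, 2),
                    d1 = two(3), din = two(4.2), dout = two(5.5),
                    ein = two(-1.3 * e), eout = two(-0.7 * e))
  starts <- list(
    list(p = rbind(c(10, 10, 10), c(17, 10.8, 10)),
         v = rbind(c(0.6, -0.05, 0.02), c(-0.2, 0.1, 0))),
    list(p = rbind(c(10, 10, 10), c(15.5, 12, 10)),
         v = rbind(c(0.5, -0.35, 0), c(-0.3, 0.1, 0.05))))
  for (s in starts) {
    st <- make_state(s$p, s$v, box = 60)
    run <- dmd_run(st, tables = tab, budget = 12, thermostat = FALSE,
                   max_time = 30, record_events = TRUE,
                   record_event_velocities = TRUE)
    keep <- run$events$kind == 0
    or <- oracle_two_body(st, tab$mass, boundaries = c(3, 4.2, 5.5),
                          energy = c(Inf, -1.3 * e, -0.7 * e, 0),
                          tmax = 30)
    n <- min(sum(keep), length(or$times))
    expect_gt(n, 2)
    expect_equal(run$events$time[keep][seq_len(n)], or$times[seq_len(n)],
                 tolerance = 1e-4)
    for (k in seq_len(n)) {
      expect_equal(run$events$velocities[keep][[k]], or$velocities[[k]],
                   tolerance = 1e-4)
    }
  }
})

test_that("a bonded dimer conserves energy to 1e-9 over a million events", {
  fx <- fixture_bonded_dimer()
  e0 <- total_kinetic(fx$state, fx$tables$mass)
  run <- dmd_run(fx$state, tables = fx$tables, budget = 1e6, thermostat = FALSE)
  expect_equal(run$counters[["pair_events"]], 1e6)
  expect_lt(abs(run$ke + run$pe - e0), 1e-9)
  # momentum to machine precision
  p0 <- colSums(fx$tables$mass * fx$state$vel)
  p1 <- colSums(fx$tables$mass * run$state$vel)
  expect_lt(max(abs(p1 - p0)), 1e-12)
})

test_that("ghost collisions thermalise to (3/2) kB T* per sphere", {
  set.seed(3)
  st <- make_state(matrix(runif(30, 0, 20), 10, 3), matrix(0, 10, 3), box = 20)
  ke <- replicate(4000, {
    s <- ghost_collision(st, sample(10, 1), mass = 2, tstar = 0.20)
    total_kinetic(s, rep(2, 10))
  })
  expect_equal(mean(ke), 1.5 * 0.20, tolerance = 0.05)
  expect_error(ghost_collision(st, 1, 1, tstar = 0), "positive")
  set.seed(5); v1 <- ghost_collision(st, 1, 1, 0.2)$vel[1, ]
  set.seed(5); v2 <- ghost_collision(st, 1, 1, 0.2)$vel[1, ]
  expect_identical(v1, v2)
})

test_that("reduced time follows t* = t / sigma * sqrt(kB T / m)", {
  expect_equal(reduced_time(0, 0.2, FF), 0)
  t1 <- reduced_time(10, 0.2, FF)
  expect_equal(reduced_time(20, 0.2, FF), 2 * t1)
  ff2 <- FF; ff2$sigma <- 2 * FF$sigma
  expect_equal(reduced_time(10, 0.2, ff2), t1 / 2)
  expect_equal(t1, 10 / 3.3 * sqrt(0.2 / 0.999))
})

test_that("budget zero returns the initial state unchanged", {
  fx <- fixture_well_pair()
  run <- dmd_run(fx$state, tables = fx$tables, budget = 0, thermostat = FALSE)
  expect_identical(run$state$pos, fx$state$pos)
  expect_identical(run$state$vel, fx$state$vel)
  expect_equal(run$counters[["pair_events"]], 0)
})

test_that("cooling is monotone and the kinetic temperature lands on T*", {
  topo <- build_chain("VQIVYK", FF)
  cfg <- simulation_config(n_chains = 1, box_length = 40, seed = 9,
                           t_start = 0.5, t_final = 0.2)
  gen <- generate_initial_configuration(topo, FF, cfg)
  set.seed(9)
  run <- dmd_run(gen$state, gen$topology, FF, budget = 4e5,
                 t_start = 0.5, t_final = 0.2, cool_events = 2e5,
                 energy_interval = 2)
  expect_true(all(diff(run$energy$tstar) <= 1e-12))
  expect_equal(run$state$tstar, 0.2)
  n <- nrow(gen$state$pos)
  late <- run$energy[run$energy$tstar == 0.2, ]
  expect_gt(nrow(late), 50)
  expect_equal(mean(late$ke) / (1.5 * n), 0.2, tolerance = 0.05)
  # no constraint is violated in the final state and chirality is intact
  expect_equal(nrow(validate_geometry(run$state, gen$topology, FF,
                                      tables = run$tables)), 0)
})

test_that("runs are deterministic under a fixed seed", {
  topo <- build_chain("AVA", FF)
  cfg <- simulation_config(n_chains = 1, box_length = 30, seed = 4)
  gen <- generate_initial_configuration(topo, FF, cfg)
  set.seed(21)
  r1 <- dmd_run(gen$state, gen$topology, FF, budget = 5e4,
                t_start = 0.3, t_final = 0.3)
  set.seed(21)
  r2 <- dmd_run(gen$state, gen$topology, FF, budget = 5e4,
                t_start = 0.3, t_final = 0.3)
  expect_identical(r1$state$pos, r2$state$pos)
  expect_identical(r1$state$vel, r2$state$vel)
})

test_that("checkpoint and restart continue event-identically", {
  topo <- build_chain("AVA", FF)
  cfg <- simulation_config(n_chains = 1, box_length = 30, seed = 4)
  gen <- generate_initial_configuration(topo, FF, cfg)
  tab <- build_interaction_tables(gen$topology, FF)

  set.seed(33)
  full <- dmd_run(gen$state, tables = tab, budget = 4e4,
                  t_start = 0.3, t_final = 0.3)

  set.seed(33)
  half <- dmd_run(gen$state, tables = tab, budget = 2e4,
                  t_start = 0.3, t_final = 0.3)
  path <- withr::local_tempfile()
  write_checkpoint(half, path)
  ck <- read_checkpoint(path)
  rest <- dmd_run(ck$state, tables = tab, budget = 2e4,
                  t_start = 0.3, t_final = 0.3,
                  registry = ck$registry,
                  pair_events_done = ck$pair_events_total,
                  next_ghost_time = ck$next_ghost_time)
  expect_equal(rest$state$time, full$state$time, tolerance = 1e-12)
  expect_equal(rest$state$pos, full$state$pos, tolerance = 1e-12)
  expect_equal(rest$state$vel, full$state$vel, tolerance = 1e-12)
})

test_that("tracked interaction energy matches a from-scratch recomputation", {
  topo <- build_chain("VQIVYK", FF)
  cfg <- simulation_config(n_chains = 2, box_length = 40, seed = 5)
  gen <- generate_initial_configuration(topo, FF, cfg)
  set.seed(5)
  run <- dmd_run(gen$state, gen$topology, FF, budget = 3e5,
                 t_start = 0.5, t_final = 0.2, cool_events = 1e5)
  e2 <- total_energy(run$state, registry = run$registry, tables = run$tables)
  expect_equal(run$pe, e2, tolerance = 1e-9)
})
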