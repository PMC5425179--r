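test_that("gamma = 0 limit conserves energy (symplectic leap-frog)", {
  ff <- forcefield(dimer_topology())
  cfg <- sim_config(120, n_steps = 1e5, dt = 5e-4, seed = 3,
                    record_stride = 500)
  cfg$gamma <- 0
  tr <- integrate_langevin(dimer_coords, ff, cfg)
  E <- tr$epot + tr$ekin
  expect_gt(abs(mean(E)), 0.1)  # started with thermal kinetic energy
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-4)
})

test_that("same seed gives bit-identical trajectories", {
  ff <- fx_ff()
  s <- fx_trefoil()
  cfg <- sim_config(150, n_steps = 5e3, seed = 77, record_stride = 500)
  t1 <- integrate_langevin(s$coords, ff, cfg)
  t2 <- integrate_langevin(s$coords, ff, cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$final_vel, t2$final_vel)
  cfg2 <- cfg; cfg2$seed <- 78
  t3 <- integrate_langevin(s$coords, ff, cfg2)
  expect_false(identical(t1$final_coords, t3$final_coords))
})

test_that("trajectory frame bookkeeping", {
  ff <- fx_ff()
  s <- fx_trefoil()
  tr <- integrate_langevin(s$coords, ff,
                           sim_config(120, n_steps = 10100,
                                      record_stride = 1000, seed = 5))
  expect_equal(n_frames(tr), floor(10100 / 1000) + 1)
  expect_equal(tr$step, seq(0, 10000, by = 1000))
  expect_equal(frame_coords(tr, 1), unname(s$coords))
  expect_true(all(is.finite(tr$frames)))
})

test_that("thermostat equipartition on a 20-bead chain", {
  ## (the 2% harmonic position-variance check runs in test-acceptance.R)
  TT <- 120
  s20 <- make_unknotted_chain(20, seed = 4)
  topo20 <- build_native_topology(s20)
  ff20 <- forcefield(topo20)
  tr20 <- integrate_langevin(s20$coords, ff20,
                             sim_config(TT, n_steps = 2e6, seed = 19,
                                        record_stride = 200))
  ke_dof <- mean(tr20$ekin[-(1:500)]) / (3 * 20)
  expect_lt(abs(ke_dof / (kB * TT / 2) - 1), 0.02)
})

test_that("free-particle velocity distribution is Maxwell-Boltzmann", {
  ## OU stationary law: each velocity component has variance kB T / m.
  ## A bead pair at huge separation with no contacts is effectively free
  ## apart from the (slack) bond - use one real bond at its minimum and
  ## look at the center-of-mass velocity, which is exactly free.
  ff <- forcefield(dimer_topology())
  TT <- 150
  tr <- integrate_langevin(dimer_coords, ff,
                           sim_config(TT, n_steps = 1e6, seed = 8,
                                      record_stride = 1000))
  ## total Ekin has 6 dofs; time-average within 3 SE of 3 kB T
  ke <- tr$ekin[-(1:50)]
  n_eff <- length(ke) / 3  # ~2000-step velocity correlation at gamma = 1
  se <- sd(ke) / sqrt(n_eff)
  expect_lt(abs(mean(ke) - 3 * kB * TT), 3 * se + 0.01 * kB * TT)
})

test_that("cage containment: caged run never leaves the cylinder", {
  s <- fx_trefoil()
  cage <- cage_spec(2.6)
  ff <- forcefield(fx_topology(), cage = cage)
  x0 <- fit_to_cage(s$coords, cage, clearance = 1)
  tr <- integrate_langevin(x0, ff, sim_config(200, n_steps = 2e5,
                                              record_stride = 500, seed = 31))
  for (i in seq_len(n_frames(tr))) {
    expect_true(all(wall_distance(frame_coords(tr, i), cage) > 0))
  }
  ## a start outside the cage is rejected outright
  expect_error(integrate_langevin(s$coords * 3, ff,
                                  sim_config(150, n_steps = 100, seed = 1)),
               "outside cage")
  ## an infeasible cage is refused by fit_to_cage
  expect_error(fit_to_cage(s$coords, cage_spec(1.2)), "outside cage")
})

test_that("generate_unfolded_pool respects the Q threshold", {
  s <- fx_trefoil()
  topo <- fx_topology()
  ff <- fx_ff()
  pool <- generate_unfolded_pool(s, ff, T_high = 300, pool_size = 5,
                                 q_max = 0.2, seed = 6, min_gap = 1e4,
                                 max_steps = 2e6)
  expect_length(pool, 5L)
  for (x in pool) expect_lt(fraction_native(x, topo), 0.2)
  ## q_max = 1: every harvested frame qualifies, pool fills in one chunk
  pool2 <- generate_unfolded_pool(s, ff, T_high = 300, pool_size = 3,
                                  q_max = 1, seed = 6, min_gap = 1000,
                                  max_steps = 1e5)
  expect_length(pool2, 3L)
  ## infeasible budget errors with the achieved count
  expect_error(
    generate_unfolded_pool(s, ff, T_high = 100, pool_size = 50,
                           q_max = 0.01, seed = 6, min_gap = 1000,
                           max_steps = 2e4),
    "unfolded pool exhausted")
})

test_that("run_protocol: starts, seeds, determinism", {
  s <- fx_trefoil()
  ff <- fx_ff()
  cfg <- sim_config(150, n_steps = 2e3, seed = 42, record_stride = 500)
  eq <- run_protocol("equilibrium", s, ff, cfg, n_replicas = 3)
  expect_length(eq, 3L)
  for (tr in eq) {
    expect_equal(frame_coords(tr, 1), unname(s$coords))
    expect_equal(tr$protocol, "equilibrium")
  }
  ## frame 0 of an equilibrium run has Q = 1
  expect_equal(fraction_native(frame_coords(eq[[1]], 1), fx_topology()), 1)
  ## distinct replicas differ; same master seed reproduces the set
  expect_false(identical(eq[[1]]$final_coords, eq[[2]]$final_coords))
  eq2 <- run_protocol("equilibrium", s, ff, cfg, n_replicas = 3)
  expect_identical(eq[[2]]$frames, eq2[[2]]$frames)

  ## folding protocol starts from the pool
  pool <- list(s$coords + 1, s$coords + 2)
  fo <- run_protocol("folding", s, ff, cfg, n_replicas = 2, pool = pool)
  expect_equal(frame_coords(fo[[1]], 1), unname(s$coords + 1))
  expect_equal(frame_coords(fo[[2]], 1), unname(s$coords + 2))
  expect_error(run_protocol("folding", s, ff, cfg), "needs a pool")
})

test_that("trajectory text container round-trips", {
  s <- fx_trefoil()
  ff <- fx_ff()
  tr <- integrate_langevin(s$coords, ff,
                           sim_config(130, n_steps = 5e3,
                                      record_stride = 1000, seed = 2))
  tf <- withr::local_tempfile(fileext = ".traj")
  write_trajectory(tr, tf)
  tr2 <- read_trajectory(tf)
  expect_equal(tr2$n_beads, tr$n_beads)
  expect_equal(tr2$step, tr$step)
  expect_equal(tr2$epot, tr$epot, tolerance = 1e-9)
  expect_equal(tr2$frames, tr$frames, tolerance = 1e-5)
  expect_equal(tr2$config$temperature, 130)
})
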