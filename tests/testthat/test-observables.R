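test_that("fraction_native threshold behaviour at 1.2 r0", {
  s <- fx_trefoil()
  topo <- fx_topology()
  expect_equal(fraction_native(s$coords, topo), 1)
  ## scale all coordinates: every contact distance scales together
  expect_equal(fraction_native(s$coords * 1.19, topo), 1)
  expect_equal(fraction_native(s$coords * 1.21, topo), 0)

  ## constructed configuration with exactly half the contacts broken:
  ## brute-force count agrees
  set.seed(3)
  x <- s$coords * 1.1  # some formed, some broken (r0 spread vs uniform scale)
  cnt <- sum(sqrt(rowSums((x[topo$contacts[, 1], ] -
                             x[topo$contacts[, 2], ])^2)) <
               1.2 * topo$contact_r0)
  expect_equal(fraction_native(x, topo), cnt / nrow(topo$contacts))

  empty <- structure(list(n_beads = 5L, bond_r0 = rep(3.8, 4),
                          angle_th0 = rep(2, 3), dihedral_phi0 = rep(1, 2),
                          contacts = matrix(integer(0), ncol = 2),
                          contact_r0 = numeric(0), min_sep = 4L,
                          residue_ids = 1:5, chain_id = "A"),
                     class = "native_topology")
  expect_error(fraction_native(s$coords[1:5, ], empty), "no contacts")
})

test_that("radius of gyration: closed forms and trace identity", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  expect_equal(radius_of_gyration(matrix(5, 4, 3)), 0)
  set.seed(11)
  x <- matrix(rnorm(60), 20, 3)
  ## independent definition: sqrt of the gyration-tensor trace
  S <- crossprod(sweep(x, 2, colMeans(x))) / nrow(x)
  expect_equal(radius_of_gyration(x), sqrt(sum(diag(S))), tolerance = 1e-12)
})

test_that("asphericity limits: rod 1, octahedron 0, square 1/4", {
  rod <- cbind(seq(0, 38, by = 3.8), 0, 0)
  expect_equal(asphericity(rod), 1, tolerance = 1e-12)
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(asphericity(oct), 0, tolerance = 1e-12)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(asphericity(sq), 0.25, tolerance = 1e-12)
  expect_error(asphericity(matrix(1, 3, 3)), "degenerate")
})

test_that("Q, Rg, asphericity invariances under rigid motions and scaling", {
  s <- fx_trefoil()
  topo <- fx_topology()
  set.seed(21)
  x <- s$coords + matrix(rnorm(105, sd = 0.4), ncol = 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  y <- sweep(x %*% R, 2, c(10, -4, 2), "+")
  expect_equal(fraction_native(y, topo), fraction_native(x, topo))
  expect_equal(radius_of_gyration(y), radius_of_gyration(x),
               tolerance = 1e-10)
  expect_equal(asphericity(y), asphericity(x), tolerance = 1e-10)
  ## uniform scaling: Rg linear, asphericity invariant
  expect_equal(radius_of_gyration(x * 2.5), 2.5 * radius_of_gyration(x),
               tolerance = 1e-10)
  expect_equal(asphericity(x * 2.5), asphericity(x), tolerance = 1e-10)
})

test_that("observable_series and strided knot evaluation", {
  s <- fx_trefoil()
  topo <- fx_topology()
  ff <- fx_ff()
  traj <- integrate_langevin(s$coords, ff,
                             sim_config(100, n_steps = 2e4,
                                        record_stride = 200, seed = 9))
  expect_equal(n_frames(traj), 101L)
  ser <- observable_series(traj, topo, knot_stride = 10, seed = 4)
  expect_equal(nrow(ser), 101L)
  expect_equal(sum(ser$knot_label != "unevaluated"), 11L)
  expect_true(all(is.na(ser$knotted[ser$knot_label == "unevaluated"])))
  ## a cold equilibrium run stays in the native (knotted) basin
  expect_true(all(ser$Q > 0.8))
  evaluated <- ser$knot_label[ser$knot_label != "unevaluated"]
  expect_true(all(evaluated == "3_1"))
  ## frame 0 is native
  expect_equal(ser$Q[1], 1)

  ## unknotted control stays unknotted
  un <- fx_unknot()
  topo_u <- build_native_topology(un)
  traj_u <- integrate_langevin(un$coords, forcefield(topo_u),
                               sim_config(100, n_steps = 1e4,
                                          record_stride = 1000, seed = 9))
  ser_u <- observable_series(traj_u, topo_u, knot_stride = 1, seed = 4)
  expect_true(all(ser_u$knot_label == "0_1"))
})

test_that("pk_profile: bins, absent bins, constructed mixtures", {
  ## knotted flag exactly (Q > 0.5): P_K steps 0 -> 1 at the boundary
  ser <- data.frame(Q = seq(0.01, 0.99, length.out = 200))
  ser$knotted <- ser$Q > 0.5
  pk <- pk_profile(ser, bin_width = 0.05)
  occ <- !is.na(pk$P_K)
  expect_true(all(pk$P_K[occ & pk$Q_hi <= 0.5] == 0))
  expect_true(all(pk$P_K[occ & pk$Q_lo >= 0.5] == 1))

  ## all-knotted series
  ser$knotted <- TRUE
  pk1 <- pk_profile(ser)
  expect_true(all(pk1$P_K[!is.na(pk1$P_K)] == 1))

  ## absent bins are NA, not zero
  ser2 <- data.frame(Q = c(0.1, 0.12, 0.9), knotted = c(FALSE, FALSE, TRUE))
  pk2 <- pk_profile(ser2)
  expect_true(is.na(pk2$P_K[pk2$Q_lo == 0.5]))
  expect_equal(pk2$n_frames[pk2$Q_lo == 0.5], 0)

  ## seeded mixture: per-bin knot fraction matches construction within
  ## binomial error
  set.seed(31)
  q <- runif(4000)
  p_true <- pmin(1, pmax(0, (q - 0.3) / 0.4))
  kn <- runif(4000) < p_true
  pk3 <- pk_profile(data.frame(Q = q, knotted = kn))
  for (b in which(!is.na(pk3$P_K) & pk3$n_frames > 100)) {
    p_bin <- mean(p_true[q >= pk3$Q_lo[b] & q < pk3$Q_hi[b]])
    se <- sqrt(p_bin * (1 - p_bin) / pk3$n_frames[b]) + 1e-9
    expect_lt(abs(pk3$P_K[b] - p_bin), 5 * se + 0.02)
  }
})
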