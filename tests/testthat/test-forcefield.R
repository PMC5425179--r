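test_that("cage potential matches its closed form and cutoff", {
  spec <- cage_spec(2)  # L = 2 nm, eps_c = 10, cutoff 2 A
  expect_equal(cage_potential(2.0, spec), 0)
  expect_equal(cage_potential(1.0, spec), 90)  # 10 * (16 - 8 + 1)
  expect_equal(cage_potential(3.0, spec), 0)
  expect_error(cage_potential(-0.1, spec), "outside cage")

  ## strictly decreasing on (0, cutoff); divergence towards the wall
  d <- seq(0.05, 1.999, length.out = 200)
  v <- cage_potential(d, spec)
  expect_true(all(diff(v) < 0))
  expect_gt(cage_potential(1e-3, spec), 1e10)

  ## continuity of V and V' at the cutoff
  h <- 1e-6
  expect_lt(cage_potential(2 - h, spec), 1e-10)
  dV <- (cage_potential(2 - h, spec) - cage_potential(2 - 2 * h, spec)) / h
  expect_lt(abs(dV), 1e-4)
})

test_that("wall distances for the cylinder geometry", {
  spec <- cage_spec(2)  # 2 nm => 20 A
  expect_equal(unname(wall_distance(c(0, 0, 0), spec)[1, ]), c(20, 20, 20))
  expect_equal(unname(wall_distance(c(0, 0, 19), spec)[1, 2:3]), c(1, 39))
  ## 3-4-5 scaling: rho = 20 on the lateral wall
  expect_equal(unname(wall_distance(c(12, 16, 0), spec)[1, 1]), 0)
})

test_that("total_energy: native reference values and independent oracle", {
  s <- fx_trefoil()
  topo <- fx_topology()
  ff <- fx_ff()
  e <- total_energy(s$coords, ff)
  ## bonded terms vanish at the native geometry; contacts contribute -eps
  expect_equal(unname(e$components["bond"]), 0, tolerance = 1e-12)
  expect_equal(unname(e$components["angle"]), 0, tolerance = 1e-12)
  expect_equal(unname(e$components["dihedral"]), 0, tolerance = 1e-10)
  expect_equal(unname(e$components["contact"]), -nrow(topo$contacts),
               tolerance = 1e-6)
  expect_lt(e$total, 0)

  ## independent R-side term-by-term oracle on a perturbed configuration
  set.seed(42)
  x <- s$coords + matrix(rnorm(length(s$coords), sd = 0.25), ncol = 3)
  e2 <- total_energy(x, ff)
  eref <- local({
    n <- nrow(x)
    dvec <- function(i, j) x[j, ] - x[i, ]
    bond <- sum(vapply(seq_len(n - 1), function(i) {
      r <- sqrt(sum(dvec(i, i + 1)^2)); 0.5 * 100 * (r - topo$bond_r0[i])^2
    }, numeric(1)))
    ang <- sum(vapply(seq_len(n - 2), function(i) {
      th <- knotcage:::bead_angle(x[i, ], x[i + 1, ], x[i + 2, ])
      0.5 * 20 * (th - topo$angle_th0[i])^2
    }, numeric(1)))
    kd <- ff$k_dihedral[1]
    dih <- sum(vapply(seq_len(n - 3), function(i) {
      ph <- knotcage:::bead_dihedral(x[i, ], x[i + 1, ], x[i + 2, ], x[i + 3, ])
      dp <- ph - topo$dihedral_phi0[i]
      kd * ((1 - cos(dp)) + 0.5 * (1 - cos(3 * dp)))
    }, numeric(1)))
    con <- sum(vapply(seq_len(nrow(topo$contacts)), function(k) {
      r <- sqrt(sum(dvec(topo$contacts[k, 1], topo$contacts[k, 2])^2))
      G <- exp(-(r - topo$contact_r0[k])^2 / (2 * 0.5^2))
      (1 + (4 / r)^12) * (1 - G) - 1
    }, numeric(1)))
    nn <- sum(apply(ff$nonnative, 1, function(p) {
      r <- sqrt(sum(dvec(p[1], p[2])^2))
      if (r >= 10) 0 else (4 / r)^12 - (4 / 10)^12
    }))
    bond + ang + dih + con + nn
  })
  expect_equal(e2$total, eref, tolerance = 1e-9)
})

test_that("analytic forces match central finite differences", {
  s <- fx_trefoil()
  ff <- fx_ff()
  set.seed(7)
  x <- s$coords + matrix(rnorm(length(s$coords), sd = 0.3), ncol = 3)
  f <- forces(x, ff)
  h <- 1e-5
  idx <- sample(nrow(x), 8)
  for (i in idx) {
    for (k in 1:3) {
      xp <- x; xp[i, k] <- xp[i, k] + h
      xm <- x; xm[i, k] <- xm[i, k] - h
      fd <- -(total_energy(xp, ff)$total - total_energy(xm, ff)$total) / (2 * h)
      expect_lt(abs(fd - f[i, k]), 1e-5)
    }
  }
  ## native forces ~ 0, total force is always zero (no cage)
  f0 <- forces(s$coords, ff)
  expect_lt(max(abs(colSums(f))), 1e-9)
  expect_lt(max(abs(f0[5:30, ])), 0.05)  # core beads: only tiny nn repulsion

  ## caged configuration: finite differences across the wall region
  ffc <- forcefield(fx_topology(), cage = cage_spec(2.6))
  xc <- sweep(s$coords, 2, colMeans(s$coords))
  fc <- forces(xc, ffc)
  for (i in idx[1:4]) {
    for (k in 1:3) {
      xp <- xc; xp[i, k] <- xp[i, k] + h
      xm <- xc; xm[i, k] <- xm[i, k] - h
      fd <- -(total_energy(xp, ffc)$total - total_energy(xm, ffc)$total) / (2 * h)
      expect_lt(abs(fd - fc[i, k]), 1e-5)
    }
  }
})

test_that("energy invariances: rigid motions, cage axis symmetry", {
  s <- fx_trefoil()
  ff <- fx_ff()
  set.seed(9)
  x <- s$coords + matrix(rnorm(length(s$coords), sd = 0.2), ncol = 3)
  e0 <- total_energy(x, ff)$total
  expect_equal(total_energy(sweep(x, 2, c(5, -3, 11), "+"), ff)$total, e0,
               tolerance = 1e-10)
  for (i in 1:3) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    expect_equal(total_energy(x %*% R, ff)$total, e0, tolerance = 1e-10)
  }
  ## with cage: invariant under rotation about z only
  ffc <- forcefield(fx_topology(), cage = cage_spec(2.6))
  xc <- sweep(x, 2, colMeans(x))
  th <- 1.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(total_energy(xc %*% Rz, ffc)$total,
               total_energy(xc, ffc)$total, tolerance = 1e-9)
  ## bead at wall distance just beyond cutoff feels no cage force
  one <- total_energy(xc, ffc)$components["cage"]
  expect_equal(unname(one), 0)  # native fits with clearance > 2 A
})

test_that("single contact at r0 with small r_ex contributes -eps", {
  topo <- structure(list(
    n_beads = 6L, bond_r0 = rep(3.8, 5), angle_th0 = rep(2, 4),
    dihedral_phi0 = rep(1, 3),
    contacts = matrix(c(1L, 6L), ncol = 2, dimnames = list(NULL, c("i", "j"))),
    contact_r0 = 8.0, min_sep = 5L, residue_ids = 1:6, chain_id = "A"),
    class = "native_topology")
  ff <- forcefield(topo, r_ex = 1.0)
  ## place beads so the single contact sits exactly at r0, others far
  x <- cbind(c(0, 100, 200, 300, 400, 8), c(0, 0, 0, 0, 0, 0), 0)
  econ <- total_energy(x, ff)$components["contact"]
  expect_equal(unname(econ), -1, tolerance = (1 / 8)^12 * 2)
})

test_that("forcefield config round-trips", {
  ff <- fx_ff()
  tf <- withr::local_tempfile(fileext = ".cfg")
  write_forcefield_config(ff, tf)
  ff2 <- read_forcefield_config(tf)
  expect_equal(ff2$k_bond, ff$k_bond)
  expect_equal(ff2$topology$contact_r0, ff$topology$contact_r0,
               tolerance = 1e-9)
  set.seed(1)
  x <- fx_trefoil()$coords + matrix(rnorm(105, sd = 0.1), ncol = 3)
  expect_equal(total_energy(x, ff2)$total, total_energy(x, ff)$total,
               tolerance = 1e-8)
})
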