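# build a fake trajectory object directly from a list of coordinate frames
traj_from_frames <- function(frames, temperature = 150) {
  nf <- length(frames)
  n <- nrow(frames[[1]])
  arr <- array(0, dim = c(3, n, nf))
  for (i in seq_len(nf)) arr[, , i] <- t(frames[[i]])
  structure(list(frames = arr, step = seq_len(nf) * 1000,
                 epot = numeric(nf), ekin = numeric(nf),
                 final_coords = frames[[nf]], final_vel = NULL,
                 config = sim_config(temperature, n_steps = nf * 1000,
                                     record_stride = 1000),
                 n_beads = n), class = "kc_trajectory")
}

test_that("contact_profile: native frames, constructed formation schedule", {
  s <- fx_trefoil()
  topo <- fx_topology()
  ## all-native frames: S = 1 in the occupied bin
  traj <- traj_from_frames(rep(list(s$coords), 10))
  cp <- contact_profile(traj, topo)
  occ <- which(cp$bin_count > 0)
  expect_length(occ, 1L)
  expect_true(all(cp$S[, occ] == 1))
  expect_true(all(is.na(cp$S[, -occ])))

  ## constructed schedule: break contact k beyond threshold in half the
  ## frames by moving a single far bead pair apart is impractical on a
  ## real chain, so instead mix native with uniformly swollen frames
  frames <- c(rep(list(s$coords), 6), rep(list(s$coords * 1.21), 6))
  cp2 <- contact_profile(traj_from_frames(frames), topo)
  occ2 <- which(cp2$bin_count > 0)
  expect_length(occ2, 2L)  # Q = 1 bin and Q = 0 bin
  expect_true(all(cp2$S[, max(occ2)] == 1))
  expect_true(all(cp2$S[, min(occ2)] == 0))
})

test_that("detect_backtracking flags exactly the injected dip", {
  topo <- fx_topology()
  nc <- nrow(topo$contacts)
  nb <- 20L
  profile <- structure(list(
    S = matrix(rep(seq(0, 1, length.out = nb), each = nc), nc, nb),
    Q_mid = seq(0.025, 0.975, by = 0.05), bin_count = rep(100L, nb),
    contacts = topo$contacts, bin_width = 0.05, condition = "toy"),
    class = "contact_profile")
  ## monotone: no flags
  rep0 <- detect_backtracking(profile, threshold = 0.05)
  expect_equal(nrow(rep0$flags), 0L)
  expect_length(rep0$groups, 0L)

  ## inject a dip of 0.2 for contact 7 at bin 12
  p2 <- profile
  p2$S[7, 12] <- p2$S[7, 12] - 0.2
  rep2 <- detect_backtracking(p2, threshold = 0.05)
  ## the dip creates one negative diff (bin 11 -> 12); the rebound
  ## (12 -> 13) is positive, so exactly one flag at contact 7
  expect_equal(rep2$flags$contact, 7L)
  expect_equal(rep2$flags$Q_bin, p2$Q_mid[12])
  expect_equal(rep2$flags$diff, 1 / (nb - 1) - 0.2, tolerance = 1e-9)
  expect_length(rep2$groups, 1L)

  ## threshold above 1: nothing can be flagged
  expect_equal(nrow(detect_backtracking(p2, threshold = 1.1)$flags), 0L)
})

test_that("profile_difference: identity, algebra, incompatibility", {
  topo <- fx_topology()
  nc <- nrow(topo$contacts)
  mk <- function(S) structure(list(
    S = S, Q_mid = seq(0.025, 0.975, by = 0.05), bin_count = rep(10L, 20),
    contacts = topo$contacts, bin_width = 0.05, condition = ""),
    class = "contact_profile")
  set.seed(5)
  a <- mk(matrix(runif(nc * 20), nc, 20))
  expect_true(all(profile_difference(a, a)$diff == 0))
  b <- mk(1 - a$S)
  expect_equal(profile_difference(a, b)$diff, 2 * a$S - 1, tolerance = 1e-12)
  ## per-residue aggregate covers every residue that has contacts
  pr <- profile_difference(a, b)$per_residue
  expect_equal(nrow(pr), max(topo$contacts))
  touched <- sort(unique(as.vector(topo$contacts)))
  expect_true(all(!is.na(pr[touched, 1])))

  bad <- mk(matrix(runif(nc * 20), nc, 20))
  bad$Q_mid <- bad$Q_mid + 0.01
  expect_error(profile_difference(a, bad), "incompatible")
})

test_that("kabsch_rmsd: zero, symmetry, rigid-motion invariance", {
  set.seed(17)
  a <- matrix(rnorm(60), 20, 3)
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-10)
  b <- a + matrix(rnorm(60, sd = 0.5), 20, 3)
  expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-10)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  b_moved <- sweep(b %*% R, 2, c(8, -2, 5), "+")
  expect_equal(kabsch_rmsd(a, b_moved), kabsch_rmsd(a, b), tolerance = 1e-10)
  ## superposition really minimises: rmsd <= raw rms deviation
  expect_lte(kabsch_rmsd(a, b), sqrt(mean(rowSums((a - b)^2))) + 1e-12)
})

test_that("cluster_at_q equals brute-force leader assignment", {
  set.seed(23)
  base1 <- matrix(rnorm(45), 15, 3) * 3
  base2 <- base1 + 40  # translation alone does not separate after Kabsch
  base2 <- matrix(rnorm(45), 15, 3) * 3
  frames <- list()
  truth <- integer(0)
  for (i in 1:20) {
    which_conf <- (i %% 2) + 1L
    base <- if (which_conf == 1L) base1 else base2
    frames[[i]] <- base + matrix(rnorm(45, sd = 0.1), 15, 3)
    truth[i] <- which_conf
  }
  th <- 2.0
  cr <- cluster_at_q(frames, th)
  ## brute force re-implementation
  leaders <- list(frames[[1]])
  ass <- c(1L, integer(19))
  for (i in 2:20) {
    hit <- 0L
    for (k in seq_along(leaders)) {
      if (kabsch_rmsd(frames[[i]], leaders[[k]]) <= th) { hit <- k; break }
    }
    if (hit == 0L) { leaders[[length(leaders) + 1L]] <- frames[[i]]; hit <- length(leaders) }
    ass[i] <- hit
  }
  expect_equal(cr$assignment, ass)
  expect_equal(cr$n_clusters, 2L)
  expect_equal(cr$largest_fraction, max(tabulate(ass)) / 20)
  expect_equal(sum(cr$sizes), 20L)

  ## identical frames: one cluster, fraction 1
  cr1 <- cluster_at_q(rep(list(base1), 5), 0.5)
  expect_equal(cr1$n_clusters, 1L)
  expect_equal(cr1$largest_fraction, 1)
  expect_error(cluster_at_q(list(base1), 1), ">= 2 frames")

  ## largest-cluster fraction is non-decreasing in the threshold
  fr <- vapply(c(0.05, 0.5, 2, 10), function(t2)
    cluster_at_q(frames, t2)$largest_fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})
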