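## Parametric space curves used by the generators
trefoil_curve <- function(t) {
  cbind(sin(t) + 2 * sin(2 * t),
        cos(t) - 2 * cos(2 * t),
        -sin(3 * t))
}

figure_eight_curve <- function(t) {
  cbind((2 + cos(2 * t)) * cos(3 * t),
        (2 + cos(2 * t)) * sin(3 * t),
        sin(4 * t))
}

## sample n points equally spaced in arc length over [0, 2*pi), scaled so
## the mean consecutive chord equals bond_length
resample_closed_curve <- function(curve, n, bond_length) {
  tt <- seq(0, 2 * pi, length.out = 4096L)
  p <- curve(tt)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  want <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  idx <- findInterval(want, s, all.inside = TRUE)
  frac <- (want - s[idx]) / pmax(s[idx + 1L] - s[idx], 1e-12)
  pts <- p[idx, , drop = FALSE] +
    (p[idx + 1L, , drop = FALSE] - p[idx, , drop = FALSE]) * frac
  chords <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
  pts <- pts * bond_length / mean(chords)
  sweep(pts, 2, colMeans(pts))
}

## outward helix appended at `start`, first direction `axis`; curl sets
## the helix radius in Angstrom: small = nearly straight (long reach),
## large = compact curled tail that stays near the core
tail_helix <- function(start, axis, n, bond_length, phase = 0, curl = 1.2) {
  if (n == 0L) return(NULL)
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  r <- curl
  om <- 2 * asin(min(0.95 * bond_length, 1.17 * r) / (2 * r))
  if (!is.finite(om) || om <= 0) om <- 0.8
  rise <- sqrt(bond_length^2 - (2 * r * sin(om / 2))^2)
  k <- seq_len(n)
  off <- outer(rise * k, a) +
    outer(r * (cos(om * k + phase) - cos(phase)), e1) +
    outer(r * (sin(om * k + phase) - sin(phase)), e2)
  sweep(off, 2, start, `+`)
}

#' Synthetic trefoil-knotted Cα chain
#'
#' Builds a knotted toy chain from the parametric trefoil
#' `(sin t + 2 sin 2t, cos t - 2 cos 2t, -sin 3t)`, which is itself the
#' left-handed (`-3_1`) form (3D writhe about -3.4); it is mirrored
#' through the xy-plane for the right-handed variant. The curve is
#' arc-length-resampled to the bond length. The sampled core is trimmed from both ends until minimally
#' knotted (one more bead off either end unties it under the package's own
#' typing), then unknotted tails are appended as gentle outward helices,
#' so the constructed tail depths are exact ground truth for the
#' fingerprint scan. `n_beads` is a target: the returned chain has
#' `core + tail_N + tail_C` beads, where the minimal core size is set by
#' the curve geometry at the requested bond length (the generator searches
#' the sampling density so the total lands on `n_beads` whenever
#' feasible).
#'
#' @param n_beads target total bead count (>= 25).
#' @param handedness `"left"` (the knotted-protein form) or `"right"`.
#' @param tail_N,tail_C unknotted beads beyond the knot core at the N/C
#'   side (default 4 each).
#' @param bond_length consecutive bead distance, Angstrom (default 3.8).
#' @param seed seed for the knot-typing projections used while trimming.
#' @param tail_curl helix radius of the appended tails in Angstrom:
#'   the default 1.2 gives nearly straight outward tails; larger values
#'   (3-4) give compact curled tails that stay near the core, useful when
#'   the chain must fit a tight cage.
#' @return [ca_structure()] with attributes `core` (bead range of the
#'   knotted core), `tail_N`, `tail_C`, `handedness`.
#' @export
make_trefoil_chain <- function(n_beads = 35L, handedness = c("left", "right"),
                               tail_N = 4L, tail_C = 4L, bond_length = 3.8,
                               seed = 1L, tail_curl = 1.2) {
  handedness <- match.arg(handedness)
  n_beads <- as.integer(n_beads)
  tail_N <- as.integer(tail_N); tail_C <- as.integer(tail_C)
  if (n_beads < 25L) stop("spec infeasible: need >= 25 beads for a knotted chain")
  n_core_target <- n_beads - tail_N - tail_C
  if (n_core_target < 15L) stop("spec infeasible: tails leave too few core beads")

  is_31 <- function(x) {
    kd <- tryCatch(knot_type(x, n_projections = 9L, seed = seed),
                   error = function(e) NULL)
    !is.null(kd) && kd$knot_label == "3_1"
  }
  build_core <- function(n_sample) {
    core <- resample_closed_curve(trefoil_curve, n_sample, bond_length)
    ## the base parametrization is the left-handed (-3_1) form: its 3D
    ## writhe is -3.4; mirror through the xy-plane for the right-handed one
    if (handedness == "right") core[, 3] <- -core[, 3]
    if (!is_31(core)) return(NULL)
    ## trim to minimal knotted core
    while (nrow(core) > 15L && is_31(core[-1, , drop = FALSE])) {
      core <- core[-1, , drop = FALSE]
    }
    while (nrow(core) > 15L && is_31(core[-nrow(core), , drop = FALSE])) {
      core <- core[-nrow(core), , drop = FALSE]
    }
    core
  }

  ## search the sampling density so the trimmed core hits the target size
  core <- NULL
  for (extra in 0:12) {
    cand <- build_core(n_core_target + extra)
    if (!is.null(cand) && nrow(cand) == n_core_target) { core <- cand; break }
    if (is.null(core) && !is.null(cand)) core <- cand  # best effort fallback
  }
  if (is.null(core)) stop("spec infeasible: could not close a trefoil at this size")

  cen <- colMeans(core)
  nN <- tail_helix(core[1, ], core[1, ] - cen, tail_N, bond_length,
                   curl = tail_curl)
  nC <- tail_helix(core[nrow(core), ], core[nrow(core), ] - cen, tail_C,
                   bond_length, curl = tail_curl)
  coords <- rbind(if (!is.null(nN)) nN[rev(seq_len(nrow(nN))), , drop = FALSE],
                  core, nC)
  s <- ca_structure(coords, residue_names = "GLY", chain_id = "A")
  kd <- knot_type(s$coords, n_projections = 11L, seed = seed)
  if (kd$knot_label != "3_1") stop("spec infeasible: tails broke the knot")
  attr(s, "core") <- c(tail_N + 1L, tail_N + nrow(core))
  attr(s, "tail_N") <- tail_N
  attr(s, "tail_C") <- tail_C
  attr(s, "handedness") <- kd$chirality
  s
}

#' Synthetic unknotted helix-hairpin Cα chain
#'
#' A helix-loop-helix built as a unit-tangent walk: every bond is exactly
#' `bond_length`; the first helix runs up, a smooth hairpin turn reverses
#' the direction, and the second helix runs back down alongside the first,
#' giving a compact unknotted fold with inter-strand native contacts. The
#' seed only rotates the helix phase; bond geometry is seed-independent.
#'
#' @param n_beads total bead count (>= 10).
#' @param seed seed (helix phase).
#' @param bond_length bond length in Angstrom (default 3.8).
#' @return [ca_structure()]
#' @export
make_unknotted_chain <- function(n_beads = 35L, seed = 1L, bond_length = 3.8) {
  n_beads <- as.integer(n_beads)
  if (n_beads < 10L) stop("need >= 10 beads")
  phase <- with_seed_(seed, stats::runif(1, 0, 2 * pi))
  n_turn <- 6L
  n1 <- (n_beads - 1L - n_turn) %/% 2L
  n2 <- n_beads - 1L - n_turn - n1

  helix_tangent <- function(k, up = TRUE, ph = 0) {
    om <- 1.75  # ~100 degrees per residue
    r <- 2.28; pitch <- 1.5
    v <- c(-r * om * sin(om * k + ph), r * om * cos(om * k + ph),
           if (up) pitch else -pitch)
    v / sqrt(sum(v^2))
  }
  tangents <- lapply(seq_len(n1), helix_tangent, up = TRUE, ph = phase)
  ## hairpin: rotate the tangent by pi over n_turn steps about a fixed axis
  t_from <- tangents[[n1]]
  t_to <- helix_tangent(1, up = FALSE, ph = phase + pi)
  axis <- c(t_from[2] * t_to[3] - t_from[3] * t_to[2],
            t_from[3] * t_to[1] - t_from[1] * t_to[3],
            t_from[1] * t_to[2] - t_from[2] * t_to[1])
  if (sqrt(sum(axis^2)) < 1e-8) axis <- c(1, 0, 0)
  axis <- axis / sqrt(sum(axis^2))
  ang_tot <- acos(max(-1, min(1, sum(t_from * t_to))))
  rot_about <- function(v, a, th) {
    v * cos(th) + c(a[2] * v[3] - a[3] * v[2], a[3] * v[1] - a[1] * v[3],
                    a[1] * v[2] - a[2] * v[1]) * sin(th) +
      a * sum(a * v) * (1 - cos(th))
  }
  for (k in seq_len(n_turn)) {
    tangents[[n1 + k]] <- rot_about(t_from, axis, ang_tot * k / n_turn)
  }
  for (k in seq_len(n2)) {
    tangents[[n1 + n_turn + k]] <- helix_tangent(k, up = FALSE, ph = phase + pi)
  }
  coords <- matrix(0, n_beads, 3)
  for (k in seq_len(n_beads - 1L)) {
    coords[k + 1L, ] <- coords[k, ] + bond_length * tangents[[k]]
  }
  coords <- sweep(coords, 2, colMeans(coords))
  ca_structure(coords, residue_names = "ALA", chain_id = "A")
}

#' Deterministic fixture suite for tests and demos
#'
#' Regenerates, from a single seed, the small objects the test-suite
#' exercises end-to-end: left- and right-handed trefoil toys, a
#' figure-eight curve, an unknotted control, and a short equilibrium
#' trajectory of the knotted toy near its (bulk) folding temperature, in
#' the bulk and in one cage.
#'
#' @param seed master seed.
#' @param n_steps steps for the mini-trajectories (default 2e5).
#' @param temperature reduced temperature of the mini-trajectories
#'   (default 120, near the toy's folding transition).
#' @param cage_L cage size in nm for the caged mini-trajectory.
#' @return list: `trefoil_left`, `trefoil_right`, `figure_eight` (coords
#'   matrix), `unknotted`, `topology`, `ff_bulk`, `ff_cage`, `traj_bulk`,
#'   `traj_cage`.
#' @export
make_fixture_suite <- function(seed = 1L, n_steps = 2e5, temperature = 120,
                               cage_L = 2.4) {
  tl <- make_trefoil_chain(35L, "left", seed = derive_seed(seed, 1))
  tr <- make_trefoil_chain(35L, "right", seed = derive_seed(seed, 2))
  f8 <- resample_closed_curve(figure_eight_curve, 60L, 3.8)
  un <- make_unknotted_chain(35L, seed = derive_seed(seed, 3))
  topo <- build_native_topology(tl)
  ff_bulk <- forcefield(topo)
  ff_cage <- forcefield(topo, cage = cage_spec(cage_L))
  cfg <- function(sd) sim_config(temperature, n_steps = n_steps,
                                 record_stride = 1000L, seed = sd)
  traj_bulk <- integrate_langevin(tl$coords, ff_bulk, cfg(derive_seed(seed, 4)))
  x_cage <- fit_to_cage(tl$coords, ff_cage$cage, clearance = 1)
  traj_cage <- integrate_langevin(x_cage, ff_cage, cfg(derive_seed(seed, 5)))
  list(trefoil_left = tl, trefoil_right = tr, figure_eight = f8,
       unknotted = un, topology = topo, ff_bulk = ff_bulk,
       ff_cage = ff_cage, traj_bulk = traj_bulk, traj_cage = traj_cage)
}
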