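#' Simulation configuration
#'
#' Langevin leap-frog settings in reduced units: the time step is in units
#' of the natural time tau (default `0.0005 tau`), friction is given as an
#' inverse friction constant (reduced time; default 1.0, i.e.
#' `gamma = 1/tau`), temperature on the reduced scale of [kB].
#'
#' @param temperature reduced temperature (> 0).
#' @param n_steps number of integration steps.
#' @param dt time step (default 0.0005).
#' @param inverse_friction inverse friction constant (default 1.0).
#' @param seed integer seed; a run is bit-reproducible given its seed.
#' @param record_stride store every `record_stride`-th step (frame 0 is
#'   always stored).
#' @param masses per-bead masses (default 1; recycled).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(temperature, n_steps, dt = 0.0005,
                       inverse_friction = 1.0, seed = 1L,
                       record_stride = 1000L, masses = 1) {
  stopifnot(temperature > 0, n_steps >= 1, dt > 0, record_stride >= 1)
  structure(list(temperature = temperature, n_steps = as.numeric(n_steps),
                 dt = dt, inverse_friction = inverse_friction,
                 gamma = 1 / inverse_friction, seed = as.numeric(seed),
                 record_stride = as.integer(record_stride), masses = masses),
            class = "sim_config")
}

#' Langevin leap-frog integration
#'
#' Integrates the chain under the forcefield with the BAOAB-split Langevin
#' leap-frog: velocity half-kick, half drift, exact Ornstein-Uhlenbeck
#' friction/noise step, half drift, half-kick. One force evaluation per
#' step; at `gamma = 0` the scheme reduces to symplectic velocity Verlet.
#' Initial velocities are drawn from the Maxwell-Boltzmann distribution at
#' the run temperature (from the run seed) unless supplied.
#'
#' @param start n x 3 starting coordinates (Angstrom).
#' @param ff [forcefield()]
#' @param cfg [sim_config()]
#' @param vel0 optional n x 3 starting velocities.
#' @return object of class `kc_trajectory`: `frames` (3 x n x n_frames
#'   array), `step`, `epot`, `ekin`, `final_coords`, `final_vel`, `config`.
#' @export
integrate_langevin <- function(start, ff, cfg, vel0 = NULL) {
  stopifnot(inherits(ff, "forcefield"), inherits(cfg, "sim_config"))
  start <- as.matrix(start)
  n <- ff$topology$n_beads
  if (nrow(start) != n) stop("coords/topology size mismatch")
  if (!is.null(ff$cage)) {
    wd <- wall_distance(start, ff$cage)
    if (any(wd <= 0)) stop("bead outside cage")
  }
  masses <- rep_len(as.numeric(cfg$masses), n)
  res <- .integrate_cpp(start, vel0, ff_to_cpp(ff), cfg$dt, cfg$gamma,
                        kB * cfg$temperature, cfg$n_steps, cfg$record_stride,
                        cfg$seed, masses)
  structure(c(res, list(config = cfg, n_beads = n)), class = "kc_trajectory")
}

#' @export
print.kc_trajectory <- function(x, ...) {
  cat(sprintf("kc_trajectory: %d beads, %d frames (stride %d), T = %g\n",
              x$n_beads, length(x$step), x$config$record_stride,
              x$config$temperature))
  invisible(x)
}

#' Extract one frame of a trajectory as an n x 3 matrix
#' @param traj `kc_trajectory`
#' @param i frame index (1-based).
#' @export
frame_coords <- function(traj, i) {
  t(traj$frames[, , i])
}

#' Number of frames in a trajectory
#' @param traj `kc_trajectory`
#' @export
n_frames <- function(traj) length(traj$step)

#' Derive a replica seed from a master seed
#'
#' Fixed affine map used everywhere the package spawns sub-seeded work
#' (replicas, knot projections, pool harvesting), so a whole experiment
#' reproduces from one integer.
#'
#' @param master master seed.
#' @param i run index.
#' @return integer-valued seed below 2^31.
#' @export
derive_seed <- function(master, i) {
  (as.numeric(master) * 48271 + as.numeric(i) * 104729) %% 2147483629
}

#' Center and align coordinates for a cylindrical cage
#'
#' Moves the centroid to the origin and rotates the principal gyration
#' axis onto the cylinder (z) axis, the orientation that fits the
#' smallest cage. Errors if any bead still has non-positive wall
#' distance.
#'
#' @param coords n x 3 coordinates.
#' @param spec [cage_spec()]
#' @param clearance required minimal wall distance in Angstrom
#'   (default 0: strictly inside).
#' @return re-oriented n x 3 coordinate matrix.
#' @export
fit_to_cage <- function(coords, spec, clearance = 0) {
  x <- sweep(as.matrix(coords), 2, colMeans(coords))
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  x <- x %*% ev$vectors[, c(2, 3, 1)]  # largest-eigenvalue axis -> z
  wd <- wall_distance(x, spec)
  if (any(wd <= clearance)) {
    stop(sprintf("bead outside cage: need L >= %.2f nm",
                 (spec$L_A + clearance - min(wd)) / 10))
  }
  x
}

#' Generate a pool of unfolded starting conformations
#'
#' Runs the chain at a high temperature and harvests well-separated frames
#' (at least `min_gap` steps apart) with `Q < q_max` (default 0.2, the
#' condition imposed on folding starts). If the forcefield has a cage, the
#' high-temperature run itself is caged, so every pool member fits.
#'
#' @param s [ca_structure()] native structure (run start).
#' @param ff [forcefield()]
#' @param T_high high reduced temperature (above the folding temperature).
#' @param pool_size number of conformations wanted.
#' @param q_max maximum fraction of native contacts (default 0.2).
#' @param seed integer seed.
#' @param min_gap minimum separation between harvested frames, in steps.
#' @param max_steps step budget before giving up.
#' @return list of n x 3 coordinate matrices, length `pool_size`.
#' @export
generate_unfolded_pool <- function(s, ff, T_high, pool_size, q_max = 0.2,
                                   seed = 1L, min_gap = 1e4,
                                   max_steps = 200 * pool_size * min_gap) {
  stopifnot(q_max > 0, q_max <= 1)
  pool <- list()
  start <- s$coords
  vel <- NULL
  chunk <- 0L
  steps_done <- 0
  while (length(pool) < pool_size && steps_done < max_steps) {
    n_steps <- min(max(pool_size, 10) * min_gap, max_steps - steps_done)
    cfg <- sim_config(T_high, n_steps = n_steps, record_stride = min_gap,
                      seed = derive_seed(seed, chunk))
    traj <- integrate_langevin(start, ff, cfg, vel0 = vel)
    q <- series_q(traj, ff$topology)
    drop_first <- if (chunk == 0L) 1L else 1L  # frame 0 duplicates the start
    ok <- which(q < q_max)
    ok <- ok[ok > drop_first]
    for (i in ok) {
      if (length(pool) >= pool_size) break
      pool[[length(pool) + 1L]] <- frame_coords(traj, i)
    }
    start <- traj$final_coords
    vel <- traj$final_vel
    steps_done <- steps_done + n_steps
    chunk <- chunk + 1L
  }
  if (length(pool) < pool_size) {
    stop(sprintf("unfolded pool exhausted: %d of %d found within %g steps",
                 length(pool), pool_size, max_steps))
  }
  pool
}

#' Run a set of independent trajectories under a named protocol
#'
#' `equilibrium` and `unfolding` runs start from the native structure;
#' `folding` runs start from members of an unfolded pool. Each replica gets
#' a sub-seed derived from the master seed, so the whole set is
#' reproducible.
#'
#' @param kind `"equilibrium"`, `"folding"` or `"unfolding"`.
#' @param s [ca_structure()] native structure.
#' @param ff [forcefield()]
#' @param cfg [sim_config()] template (its seed acts as the master seed).
#' @param n_replicas number of independent trajectories.
#' @param pool unfolded pool (required for `kind = "folding"`); replicas
#'   cycle through it.
#' @return list of `kc_trajectory`, each tagged with `protocol` and
#'   `replica`.
#' @export
run_protocol <- function(kind = c("equilibrium", "folding", "unfolding"),
                         s, ff, cfg, n_replicas = 1L, pool = NULL) {
  kind <- match.arg(kind)
  if (kind == "folding" && is.null(pool)) stop("folding protocol needs a pool")
  out <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    start <- if (kind == "folding") {
      pool[[(r - 1L) %% length(pool) + 1L]]
    } else {
      s$coords
    }
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(cfg$seed, r)
    traj <- integrate_langevin(start, ff, cfg_r)
    traj$protocol <- kind
    traj$replica <- r
    out[[r]] <- traj
  }
  out
}

#' Write / read a trajectory as a plain-text table
#'
#' Tab-separated: a header line with metadata, then one line per frame with
#' the step index, potential and kinetic energy, followed by the flattened
#' coordinates (bead-major). A plain-text stand-in for a binary trajectory
#' container so archives stay portable and diffable.
#'
#' @param traj `kc_trajectory`
#' @param path file path.
#' @return `path` / `kc_trajectory`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kc_trajectory n_beads=%d n_frames=%d temperature=%.10g stride=%d",
                     traj$n_beads, n_frames(traj), traj$config$temperature,
                     traj$config$record_stride), con)
  for (i in seq_len(n_frames(traj))) {
    writeLines(paste(c(sprintf("%.0f", traj$step[i]),
                       sprintf("%.10g", traj$epot[i]),
                       sprintf("%.10g", traj$ekin[i]),
                       sprintf("%.6f", as.numeric(traj$frames[, , i]))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  nb <- as.integer(sub(".*n_beads=(\\d+).*", "\\1", hdr))
  tt <- as.numeric(sub(".*temperature=([0-9.eE+-]+).*", "\\1", hdr))
  stride <- as.integer(sub(".*stride=(\\d+).*", "\\1", hdr))
  body <- lines[-1]
  nf <- length(body)
  frames <- array(0, dim = c(3, nb, nf))
  step <- epot <- ekin <- numeric(nf)
  for (i in seq_len(nf)) {
    v <- as.numeric(strsplit(body[i], "\t", fixed = TRUE)[[1]])
    step[i] <- v[1]; epot[i] <- v[2]; ekin[i] <- v[3]
    frames[, , i] <- v[-(1:3)]
  }
  cfg <- sim_config(tt, n_steps = max(step, 1), record_stride = stride)
  structure(list(frames = frames, step = step, epot = epot, ekin = ekin,
                 final_coords = t(frames[, , nf]), final_vel = NULL,
                 config = cfg, n_beads = nb),
            class = "kc_trajectory")
}
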