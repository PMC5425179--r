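#' Fraction of native contacts Q
#'
#' A native contact is counted as formed when the Cα-Cα distance is less
#' than 1.2 times its native distance; Q is the formed fraction.
#'
#' @param coords n x 3 coordinates (Angstrom).
#' @param topology `native_topology`.
#' @return Q in `[0, 1]`.
#' @export
fraction_native <- function(coords, topology) {
  if (nrow(topology$contacts) == 0L) stop("no contacts defined")
  coords <- as.matrix(coords)
  i <- topology$contacts[, 1]; j <- topology$contacts[, 2]
  d <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
  mean(d < 1.2 * topology$contact_r0)
}

#' Fraction of native contacts for every frame of a trajectory
#'
#' Vectorized [fraction_native()] over a whole trajectory.
#'
#' @param traj `kc_trajectory`
#' @param topology `native_topology`
#' @return numeric vector of Q values, one per recorded frame.
#' @export
series_q <- function(traj, topology) {
  if (nrow(topology$contacts) == 0L) stop("no contacts defined")
  formed <- .contact_formed_cpp(traj$frames, topology$contacts - 1L,
                                topology$contact_r0, 1.2)
  rowMeans(formed)
}

#' Radius of gyration
#'
#' Root-mean-square distance of the beads from their centroid, with unit
#' masses (all beads identical in the Cα model).
#'
#' @param coords n x 3 coordinates.
#' @return R_g in Angstrom.
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  cen <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, cen)^2)))
}

gyration_eigenvalues <- function(coords) {
  coords <- as.matrix(coords)
  cen <- sweep(coords, 2, colMeans(coords))
  S <- crossprod(cen) / nrow(coords)
  sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Asphericity of a bead cloud
#'
#' Gyration-tensor shape invariant
#' `Delta = 1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1 + l2 + l3)^2` from the
#' eigenvalues `l1 >= l2 >= l3`: 0 for spherically symmetric objects,
#' 1 for a rod.
#'
#' @param coords n x 3 coordinates (>= 2 beads, not all coincident).
#' @return Delta in `[0, 1]`.
#' @export
asphericity <- function(coords) {
  l <- gyration_eigenvalues(coords)
  tr <- sum(l)
  if (tr <= 0) stop("degenerate configuration")
  max(0, min(1, 1 - 3 * (l[1] * l[2] + l[2] * l[3] + l[3] * l[1]) / tr^2))
}

#' Per-frame reaction coordinates of a trajectory
#'
#' Computes Q, the radius of gyration, asphericity, and (optionally strided)
#' knottedness for every recorded frame. Frames between strided knot
#' evaluations carry the label `"unevaluated"`; they are never interpolated.
#'
#' @param traj `kc_trajectory`
#' @param topology `native_topology`
#' @param knot_stride evaluate the knot type every `knot_stride`-th frame
#'   (default 1 = every frame); `NA` skips knot detection entirely.
#' @param n_projections projections per knot call (default 7).
#' @param seed seed for the knot-projection directions.
#' @return data.frame of class `observable_series`: `step`, `Q`, `Rg`,
#'   `asphericity`, `knot_label`, `knotted` (NA where unevaluated).
#' @export
observable_series <- function(traj, topology, knot_stride = 1L,
                              n_projections = 7L, seed = 1L) {
  nf <- n_frames(traj)
  q <- series_q(traj, topology)
  rg <- numeric(nf)
  asp <- numeric(nf)
  for (i in seq_len(nf)) {
    x <- frame_coords(traj, i)
    rg[i] <- radius_of_gyration(x)
    asp[i] <- asphericity(x)
  }
  label <- rep(NA_character_, nf)
  if (!is.na(knot_stride)) {
    eval_at <- seq(1L, nf, by = as.integer(knot_stride))
    for (k in seq_along(eval_at)) {
      i <- eval_at[k]
      kd <- knot_type(frame_coords(traj, i), n_projections = n_projections,
                      seed = derive_seed(seed, i))
      label[i] <- kd$knot_label
    }
    label[is.na(label)] <- "unevaluated"
  } else {
    label[] <- "unevaluated"
  }
  out <- data.frame(step = traj$step, Q = q, Rg = rg, asphericity = asp,
                    knot_label = label,
                    knotted = ifelse(label == "unevaluated", NA,
                                     label != "0_1"),
                    stringsAsFactors = FALSE)
  class(out) <- c("observable_series", "data.frame")
  out
}

#' Knotting probability profile P_K(Q)
#'
#' Bins evaluated frames by Q and reports the fraction of knotted frames
#' per bin. Bins without any evaluated frame are flagged absent (`NA`)
#' rather than zero.
#'
#' @param series an `observable_series` (or a data.frame with columns `Q`
#'   and `knotted`), or a list of them (pooled).
#' @param bin_width Q bin width on `[0, 1]` (default 0.05).
#' @return data.frame of class `pk_profile`: `Q_lo`, `Q_hi`, `Q_mid`,
#'   `P_K`, `n_frames`.
#' @export
pk_profile <- function(series, bin_width = 0.05) {
  if (is.list(series) && !is.data.frame(series)) {
    series <- do.call(rbind, lapply(series, function(s) {
      as.data.frame(s)[, c("Q", "knotted")]
    }))
  }
  dat <- series[!is.na(series$knotted), , drop = FALSE]
  if (nrow(dat) == 0L) stop("no evaluated frames")
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin <- cut(pmin(dat$Q, 1 - 1e-12), edges, right = FALSE, labels = FALSE)
  nb <- length(edges) - 1L
  cnt <- tabulate(bin, nbins = nb)
  kn <- vapply(seq_len(nb), function(b) sum(dat$knotted[bin == b]), numeric(1))
  out <- data.frame(Q_lo = edges[-length(edges)], Q_hi = edges[-1],
                    Q_mid = (edges[-length(edges)] + edges[-1]) / 2,
                    P_K = ifelse(cnt > 0, kn / pmax(cnt, 1), NA),
                    n_frames = cnt)
  class(out) <- c("pk_profile", "data.frame")
  out
}

#' First Q bin at which P_K crosses one half
#'
#' Used to compare the knotting step with the position of the free-energy
#' barrier in F(Q).
#'
#' @param profile a [pk_profile()] result.
#' @param min_frames ignore bins with fewer evaluated frames (default 10;
#'   sparsely populated bins carry binomial noise of order
#'   `1/sqrt(n_frames)` and would otherwise fake a crossing).
#' @return the `Q_mid` of the first sufficiently occupied bin with
#'   `P_K >= 0.5` (`NA` if never crossed).
#' @export
pk_crossing <- function(profile, min_frames = 10) {
  occ <- which(!is.na(profile$P_K) & profile$n_frames >= min_frames &
                 profile$P_K >= 0.5)
  if (!length(occ)) return(NA_real_)
  profile$Q_mid[occ[1]]
}

#' Write an observable series as a tab-separated table
#' @param series `observable_series`
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_observables <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
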