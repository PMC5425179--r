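#' Per-contact formation probability profile S_n(Q)
#'
#' For every native contact n and every occupied Q bin, the fraction of
#' frames (pooled over the supplied trajectories) in which the contact is
#' formed under the 1.2 x native-distance rule. Columns are Q bins, rows
#' are contacts; bins without frames are `NA`.
#'
#' @param trajectories a `kc_trajectory` or list of them.
#' @param topology `native_topology`
#' @param bin_width Q bin width (default 0.05).
#' @param condition free-text label carried in the result (for example
#'   `"bulk"` or `"L=2.0"`).
#' @return object of class `contact_profile`: `S` (contacts x bins),
#'   `Q_mid`, `bin_count`, `contacts`, `condition`.
#' @export
contact_profile <- function(trajectories, topology, bin_width = 0.05,
                            condition = "") {
  if (inherits(trajectories, "kc_trajectory")) trajectories <- list(trajectories)
  formed_all <- NULL
  q_all <- NULL
  for (tr in trajectories) {
    formed <- .contact_formed_cpp(tr$frames, topology$contacts - 1L,
                                  topology$contact_r0, 1.2)
    formed_all <- rbind(formed_all, formed)
    q_all <- c(q_all, rowMeans(formed))
  }
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  nb <- length(edges) - 1L
  bin <- findInterval(pmin(q_all, 1 - 1e-12), edges, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = nb)
  S <- matrix(NA_real_, nrow = ncol(formed_all), ncol = nb)
  for (b in which(cnt > 0)) {
    S[, b] <- colMeans(formed_all[bin == b, , drop = FALSE])
  }
  structure(list(S = S, Q_mid = (edges[-length(edges)] + edges[-1]) / 2,
                 bin_count = cnt, contacts = topology$contacts,
                 bin_width = bin_width, condition = condition),
            class = "contact_profile")
}

#' Backtracking detection from consecutive S_n(Q) differences
#'
#' Computes `S_n(Q)_diff`, the difference of each contact's formation
#' probability between consecutive *occupied* Q bins; a drop below
#' `-threshold` flags backtracking: native structure that must partially
#' unform for folding to proceed. Flagged contacts that are
#' sequence-adjacent (consecutive rows of the contact list sharing a
#' flag) are grouped.
#'
#' @param profile [contact_profile()]
#' @param threshold flag magnitude theta (default 0.05).
#' @param min_frames ignore bins with fewer frames (default 10).
#' @param wham optional [free_energy_profile()] result; when supplied each
#'   flag is annotated with its position relative to the F(Q) barrier.
#' @return object of class `backtrack_report`: `diff` (contacts x
#'   (occupied bins - 1)), `flags` (data.frame `contact`, `i`, `j`,
#'   `Q_bin`, `diff`, optionally `rel_barrier`), `groups` (list of
#'   flagged-contact runs), `threshold`.
#' @export
detect_backtracking <- function(profile, threshold = 0.05, min_frames = 10,
                                wham = NULL) {
  occ <- which(profile$bin_count >= min_frames)
  if (length(occ) < 2L) stop("need >= 2 occupied bins")
  S <- profile$S[, occ, drop = FALSE]
  D <- S[, -1, drop = FALSE] - S[, -ncol(S), drop = FALSE]
  flags <- which(D < -threshold, arr.ind = TRUE)
  fl <- if (nrow(flags)) {
    data.frame(contact = flags[, 1],
               i = profile$contacts[flags[, 1], 1],
               j = profile$contacts[flags[, 1], 2],
               Q_bin = profile$Q_mid[occ[flags[, 2] + 1L]],
               diff = D[flags])
  } else {
    data.frame(contact = integer(0), i = integer(0), j = integer(0),
               Q_bin = numeric(0), diff = numeric(0))
  }
  if (!is.null(wham) && nrow(fl)) {
    bq <- fq_barrier(wham)$Q
    fl$rel_barrier <- if (is.na(bq)) NA_real_ else fl$Q_bin - bq
  }
  ## maximal runs of consecutive flagged contact indices
  fc <- sort(unique(fl$contact))
  groups <- if (length(fc)) {
    split(fc, cumsum(c(1, diff(fc) != 1)))
  } else list()
  structure(list(diff = D, Q_mid_diff = profile$Q_mid[occ[-1]],
                 flags = fl, groups = unname(groups),
                 threshold = threshold),
            class = "backtrack_report")
}

#' Difference between two contact profiles
#'
#' Elementwise `a - b` per Q bin occupied in both profiles, plus a
#' per-residue aggregate (mean absolute difference over the contacts each
#' residue participates in) for structure colouring.
#'
#' @param a,b [contact_profile()] objects over the same topology and
#'   binning.
#' @return list: `diff` (contacts x bins, NA where either is absent),
#'   `Q_mid`, `per_residue` (residues x bins).
#' @export
profile_difference <- function(a, b) {
  if (!identical(dim(a$S), dim(b$S)) ||
      !isTRUE(all.equal(a$Q_mid, b$Q_mid)) ||
      !identical(a$contacts, b$contacts)) {
    stop("incompatible profiles")
  }
  D <- a$S - b$S
  n_res <- max(a$contacts)
  per_res <- matrix(NA_real_, n_res, ncol(D))
  for (r in seq_len(n_res)) {
    rows <- which(a$contacts[, 1] == r | a$contacts[, 2] == r)
    if (length(rows)) {
      per_res[r, ] <- colMeans(abs(D[rows, , drop = FALSE]))
    }
  }
  list(diff = D, Q_mid = a$Q_mid, per_residue = per_res)
}

#' Optimal-superposition (Kabsch) RMSD between two conformations
#'
#' Minimal root-mean-square deviation after optimal rigid superposition,
#' via the SVD of the covariance matrix with the proper-rotation
#' (determinant) correction.
#'
#' @param a,b n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  H <- crossprod(ac, bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  dif <- ac %*% t(R) - bc
  sqrt(mean(rowSums(dif^2)))
}

#' Greedy leader clustering of conformations at fixed Q
#'
#' Deterministic leader algorithm in frame order: each frame joins the
#' first existing cluster whose leader lies within `rmsd_threshold`
#' (Kabsch RMSD), otherwise it founds a new cluster.
#'
#' @param frames list of n x 3 coordinate matrices (frames within one Q
#'   bin, in step order; >= 2 frames).
#' @param rmsd_threshold clustering radius in Angstrom.
#' @return object of class `cluster_report`: `assignment`, `sizes`,
#'   `n_clusters`, `largest_fraction`, `rmsd_threshold`.
#' @export
cluster_at_q <- function(frames, rmsd_threshold) {
  if (length(frames) < 2L) stop("need >= 2 frames")
  leaders <- list(frames[[1]])
  assign_ <- integer(length(frames))
  assign_[1] <- 1L
  for (i in 2:length(frames)) {
    placed <- FALSE
    for (k in seq_along(leaders)) {
      if (kabsch_rmsd(frames[[i]], leaders[[k]]) <= rmsd_threshold) {
        assign_[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders[[length(leaders) + 1L]] <- frames[[i]]
      assign_[i] <- length(leaders)
    }
  }
  sizes <- tabulate(assign_)
  structure(list(assignment = assign_, sizes = sizes,
                 n_clusters = length(sizes),
                 largest_fraction = max(sizes) / length(frames),
                 rmsd_threshold = rmsd_threshold),
            class = "cluster_report")
}

#' Cluster-size scan over Q bins and RMSD thresholds
#'
#' @param trajectories a `kc_trajectory` or list of them.
#' @param topology `native_topology`
#' @param q_bins data.frame-free spec: numeric vector of bin edges
#'   (default `seq(0, 1, 0.05)`).
#' @param thresholds RMSD radii in Angstrom (default `seq(3, 6, 0.25)`,
#'   the 3-6 Angstrom window sampled at 0.25).
#' @param min_frames minimum frames per bin to attempt clustering.
#' @return data.frame: `Q_lo`, `Q_hi`, `threshold`, `n_frames`,
#'   `n_clusters`, `largest_fraction`.
#' @export
cluster_scan <- function(trajectories, topology,
                         q_bins = seq(0, 1, 0.05),
                         thresholds = seq(3, 6, 0.25), min_frames = 2L) {
  if (inherits(trajectories, "kc_trajectory")) trajectories <- list(trajectories)
  frames <- list()
  qv <- numeric(0)
  for (tr in trajectories) {
    q <- series_q(tr, topology)
    for (i in seq_len(n_frames(tr))) {
      frames[[length(frames) + 1L]] <- frame_coords(tr, i)
    }
    qv <- c(qv, q)
  }
  rows <- list()
  for (b in seq_len(length(q_bins) - 1L)) {
    sel <- which(qv >= q_bins[b] & qv < q_bins[b + 1L])
    if (length(sel) < min_frames) next
    for (th in thresholds) {
      cr <- cluster_at_q(frames[sel], th)
      rows[[length(rows) + 1L]] <- data.frame(
        Q_lo = q_bins[b], Q_hi = q_bins[b + 1L], threshold = th,
        n_frames = length(sel), n_clusters = cr$n_clusters,
        largest_fraction = cr$largest_fraction)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
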