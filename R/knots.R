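#' KMT reduction of an open chain
#'
#' Koniaris-Muthukumar-Taylor simplification: an interior vertex is deleted
#' whenever the triangle it forms with its two neighbours is crossed by no
#' other chain segment; passes repeat until nothing is deletable.
#' Zero-area (collinear) triangles are always deletable. The reduction
#' preserves the knot type of the (closed) curve and is idempotent.
#'
#' @param coords n x 3 polyline coordinates (n >= 3).
#' @return object of class `reduced_chain`: `coords` (m x 3), `indices`
#'   (1-based positions of the survivors in the input chain, always
#'   including both termini).
#' @export
kmt_reduce <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) {
    return(structure(list(coords = coords, indices = seq_len(nrow(coords))),
                     class = "reduced_chain"))
  }
  d <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                       coords[-nrow(coords), , drop = FALSE])^2))
  if (any(d == 0)) stop("coincident consecutive vertices")
  res <- .kmt_reduce_cpp(coords)
  structure(list(coords = res$coords, indices = res$indices),
            class = "reduced_chain")
}

#' Deterministic closure of an open chain
#'
#' Both termini are extended to a sphere of radius ten times the maximal
#' centroid distance along a single common outward direction (the
#' normalised sum of the two terminus-minus-centroid unit vectors), then
#' connected through a far apex, adding exactly three vertices. Using one
#' common direction makes the two extension segments parallel, so they
#' cannot clasp a chain strand between them; if the outward ray passes
#' exactly through a chain vertex (symmetric synthetic curves do this),
#' the direction is deflected by a deterministic sequence of small tilts
#' until both extensions clear the chain.
#'
#' @param coords m x 3 open-chain coordinates (typically KMT-reduced).
#' @return closed polygon as an (m + 3) x 3 matrix (the last three rows
#'   are the closure vertices; the polygon closes back to row 1).
#' @export
close_chain <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  cen <- colMeans(coords)
  rmax <- max(sqrt(rowSums(sweep(coords, 2, cen)^2)))
  if (rmax <= 0) stop("degenerate chain")
  R <- 10 * rmax
  unitv <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12 * rmax) c(1, 0, 0) else v / nv
  }
  u1 <- unitv(coords[1, ] - cen)
  u2 <- unitv(coords[n, ] - cen)
  um <- u1 + u2
  if (sqrt(sum(um^2)) < 1e-8) {
    ## antipodal termini: deterministic perpendicular
    um <- c(-u1[2], u1[1], 0)
    if (sqrt(sum(um^2)) < 1e-8) um <- c(0, -u1[3], u1[2])
  }
  um <- unitv(um)
  ref <- if (abs(um[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(ref - sum(ref * um) * um)
  e2 <- c(um[2] * e1[3] - um[3] * e1[2], um[3] * e1[1] - um[1] * e1[3],
          um[1] * e1[2] - um[2] * e1[1])
  tilts <- c(0, 0.02, -0.02, 0.05, -0.05, 0.11, -0.11, 0.23, -0.23, 0.41)
  dir <- um
  for (a in tilts) {
    v <- unitv(um + a * e1 + (a / 2) * e2)
    ok1 <- segment_clears(coords[1, ], coords[1, ] + R * v, coords,
                          1e-4 * rmax, 1L)
    ok2 <- segment_clears(coords[n, ], coords[n, ] + R * v, coords,
                          1e-4 * rmax, n)
    if (ok1 && ok2) { dir <- v; break }
  }
  p1 <- coords[1, ] + R * dir
  p2 <- coords[n, ] + R * dir
  apex <- cen + 2.5 * R * dir
  rbind(coords, p2, apex, p1)
}

## minimum distance from segment ab to every chain vertex except its own
## start point; used to keep closure extensions off the chain
segment_clears <- function(a, b, coords, tol, exclude) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(coords, 2, a)
  t <- pmin(pmax((rel %*% ab) / len2, 0), 1)
  dif <- rel - outer(as.numeric(t), ab)
  d <- sqrt(rowSums(dif^2))
  min(d[-exclude]) > tol
}

label_from_det <- function(det) {
  if (is.na(det)) return("other")
  if (det == 1) "0_1" else if (det == 3) "3_1" else if (det == 5) "4_1" else "other"
}

random_rotation <- function() {
  ## QR of a random normal matrix, sign-fixed; forced proper (det = +1) so
  ## no projection is a mirror image (diagram writhe signs stay coherent)
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q * sign(diag(qr.R(qr_)))[col(q)]
  if (det(q) < 0) q[3, ] <- -q[3, ]
  q
}

with_seed_ <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Knot type of an open chain
#'
#' Pipeline: deterministic closure, KMT reduction of the closed polygon
#' (closed-curve deletions preserve the knot type exactly), projection
#' onto random planes, crossing-diagram construction, Alexander
#' determinant `|Delta(-1)|` by majority vote across projections. Degenerate
#' projections (crossing at a vertex, ambiguous height) are discarded and
#' resampled. The determinant maps to a label:
#' 1 = unknot `0_1`, 3 = trefoil `3_1`, 5 = figure-eight `4_1`, anything
#' else = `other`. For trefoils, chirality is taken from the sign of the
#' summed crossing signs (diagram writhe), majority across projections:
#' negative writhe = left-handed (the `-3_1` form found in knotted
#' proteins), positive = right-handed.
#'
#' @param coords n x 3 open-chain coordinates (n >= 3).
#' @param n_projections number of projection planes (default 11).
#' @param seed seed for the projection directions.
#' @param reduce apply [kmt_reduce()] first (default TRUE).
#' @return object of class `knot_diagnosis`: `knot_label`,
#'   `alexander_det`, `chirality` (`"left"`, `"right"` or `"n/a"`),
#'   `projections_agreeing` (fraction), `writhe` (median over projections).
#' @export
knot_type <- function(coords, n_projections = 11L, seed = 1L, reduce = TRUE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) stop("need at least 3 vertices")
  closed <- close_chain(coords)
  ## reduce *after* closing: every deletion on the closed polygon is a
  ## legal isotopy of the closed curve, so the type is preserved exactly
  ## (open-chain reduction can slip past the virtual closure)
  if (reduce) closed <- .kmt_reduce_closed_cpp(closed)
  dets <- numeric(0)
  writhes <- numeric(0)
  with_seed_(seed, {
    tries <- 0L
    max_tries <- 20L * n_projections
    while (length(dets) < n_projections && tries < max_tries) {
      tries <- tries + 1L
      rot <- random_rotation()
      res <- .alexander_proj_cpp(closed, rot)
      if (!isTRUE(res$ok)) next
      if (res$det %% 2 == 0) next  # even determinant: bad diagram, resample
      dets <- c(dets, res$det)
      writhes <- c(writhes, res$writhe)
    }
  })
  if (!length(dets)) stop("projection failure")
  tab <- table(dets)
  det <- as.numeric(names(tab)[which.max(tab)])
  agree <- max(tab) / length(dets)
  label <- label_from_det(det)
  chir <- "n/a"
  if (label == "3_1") {
    w <- stats::median(writhes[dets == det])
    chir <- if (w < 0) "left" else "right"
  }
  structure(list(knot_label = label, alexander_det = det, chirality = chir,
                 projections_agreeing = agree,
                 writhe = stats::median(writhes),
                 n_projections_used = length(dets)),
            class = "knot_diagnosis")
}

#' @export
print.knot_diagnosis <- function(x, ...) {
  cat(sprintf("knot_diagnosis: %s (det %g, chirality %s, %.0f%% projections agree)\n",
              x$knot_label, x$alexander_det, x$chirality,
              100 * x$projections_agreeing))
  invisible(x)
}

type_subchain <- function(coords, i, j, n_projections, seed) {
  if (j - i + 1L < 5L) return("0_1")
  kd <- tryCatch(
    knot_type(coords[i:j, , drop = FALSE], n_projections = n_projections,
              seed = seed),
    error = function(e) NULL)
  if (is.null(kd)) "0_1" else kd$knot_label
}

#' Subchain topological fingerprint
#'
#' Types every subchain `(i, j)` on a stride grid and locates the knot
#' core: the minimal subchain that still carries the full-chain knot type,
#' found by shrinking from the N side then the C side (refined to single
#' beads near the boundaries). Tail depths are the bead counts outside the
#' core.
#'
#' @param coords n x 3 open-chain coordinates.
#' @param stride grid stride for the subchain matrix (default 2).
#' @param n_projections projections per subchain typing call (default 7).
#' @param seed seed.
#' @return object of class `knot_fingerprint`: `matrix` (data.frame
#'   `i`, `j`, `label`), `full_label`, `core` (`c(i, j)` or NULL),
#'   `tail_N`, `tail_C`.
#' @export
fingerprint <- function(coords, stride = 2L, n_projections = 7L, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  full <- knot_type(coords, n_projections = max(n_projections, 11L),
                    seed = seed)
  is <- unique(c(seq(1L, n - 4L, by = stride)))
  js <- unique(c(seq(5L, n, by = stride), n))
  rows <- list()
  for (i in is) {
    for (j in js) {
      if (j - i + 1L < 5L) next
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j,
        label = type_subchain(coords, i, j, n_projections,
                              derive_seed(seed, i * n + j)))
    }
  }
  mat <- do.call(rbind, rows)

  core <- NULL; tail_n <- NA_integer_; tail_c <- NA_integer_
  if (full$knot_label != "0_1") {
    target <- full$knot_label
    keeps <- function(i, j) {
      type_subchain(coords, i, j, n_projections,
                    derive_seed(seed, i * n + j)) == target
    }
    i0 <- 1L; j0 <- n
    while (i0 < j0 - 4L && keeps(i0 + 1L, j0)) i0 <- i0 + 1L
    while (j0 > i0 + 4L && keeps(i0, j0 - 1L)) j0 <- j0 - 1L
    core <- c(i0, j0)
    tail_n <- i0 - 1L
    tail_c <- n - j0
  }
  structure(list(matrix = mat, full_label = full$knot_label, core = core,
                 tail_N = tail_n, tail_C = tail_c, n_beads = n),
            class = "knot_fingerprint")
}

#' @export
print.knot_fingerprint <- function(x, ...) {
  if (is.null(x$core)) {
    cat(sprintf("knot_fingerprint: %s, no core (%d beads)\n",
                x$full_label, x$n_beads))
  } else {
    cat(sprintf("knot_fingerprint: %s, core %d-%d, tails N=%d C=%d\n",
                x$full_label, x$core[1], x$core[2], x$tail_N, x$tail_C))
  }
  invisible(x)
}

#' Export a fingerprint matrix as a tab-separated table
#' @param fp `knot_fingerprint`
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fingerprint <- function(fp, path) {
  utils::write.table(fp$matrix, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
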