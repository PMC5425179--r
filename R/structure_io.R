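#' Cα bead structure
#'
#' An ordered single-chain Cα bead model: one bead per residue, Cartesian
#' coordinates in Angstrom. This is the common currency of the whole
#' pipeline: the PDB reader, the synthetic chain generators and the
#' simulation engine all produce or consume `ca_structure` objects.
#'
#' @param coords numeric matrix, n x 3, Angstrom.
#' @param residue_ids integer vector, strictly increasing residue numbers.
#' @param residue_names character vector of 3-letter codes (recycled).
#' @param chain_id single character chain label.
#' @param flagged logical; `TRUE` marks a structure rejected for simulation
#'   (chain break or too few beads) while still usable for inspection.
#'
#' @return object of class `ca_structure` with fields `coords`,
#'   `residue_ids`, `residue_names`, `chain_id`, `flagged`.
#' @export
ca_structure <- function(coords, residue_ids = seq_len(nrow(coords)),
                         residue_names = "ALA", chain_id = "A",
                         flagged = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be n x 3")
  n <- nrow(coords)
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != n) stop("residue_ids length mismatch")
  if (anyDuplicated(residue_ids)) stop("duplicate residue_ids")
  if (is.unsorted(residue_ids, strictly = TRUE)) {
    stop("residue_ids must be strictly increasing")
  }
  residue_names <- rep_len(as.character(residue_names), n)
  out <- structure(
    list(coords = coords, residue_ids = residue_ids,
         residue_names = residue_names, chain_id = as.character(chain_id)[1],
         flagged = isTRUE(flagged)),
    class = "ca_structure")
  if (n < 5L) out$flagged <- TRUE
  d <- bead_distances(out)
  if (length(d) && (any(d < 2.5) || any(d > 4.5))) out$flagged <- TRUE
  out
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("ca_structure: %d beads, chain %s, residues %d-%d%s\n",
              nrow(x$coords), x$chain_id, x$residue_ids[1],
              x$residue_ids[length(x$residue_ids)],
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

n_beads <- function(s) nrow(s$coords)

bead_distances <- function(s) {
  x <- s$coords
  if (nrow(x) < 2L) return(numeric(0))
  sqrt(rowSums((x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])^2))
}

#' Read a single protein chain from a PDB file as a Cα bead model
#'
#' Parses fixed-column ATOM records, keeps one CA atom per residue
#' (alternate locations resolved by highest occupancy, ties by file order)
#' and orders beads by residue number. Residues with an insertion code are
#' rejected; residues without a CA atom are skipped with a warning. A
#' consecutive-bead distance above 4.5 Angstrom marks a chain break: the
#' structure is returned flagged and later refused by the simulation setup.
#'
#' @param path PDB file path.
#' @param chain chain identifier (single character). Default `"A"`.
#' @param model model number for multi-model files; the default 1 takes the
#'   first MODEL block (or the whole file when no MODEL records exist).
#' @return [ca_structure()]
#' @export
read_pdb <- function(path, chain = "A", model = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  ## restrict to the requested model when MODEL records are present
  mstart <- grep("^MODEL", lines)
  if (length(mstart)) {
    mnum <- suppressWarnings(as.integer(substr(lines[mstart], 11, 14)))
    pick <- which(mnum == as.integer(model))
    if (!length(pick)) pick <- min(length(mstart), as.integer(model))
    from <- mstart[pick[1]]
    ends <- grep("^ENDMDL", lines)
    to <- ends[ends > from]
    to <- if (length(to)) to[1] else length(lines)
    lines <- lines[from:to]
  }

  atom <- lines[startsWith(lines, "ATOM")]
  if (!length(atom)) stop("no CA atoms")
  fld <- function(x, a, b) substr(x, a, b)
  name <- trimws(fld(atom, 13, 16))
  alt <- fld(atom, 17, 17)
  ch <- fld(atom, 22, 22)
  resno <- suppressWarnings(as.integer(fld(atom, 23, 26)))
  icode <- fld(atom, 27, 27)
  occ <- suppressWarnings(as.numeric(fld(atom, 55, 60)))
  occ[is.na(occ)] <- 1

  if (!any(ch == chain)) stop("chain not found: ", chain)
  sel <- ch == chain & name == "CA"
  if (!any(sel)) stop("no CA atoms")
  if (any(trimws(icode[sel]) != "")) {
    stop("residue insertion codes are not supported")
  }

  resname <- trimws(fld(atom, 18, 20))
  xs <- as.numeric(fld(atom, 31, 38))
  ys <- as.numeric(fld(atom, 39, 46))
  zs <- as.numeric(fld(atom, 47, 54))

  idx <- which(sel)
  ## altLoc resolution: highest occupancy, then first listed
  ord <- idx[order(resno[idx], -occ[idx], seq_along(idx))]
  keep <- ord[!duplicated(resno[ord])]
  keep <- keep[order(resno[keep])]

  s <- ca_structure(cbind(xs[keep], ys[keep], zs[keep]),
                    residue_ids = resno[keep],
                    residue_names = resname[keep], chain_id = chain)
  d <- bead_distances(s)
  if (length(d) && any(d > 4.5)) {
    warning("chain break: consecutive CA distance > 4.5 A; structure flagged")
  }
  if (length(d) && any(d < 2.5)) {
    warning("unphysical consecutive CA distance < 2.5 A; structure flagged")
  }
  s
}

#' Write a Cα-only PDB file
#'
#' Minimal writer used by the synthetic-chain generator so that every
#' structure in the pipeline can round-trip through [read_pdb()].
#'
#' @param s [ca_structure()]
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(s, path) {
  n <- n_beads(s)
  rec <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), substr(s$residue_names, 1, 3), s$chain_id, s$residue_ids,
    s$coords[, 1], s$coords[, 2], s$coords[, 3])
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Native topology of a Cα chain
#'
#' Derives the reference geometry that parameterises the structure-based
#' forcefield: native bond lengths, bend angles, dihedral angles, and the
#' native contact set. Contacts are all bead pairs `(i, j)` with
#' `j - i >= min_sep` whose native Cα-Cα distance is at most
#' `contact_cutoff`; each is stored once with `i < j` together with its
#' native distance `r0`.
#'
#' @param s [ca_structure()]; must not be flagged.
#' @param contact_cutoff Cα-Cα distance cutoff in Angstrom (default 8.0).
#' @param min_sep minimum sequence separation `j - i` for a contact
#'   (default 4; must be >= 3).
#' @return object of class `native_topology`: `bond_r0`, `angle_th0`,
#'   `dihedral_phi0` (radians), `contacts` (m x 2 integer matrix of 1-based
#'   bead indices), `contact_r0`, `min_sep`, `n_beads`, plus residue labels
#'   carried along for reporting.
#' @export
build_native_topology <- function(s, contact_cutoff = 8.0, min_sep = 4L) {
  stopifnot(inherits(s, "ca_structure"))
  if (s$flagged) stop("broken chain")
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0")
  min_sep <- as.integer(min_sep)
  if (min_sep < 3L) stop("min_sep must be >= 3")
  x <- s$coords
  n <- nrow(x)

  bond_r0 <- bead_distances(s)
  angle_th0 <- vapply(seq_len(n - 2L), function(i) {
    bead_angle(x[i, ], x[i + 1L, ], x[i + 2L, ])
  }, numeric(1))
  dihedral_phi0 <- vapply(seq_len(n - 3L), function(i) {
    bead_dihedral(x[i, ], x[i + 1L, ], x[i + 2L, ], x[i + 3L, ])
  }, numeric(1))

  dm <- as.matrix(stats::dist(x))
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  sel <- (pairs[, 2] - pairs[, 1]) >= min_sep & dm[pairs] <= contact_cutoff
  contacts <- pairs[sel, , drop = FALSE]
  ord <- order(contacts[, 1], contacts[, 2])
  contacts <- contacts[ord, , drop = FALSE]
  dimnames(contacts) <- list(NULL, c("i", "j"))
  contact_r0 <- dm[contacts]

  structure(
    list(n_beads = n, bond_r0 = bond_r0, angle_th0 = angle_th0,
         dihedral_phi0 = dihedral_phi0,
         contacts = matrix(as.integer(contacts), ncol = 2,
                           dimnames = list(NULL, c("i", "j"))),
         contact_r0 = as.numeric(contact_r0), min_sep = min_sep,
         residue_ids = s$residue_ids, chain_id = s$chain_id),
    class = "native_topology")
}

#' @export
print.native_topology <- function(x, ...) {
  cat(sprintf(
    "native_topology: %d beads, %d bonds, %d angles, %d dihedrals, %d contacts (min_sep %d)\n",
    x$n_beads, length(x$bond_r0), length(x$angle_th0),
    length(x$dihedral_phi0), nrow(x$contacts), x$min_sep))
  invisible(x)
}

bead_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cth <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cth)))
}

bead_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

#' Serialize / read a native topology as a plain-text table
#'
#' One section per term type (`bonds`, `angles`, `dihedrals`, `contacts`),
#' tab-separated columns: 1-based bead indices and the native reference
#' value (Angstrom or radians).
#'
#' @param topo `native_topology`
#' @param path output path.
#' @return `path` (write) / `native_topology` (read), invisibly.
#' @export
write_topology <- function(topo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# native_topology n_beads=%d min_sep=%d",
                     topo$n_beads, topo$min_sep), con)
  writeLines("[bonds]", con)
  writeLines(sprintf("%d\t%d\t%.10g", seq_along(topo$bond_r0),
                     seq_along(topo$bond_r0) + 1L, topo$bond_r0), con)
  writeLines("[angles]", con)
  writeLines(sprintf("%d\t%d\t%d\t%.10g", seq_along(topo$angle_th0),
                     seq_along(topo$angle_th0) + 1L,
                     seq_along(topo$angle_th0) + 2L, topo$angle_th0), con)
  writeLines("[dihedrals]", con)
  writeLines(sprintf("%d\t%d\t%d\t%d\t%.10g", seq_along(topo$dihedral_phi0),
                     seq_along(topo$dihedral_phi0) + 1L,
                     seq_along(topo$dihedral_phi0) + 2L,
                     seq_along(topo$dihedral_phi0) + 3L,
                     topo$dihedral_phi0), con)
  writeLines("[contacts]", con)
  if (nrow(topo$contacts)) {
    writeLines(sprintf("%d\t%d\t%.10g", topo$contacts[, 1],
                       topo$contacts[, 2], topo$contact_r0), con)
  }
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  nb <- as.integer(sub(".*n_beads=(\\d+).*", "\\1", hdr))
  ms <- as.integer(sub(".*min_sep=(\\d+).*", "\\1", hdr))
  sec <- function(name) {
    i <- which(lines == sprintf("[%s]", name))
    j <- grep("^\\[", lines)
    j <- j[j > i]
    to <- if (length(j)) j[1] - 1L else length(lines)
    if (to < i + 1L) return(character(0))
    lines[(i + 1L):to]
  }
  parse_num <- function(v, col) {
    if (!length(v)) return(numeric(0))
    vapply(strsplit(v, "\t"), function(p) as.numeric(p[col]), numeric(1))
  }
  cn <- sec("contacts")
  contacts <- if (length(cn)) {
    cbind(i = as.integer(parse_num(cn, 1)), j = as.integer(parse_num(cn, 2)))
  } else matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  structure(
    list(n_beads = nb, bond_r0 = parse_num(sec("bonds"), 3),
         angle_th0 = parse_num(sec("angles"), 4),
         dihedral_phi0 = parse_num(sec("dihedrals"), 5),
         contacts = contacts, contact_r0 = parse_num(cn, 3),
         min_sep = ms, residue_ids = seq_len(nb), chain_id = "A"),
    class = "native_topology")
}
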