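#' Boltzmann constant of the reduced unit system
#'
#' Energies are measured in the contact energy epsilon; temperature is on a
#' Gromacs-style reduced scale with `k_B = 0.00831451` epsilon per
#' temperature unit, so temperatures near 120 correspond to `k_B T` of
#' about 1 epsilon.
#' @export
kB <- 0.00831451

#' Cylindrical chaperonin cage specification
#'
#' A passive repulsive cylinder of height `2L` and diameter `2L`, axis along
#' z, centered at the origin. Each bead interacts with the lateral wall and
#' both caps through the short-ranged wall potential
#' `V(d) = eps_c * ((2/d)^2 - 1)^2` for wall distance `d` below `cutoff`
#' (both the potential and its derivative vanish at `d = cutoff = 2` A, so
#' the truncation is smooth).
#'
#' @param L characteristic half-size in nm (height and diameter are `2L`).
#' @param eps_c wall energy scale in epsilon (default 10).
#' @param cutoff interaction range from the wall in Angstrom (default 2).
#' @return object of class `cage_spec` (`L_A` is `L` converted to Angstrom).
#' @export
cage_spec <- function(L, eps_c = 10.0, cutoff = 2.0) {
  stopifnot(L > 0, eps_c > 0, cutoff > 0)
  structure(list(L = L, L_A = 10 * L, eps_c = eps_c, cutoff = cutoff,
                 geometry = "cylinder, height 2L, diameter 2L, axis z, centered at origin"),
            class = "cage_spec")
}

#' Wall potential of the cage
#'
#' @param d distance(s) from a wall in Angstrom; must be positive.
#' @param spec [cage_spec()] (only `eps_c` and `cutoff` are used).
#' @return energy in epsilon; exactly 0 for `d >= cutoff`.
#' @export
cage_potential <- function(d, spec = cage_spec(2)) {
  if (any(d <= 0)) stop("bead outside cage")
  u <- (2 / d)^2
  ifelse(d >= spec$cutoff, 0, spec$eps_c * (u - 1)^2)
}

#' Distances from a point to the three cage walls
#'
#' @param coord length-3 coordinate in Angstrom (or n x 3 matrix).
#' @param spec [cage_spec()]
#' @return matrix with columns `d_lateral` (`L - rho`), `d_cap_top`
#'   (`L - z`) and `d_cap_bottom` (`L + z`), in Angstrom. Non-positive
#'   values mark a bead outside the cage (returned, not raised).
#' @export
wall_distance <- function(coord, spec) {
  x <- if (is.matrix(coord)) coord else matrix(coord, ncol = 3)
  rho <- sqrt(x[, 1]^2 + x[, 2]^2)
  cbind(d_lateral = spec$L_A - rho,
        d_cap_top = spec$L_A - x[, 3],
        d_cap_bottom = spec$L_A + x[, 3])
}

#' Structure-based (Gō) forcefield for a Cα chain
#'
#' Assembles the full potential from a [build_native_topology()] result:
#' harmonic bonds and angles, a cosine dihedral term, a Gaussian
#' native-contact well with an `r^-12` excluded-volume core, `r^-12`
#' repulsion between all non-native pairs with `j - i >= min_sep`
#' (truncated and shifted to zero at `2.5 * r_ex`), and optionally the
#' cylindrical cage walls.
#'
#' The dihedral stiffness is rescaled uniformly so that total contact
#' energy and total dihedral strength sit in a 2:1 ratio
#' (`sum(eps) : sum(k_d) = 2 : 1`), the conventional balance for Cα
#' structure-based models.
#'
#' @param topology `native_topology`.
#' @param k_bond bond stiffness, epsilon/A^2 (default 100).
#' @param k_angle angle stiffness, epsilon/rad^2 (default 20).
#' @param eps_contact contact well depth epsilon (default 1; the unit).
#' @param sigma_g Gaussian well width in Angstrom (default 0.5).
#' @param r_ex excluded-volume radius in Angstrom (default 4.0).
#' @param cage optional [cage_spec()].
#' @param dihedral_contact_ratio `sum(k_d)` as a fraction of `sum(eps)`
#'   (default 0.5, i.e. the 2:1 ratio).
#' @return object of class `forcefield`.
#' @export
forcefield <- function(topology, k_bond = 100, k_angle = 20,
                       eps_contact = 1, sigma_g = 0.5, r_ex = 4.0,
                       cage = NULL, dihedral_contact_ratio = 0.5) {
  stopifnot(inherits(topology, "native_topology"),
            k_bond > 0, k_angle > 0, eps_contact > 0, sigma_g > 0, r_ex > 0)
  if (!is.null(cage)) stopifnot(inherits(cage, "cage_spec"))
  n <- topology$n_beads
  n_dih <- length(topology$dihedral_phi0)
  n_con <- nrow(topology$contacts)
  k_d <- if (n_dih > 0) {
    dihedral_contact_ratio * eps_contact * max(n_con, 1) / n_dih
  } else 0
  ## non-native pairs: all (i, j), j - i >= min_sep, not in the contact set
  all_pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  all_pairs <- all_pairs[(all_pairs[, 2] - all_pairs[, 1]) >= topology$min_sep, ,
                         drop = FALSE]
  key <- all_pairs[, 1] * (n + 1L) + all_pairs[, 2]
  ckey <- topology$contacts[, 1] * (n + 1L) + topology$contacts[, 2]
  nonnative <- all_pairs[!(key %in% ckey), , drop = FALSE]

  structure(
    list(topology = topology, k_bond = k_bond, k_angle = k_angle,
         k_dihedral = rep(k_d, n_dih), eps_contact = eps_contact,
         sigma_g = sigma_g, r_ex = r_ex, cage = cage,
         nonnative = matrix(as.integer(nonnative), ncol = 2)),
    class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf(
    "forcefield: %d beads, %d contacts, %d non-native pairs%s\n",
    x$topology$n_beads, nrow(x$topology$contacts), nrow(x$nonnative),
    if (!is.null(x$cage)) sprintf(", cage L = %g nm", x$cage$L) else ", bulk"))
  invisible(x)
}

## flat list handed to the C++ kernels (0-based indices)
ff_to_cpp <- function(ff) {
  topo <- ff$topology
  n <- topo$n_beads
  nb <- length(topo$bond_r0)
  bonds <- cbind(seq_len(nb), seq_len(nb) + 1L) - 1L
  na <- length(topo$angle_th0)
  angles <- cbind(seq_len(na), seq_len(na) + 1L, seq_len(na) + 2L) - 1L
  nd <- length(topo$dihedral_phi0)
  dihedrals <- cbind(seq_len(nd), seq_len(nd) + 1L, seq_len(nd) + 2L,
                     seq_len(nd) + 3L) - 1L
  list(bonds = matrix(as.integer(bonds), ncol = 2), bond_r0 = topo$bond_r0,
       k_bond = ff$k_bond,
       angles = matrix(as.integer(angles), ncol = 3),
       angle_th0 = topo$angle_th0, k_angle = ff$k_angle,
       dihedrals = matrix(as.integer(dihedrals), ncol = 4),
       dihedral_phi0 = topo$dihedral_phi0, k_dihedral = ff$k_dihedral,
       contacts = topo$contacts - 1L, contact_r0 = topo$contact_r0,
       eps_contact = ff$eps_contact, sigma_g = ff$sigma_g, r_ex = ff$r_ex,
       nonnative = ff$nonnative - 1L,
       has_cage = !is.null(ff$cage),
       cage_L = if (!is.null(ff$cage)) ff$cage$L_A else 0,
       cage_eps = if (!is.null(ff$cage)) ff$cage$eps_c else 0,
       cage_cutoff = if (!is.null(ff$cage)) ff$cage$cutoff else 0)
}

#' Total potential energy and per-term components
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param ff [forcefield()]
#' @return list with `total` (epsilon) and named `components`
#'   (`bond`, `angle`, `dihedral`, `contact`, `nonnative`, `cage`).
#' @export
total_energy <- function(coords, ff) {
  stopifnot(inherits(ff, "forcefield"))
  coords <- as.matrix(coords)
  if (nrow(coords) != ff$topology$n_beads) stop("coords/topology size mismatch")
  .ff_energy_cpp(coords, ff_to_cpp(ff))
}

#' Analytic forces (-gradient of [total_energy()])
#'
#' @inheritParams total_energy
#' @return n x 3 matrix of forces in epsilon/Angstrom.
#' @export
forces <- function(coords, ff) {
  stopifnot(inherits(ff, "forcefield"))
  coords <- as.matrix(coords)
  if (nrow(coords) != ff$topology$n_beads) stop("coords/topology size mismatch")
  .ff_forces_cpp(coords, ff_to_cpp(ff))
}

#' Write / read forcefield parameters as a flat key-value config
#'
#' @param ff [forcefield()]; `topo_path` is written next to it.
#' @param path config file path.
#' @param topo_path path for the topology table (default `paste0(path, ".topo")`).
#' @return `path` / a `forcefield`, invisibly.
#' @export
write_forcefield_config <- function(ff, path, topo_path = paste0(path, ".topo")) {
  write_topology(ff$topology, topo_path)
  kv <- c(sprintf("topology=%s", basename(topo_path)),
          sprintf("k_bond=%.10g", ff$k_bond),
          sprintf("k_angle=%.10g", ff$k_angle),
          sprintf("eps_contact=%.10g", ff$eps_contact),
          sprintf("sigma_g=%.10g", ff$sigma_g),
          sprintf("r_ex=%.10g", ff$r_ex),
          sprintf("k_dihedral=%.10g",
                  if (length(ff$k_dihedral)) ff$k_dihedral[1] else 0))
  if (!is.null(ff$cage)) {
    kv <- c(kv, sprintf("cage_L=%.10g", ff$cage$L),
            sprintf("cage_eps=%.10g", ff$cage$eps_c),
            sprintf("cage_cutoff=%.10g", ff$cage$cutoff))
  }
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_forcefield_config
#' @export
read_forcefield_config <- function(path) {
  kv <- readLines(path)
  kv <- kv[nzchar(kv) & !startsWith(kv, "#")]
  keys <- sub("=.*", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  get <- function(k, default = NULL) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  topo <- read_topology(file.path(dirname(path), get("topology")))
  cage <- if (!is.null(get("cage_L"))) {
    cage_spec(as.numeric(get("cage_L")), as.numeric(get("cage_eps", "10")),
              as.numeric(get("cage_cutoff", "2")))
  } else NULL
  ff <- forcefield(topo, k_bond = as.numeric(get("k_bond", "100")),
                   k_angle = as.numeric(get("k_angle", "20")),
                   eps_contact = as.numeric(get("eps_contact", "1")),
                   sigma_g = as.numeric(get("sigma_g", "0.5")),
                   r_ex = as.numeric(get("r_ex", "4")), cage = cage)
  invisible(ff)
}
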