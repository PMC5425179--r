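# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

fx_trefoil <- function() fx("trefoil", function() {
  make_trefoil_chain(35L, "left", tail_N = 4L, tail_C = 4L, seed = 1L)
})

fx_trefoil_right <- function() fx("trefoil_right", function() {
  make_trefoil_chain(35L, "right", tail_N = 4L, tail_C = 4L, seed = 1L)
})

fx_unknot <- function() fx("unknot", function() make_unknotted_chain(35L, seed = 2L))

fx_topology <- function() fx("topology", function() {
  build_native_topology(fx_trefoil())
})

fx_ff <- function() fx("ff", function() forcefield(fx_topology()))

# parametric curves at protein-like scale
curve_trefoil <- function(n = 60, scale = 10) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(sin(tt) + 2 * sin(2 * tt), cos(tt) - 2 * cos(2 * tt),
        -sin(3 * tt)) * scale
}

curve_figure_eight <- function(n = 70, scale = 8) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind((2 + cos(2 * tt)) * cos(3 * tt),
        (2 + cos(2 * tt)) * sin(3 * tt),
        sin(4 * tt)) * scale
}

# independent 3D writhe oracle: discretised Gauss double integral over
# segment pairs of a closed polygon
writhe_gauss <- function(x, subdiv = 4) {
  n <- nrow(x)
  w <- 0
  u <- (seq_len(subdiv) - 0.5) / subdiv
  for (i in seq_len(n)) {
    ia <- x[i, ]; ib <- x[(i %% n) + 1, ]
    d1 <- (ib - ia) / subdiv
    for (j in seq_len(n)) {
      if (i >= j) next
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      ja <- x[j, ]; jb <- x[(j %% n) + 1, ]
      d2 <- (jb - ja) / subdiv
      for (a in u) for (b in u) {
        r1 <- ia + a * (ib - ia)
        r2 <- ja + b * (jb - ja)
        r12 <- r1 - r2
        cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
                d1[3] * d2[1] - d1[1] * d2[3],
                d1[1] * d2[2] - d1[2] * d2[1])
        w <- w + sum(cr * r12) / sum(r12^2)^1.5
      }
    }
  }
  2 * w / (4 * pi)
}

# seeded self-avoiding-ish random walk used by knot-invariance tests
random_walk_chain <- function(n, seed, step = 3.8) {
  set.seed(seed)
  x <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2)) * step
      cand <- x[i - 1, ] + d
      if (i <= 3) break
      dmin <- min(sqrt(rowSums(sweep(x[1:(i - 2), , drop = FALSE], 2,
                                     cand)^2)))
      if (dmin > 1.0) break
    }
    x[i, ] <- cand
  }
  x
}

# minimal PDB text fixture writer
write_pdb_lines <- function(path, lines) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1.0, altloc = " ", icode = " ") {
  sprintf("ATOM  %5d %-4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f  0.00           C",
          serial, paste0(" ", name), altloc, resname, chain, resno, icode,
          x, y, z, occ)
}

# a 2-bead harmonic "dimer" exercises the integrator with trivial forces
dimer_topology <- function() {
  structure(list(n_beads = 2L, bond_r0 = 3.8, angle_th0 = numeric(0),
                 dihedral_phi0 = numeric(0),
                 contacts = matrix(integer(0), ncol = 2,
                                   dimnames = list(NULL, c("i", "j"))),
                 contact_r0 = numeric(0), min_sep = 4L, residue_ids = 1:2,
                 chain_id = "A"), class = "native_topology")
}

dimer_coords <- rbind(c(0, 0, 0), c(3.8, 0, 0))

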