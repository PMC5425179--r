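test_that("read_pdb parses minimal files, orders beads, resolves altLocs", {
  tf <- withr::local_tempfile(fileext = ".pdb")

  ## single CA record parses to a single (flagged) bead
  write_pdb_lines(tf, c(pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3), "END"))
  s <- read_pdb(tf, "A")
  expect_equal(nrow(s$coords), 1L)
  expect_true(s$flagged)
  expect_equal(unname(s$coords[1, ]), c(1, 2, 3))

  ## altLoc: highest occupancy wins, ties broken by file order
  write_pdb_lines(tf, c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 9, 9, 9, occ = 0.4, altloc = "B"),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0, occ = 0.6, altloc = "A"),
    pdb_atom_line(4, "CA", "SER", "A", 3, 7.6, 0, 0),
    pdb_atom_line(5, "CA", "LEU", "A", 4, 11.4, 0, 0),
    pdb_atom_line(6, "CA", "VAL", "A", 5, 15.2, 0, 0),
    "END"))
  s <- read_pdb(tf, "A")
  expect_equal(nrow(s$coords), 5L)
  expect_false(s$flagged)
  expect_equal(unname(s$coords[2, ]), c(3.8, 0, 0))
  expect_equal(s$residue_names[2], "GLY")

  ## non-CA atoms ignored; beads ordered by residue number
  write_pdb_lines(tf, c(
    pdb_atom_line(1, "CA", "ALA", "A", 3, 7.6, 0, 0),
    pdb_atom_line(2, "N", "ALA", "A", 1, 99, 99, 99),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(4, "CA", "ALA", "A", 2, 3.8, 0, 0),
    pdb_atom_line(5, "CA", "ALA", "A", 4, 11.4, 0, 0),
    pdb_atom_line(6, "CA", "ALA", "A", 5, 15.2, 0, 0),
    "END"))
  s <- read_pdb(tf, "A")
  expect_equal(s$residue_ids, 1:5)
  expect_equal(s$coords[, 1], c(0, 3.8, 7.6, 11.4, 15.2))
})

test_that("read_pdb error contract: chain, CA, insertion codes, breaks", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(tf, c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "END"))
  expect_error(read_pdb(tf, "B"), "chain not found")
  expect_error(read_pdb("no/such/file.pdb"), "file not found")

  write_pdb_lines(tf, c(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0), "END"))
  expect_error(read_pdb(tf, "A"), "no CA atoms")

  write_pdb_lines(tf, c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 3.8, 0, 0, icode = "A"),
    "END"))
  expect_error(read_pdb(tf, "A"), "insertion codes")

  ## chain break: warning + flagged structure that topology refuses
  write_pdb_lines(tf, c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "ALA", "A", 3, 30, 0, 0),
    pdb_atom_line(4, "CA", "ALA", "A", 4, 33.8, 0, 0),
    pdb_atom_line(5, "CA", "ALA", "A", 5, 37.6, 0, 0),
    "END"))
  expect_warning(s <- read_pdb(tf, "A"), "chain break")
  expect_true(s$flagged)
  expect_error(build_native_topology(s), "broken chain")
})

test_that("write_pdb_ca round-trips through read_pdb", {
  s <- fx_unknot()
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ca(s, tf)
  s2 <- read_pdb(tf, "A")
  expect_equal(nrow(s2$coords), nrow(s$coords))
  expect_equal(s2$coords, unname(s$coords), tolerance = 1e-3)
  expect_false(s2$flagged)
})

test_that("build_native_topology: chain combinatorics and contact rules", {
  ## collinear chain: bonds/angles/dihedrals counts, zero contacts at 8 A
  line <- ca_structure(cbind(seq(0, by = 3.8, length.out = 10), 0, 0))
  topo <- build_native_topology(line, contact_cutoff = 8, min_sep = 4)
  expect_length(topo$bond_r0, 9L)
  expect_length(topo$angle_th0, 8L)
  expect_length(topo$dihedral_phi0, 7L)
  expect_equal(nrow(topo$contacts), 0L)

  ## brute-force oracle on the trefoil toy
  s <- fx_trefoil()
  topo <- fx_topology()
  d <- as.matrix(dist(s$coords))
  brute <- which(upper.tri(d) & d <= 8 &
                   abs(row(d) - col(d)) >= 4, arr.ind = TRUE)
  brute <- brute[order(brute[, 1], brute[, 2]), , drop = FALSE]
  expect_equal(nrow(topo$contacts), nrow(brute))
  expect_equal(topo$contacts[, 1], unname(pmin(brute[, 1], brute[, 2])))
  expect_equal(topo$contact_r0, d[brute], tolerance = 1e-12)

  ## every native contact is formed at native coordinates
  expect_equal(fraction_native(s$coords, topo), 1)

  ## determinism and monotonicity in cutoff / min_sep
  expect_identical(build_native_topology(s), build_native_topology(s))
  n8 <- nrow(build_native_topology(s, 8)$contacts)
  n10 <- nrow(build_native_topology(s, 10)$contacts)
  expect_gte(n10, n8)
  n_sep6 <- nrow(build_native_topology(s, 8, min_sep = 6)$contacts)
  expect_lte(n_sep6, n8)
  expect_error(build_native_topology(s, min_sep = 2), "min_sep")
})

test_that("topology serialization round-trips", {
  topo <- fx_topology()
  tf <- withr::local_tempfile(fileext = ".topo")
  write_topology(topo, tf)
  t2 <- read_topology(tf)
  expect_equal(t2$n_beads, topo$n_beads)
  expect_equal(t2$bond_r0, topo$bond_r0, tolerance = 1e-9)
  expect_equal(t2$angle_th0, topo$angle_th0, tolerance = 1e-9)
  expect_equal(t2$dihedral_phi0, topo$dihedral_phi0, tolerance = 1e-9)
  expect_equal(t2$contacts, topo$contacts)
  expect_equal(t2$contact_r0, topo$contact_r0, tolerance = 1e-9)
})

test_that("ca_structure invariants are enforced", {
  expect_error(ca_structure(cbind(1:5, 1:5, 1:5), residue_ids = c(1, 2, 2, 3, 4)),
               "duplicate")
  expect_error(ca_structure(cbind(1:5, 1:5, 1:5), residue_ids = c(5, 4, 3, 2, 1)),
               "increasing")
  ## bead distances outside [2.5, 4.5] flag the structure
  s <- ca_structure(cbind(seq(0, by = 5, length.out = 6), 0, 0))
  expect_true(s$flagged)
})
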