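Package: knotcage
Title: Structure-Based Folding Simulations of Knotted Proteins in Chaperonin-Like Cages
Version: 0.1.0
Authors@R:
    person("knotcage", "developers", email = "knotcage@example.org", role = c("aut", "cre"))
Description: Coarse-grained (C-alpha, structure-based) Langevin folding
    simulations of proteins, optionally confined to a repulsive cylindrical
    cage that mimics the chaperonin cavity. Includes knot detection for open
    chains (KMT reduction, deterministic closure, Alexander-determinant
    typing, writhe-based trefoil chirality and subchain fingerprints),
    reaction coordinates (fraction of native contacts Q, radius of gyration,
    asphericity, knotting probability P_K(Q)), WHAM thermodynamics (heat
    capacity, folding temperature, free-energy profiles F(Q)), transition and
    first-passage kinetics, and folding-pathway diagnostics (per-contact
    formation profiles, backtracking detection, RMSD clustering). A synthetic
    generator produces trefoil-knotted and unknotted toy chains so the whole
    pipeline runs end-to-end without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
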