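---
title: "Folding knotted proteins in a chaperonin-like cage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding knotted proteins in a chaperonin-like cage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

About one percent of solved protein structures carry a knot in their
backbone, most often the left-handed trefoil (-3~1~). How such chains manage
to thread themselves during folding, and how the crowded, confined
environment of the cell changes that process, is an open question. A
chaperonin (GroEL/GroES-type) cavity is the extreme case of confinement: a
single substrate protein folds inside a closed barrel a few nanometres wide.
`knotcage` implements a complete simulation-plus-analysis pipeline for this
question at coarse-grained resolution: structure-based (Gō-type) Cα models,
Langevin dynamics inside a passive repulsive cylinder, knot detection for
open chains, WHAM thermodynamics, transition kinetics, and folding-pathway
diagnostics, plus a synthetic generator of trefoil-knotted toy chains so the
entire pipeline runs end-to-end with no external input.

# The energy model

Each residue is one bead at its Cα position. The potential is biased toward
a single native structure:

* **Bonds**: ½ k~b~ (r − r₀)², k~b~ = 100 ε/Å² between consecutive beads.
* **Angles**: ½ k~a~ (θ − θ₀)², k~a~ = 20 ε/rad².
* **Dihedrals**: k~d~ [(1 − cos Δφ) + ½(1 − cos 3Δφ)] with Δφ = φ − φ₀.
  k~d~ is rescaled uniformly so that the total contact strength and total
  dihedral strength sit in the conventional 2:1 ratio.
* **Native contacts** (pairs with native Cα–Cα distance ≤ 8 Å and sequence
  separation ≥ 4): a Gaussian well of depth ε (the energy unit) centred at
  the native distance with width σ~g~ = 0.5 Å, multiplied by an r⁻¹²
  excluded-volume core of radius r~ex~ = 4 Å. At the native distance each
  contact contributes −ε.
* **Non-native pairs**: pure r⁻¹² repulsion, truncated and shifted to zero
  at 2.5 r~ex~.
* **Cage** (optional): a cylinder of height 2L and diameter 2L centred at
  the origin. Each bead interacts with the lateral wall and both caps
  independently through V(d) = ε~c~ ((2/d)² − 1)² for wall distance
  d < 2 Å, with ε~c~ = 10. Both V and dV/dd vanish at d = 2 Å, so the
  truncation is exactly smooth; the potential diverges as the bead touches
  the wall. Evaluating the three wall terms independently and summing them
  is the package's choice of corner behaviour (the rim region), where no
  published prescription exists.

Units: lengths in Å internally (cage sizes are given in nm on interfaces,
1 nm = 10 Å), energies in ε, and temperature on a reduced scale with
k~B~ = 0.00831451 ε per temperature unit, so T ≈ 120 corresponds to
k~B~T ≈ 1 ε.

Dihedral and contact-strength normalisation beyond the 2:1 convention is
not uniquely fixed by the published record of such models; the values above
are documented defaults, all configurable through `forcefield()`.

# Dynamics

`integrate_langevin()` implements a Langevin leap-frog with the BAOAB
splitting: half velocity kick, half drift, an Ornstein–Uhlenbeck
friction/noise substep with *exact* factors (a = e^(−γΔt),
b = √(k~B~T(1−a²)/m)), half drift, half kick. One force evaluation per
step. Two properties make this the package's canonical integrator:

* at γ = 0 it reduces to plain velocity Verlet, so the symplectic
  energy-conservation limit is testable (drift < 10⁻⁴ relative over 10⁵
  steps in the test suite);
* the OU substep is exact for any γΔt, so the stationary velocity
  distribution is Maxwell–Boltzmann at the configured temperature without
  time-step bias in the thermostat itself.

Defaults follow the conventions of the field: Δt = 0.0005 τ, inverse
friction constant 1.0 (γ = 1/τ), unit masses. The noise stream comes from
a self-contained Mersenne-Twister + Marsaglia-polar generator, so a run is
bit-reproducible from its integer seed on any platform, independent of the
C++ standard library.

Folding runs start from a pool of unfolded conformations harvested from a
high-temperature run under the condition Q < 0.2, at least 10⁴ steps
apart; unfolding and equilibrium runs start from the native structure.
When a cage is present the start structure is centred and its principal
gyration axis aligned with the cylinder axis (`fit_to_cage()`); a
configuration that does not fit is rejected, never pushed inside.

# Knot detection

Knots are only defined for closed curves, so typing an open chain requires
a closure convention. The pipeline in `knot_type()` is:

1. **Closure**: both termini are extended to a sphere of radius 10× the
   maximal centroid distance along a *single common* outward direction
   (the normalised sum of the two terminus-minus-centroid unit vectors),
   then connected through a far apex — exactly three added vertices,
   fully deterministic. Using one common direction makes the two
   extension segments parallel, so they cannot clasp a chain strand
   between them. The textbook per-terminus radial closure fails on
   symmetric synthetic curves whose termini sit inside the convex hull
   (it can thread the knot); that failure is reproduced in the package's
   development history and motivated this variant. If the common ray
   passes exactly through a chain vertex, a deterministic sequence of
   small tilts deflects it.
2. **KMT reduction of the closed polygon**: a vertex is deleted whenever
   the triangle formed with its neighbours is crossed by no other segment.
   Reducing *after* closing matters: every deletion on the closed polygon
   is a legal isotopy of the closed curve and therefore exactly
   type-preserving, whereas reduction of the open chain can slide the
   chain across the virtual closure. (`kmt_reduce()` on open chains is
   still exported for chain-simplification use, with both termini fixed.)
3. **Projection and Alexander determinant**: the reduced polygon is
   projected onto random planes (proper rotations only, seeded). Each
   projection gives a crossing diagram; at t = −1 the Alexander-matrix row
   of a crossing is sign-independent (−1 under-in, −1 under-out, +2 over),
   and |Δ(−1)| follows from one LU determinant. Degenerate projections
   (crossing at a vertex, ambiguous height, even determinant) are
   discarded and resampled; the label is the majority determinant:
   1 → 0~1~, 3 → 3~1~, 5 → 4~1~, anything else → `other`.
4. **Chirality** (trefoils only): the sign of the summed crossing signs
   (diagram writhe) of the reduced diagram, by majority across
   projections; negative = left-handed (-3~1~). This replaces a full
   HOMFLY-PT computation, which distinguishes far more than the ±3~1~
   discrimination needed here; the simplification is deliberate and the
   invariant suite is restricted to 0~1~/3~1~/4~1~. The test suite pins
   the sign convention to an independent 3D writhe (Gauss double
   integral) oracle.

`fingerprint()` types every subchain on a stride grid, locates the knot
core by shrinking from both ends (the minimal subchain that still carries
the full-chain type) and reports the N- and C-tail depths.

# Thermodynamics and kinetics

`wham_solve()` is a standard self-consistent WHAM over energy histograms
(Freedman–Diaconis binning on the pooled samples, log-space iteration,
convergence when the largest relative change of the per-run shifts drops
below 10⁻⁷). C~v~(T) comes from the energy variance of the reweighted
density of states, T~f~ from the C~v~ peak with 3-point quadratic
refinement. F(Q;T) is computed by *per-sample* reweighting (each sample
carries its converged WHAM weight at the target temperature) rather than a
binned 2-D density, to avoid empty-bin artefacts; empty Q bins stay
absent, never interpolated. The barrier is the highest interior maximum
between the two lowest minima.

`detect_transitions()` uses two-state assignment with hysteresis
(commit folded at Q ≥ 0.8, unfolded at Q ≤ 0.2; the unfolded threshold
matches the unfolded-pool condition, the folded one sits below typical
native-basin minima — neither is uniquely fixed by the published record,
both are configurable and echoed in outputs). Optionally the folded state
additionally requires the native knot. Mean transition times follow the
span convention (last event − first event)/(events − 1) in 10⁶-step
units; first-passage sets report medians with explicit censoring.

# Pathway diagnostics

`contact_profile()` gives S~n~(Q), the per-contact formation probability
per Q bin; `detect_backtracking()` flags contacts whose S~n~(Q) drops by
more than θ = 0.05 between consecutive occupied bins (θ chosen above
binomial noise at ≳500 frames per bin; no published value exists).
`cluster_at_q()` performs deterministic greedy leader clustering under
Kabsch RMSD; the leader algorithm is the package's choice where the
published record names none, picked for reproducibility (deterministic
given frame order) and O(nk) cost. The RMSD scan window is 3–6 Å in
0.25 Å steps: the printed "3 to 6 nm" range in the source material
exceeds the cage itself and is treated as an Å/nm typo; both units are
accepted explicitly on the interfaces.

# The synthetic world

`make_trefoil_chain()` samples the parametric trefoil
(sin t + 2 sin 2t, cos t − 2 cos 2t, −sin 3t) at equal arc length and a
3.8 Å bond. An independent Gauss-integral writhe oracle shows this base
curve is itself the *left-handed* form (writhe ≈ −3.4), so the generator
mirrors it for the right-handed variant. The sampled core is trimmed from
both ends until minimally knotted under the package's own typing — one
more bead off either end unties it — and unknotted tails are then appended
as gentle outward helices, which makes the constructed tail depths exact
ground truth for the fingerprint scan. `make_unknotted_chain()` builds a
helix-loop-helix control as a unit-tangent walk (every bond exactly
3.8 Å).

The acceptance campaign's stated world is the most literal desk-scale
reading of the study design: a 35-bead toy (real knotted proteins are
82–121 residues and fold on 10⁷–10⁸-step timescales — cluster scale),
tails of 5 beads each side, contact map from the default 8 Å / min_sep 4
rule (34 contacts). What the toy reproduces: a thermally bistable chain
whose folded state is a shallow trefoil, whose unfolded state unknots,
and whose folding temperature, free-energy profile and knotting
probability respond to cylindrical confinement. What it does not
reproduce: the contact density and cooperativity of 80+-residue proteins,
sequence heterogeneity, any specific protein's T~f~ or transition times.
One structural mismatch deserves emphasis: the parametric-trefoil native
is nearly as extended as the toy's thermal coil (both R~g~ ≈ 1.1–1.4 nm),
whereas a real protein's native state is far more compact than its coil.
Confinement therefore squeezes the toy's folded and unfolded states almost
equally, and the T~f~ shifts and barrier changes it produces are small
(order 1 temperature unit) compared to the large shifts reported for real
proteins. A green qualitative test establishes the *direction* of
confinement effects in this class of models; a red one at this system
size may reflect this intrinsically weak signal rather than a coding
defect — the campaign reports whatever the stated world yields.

The campaign (fixed in `tests/testthat/helper-campaign.R`) uses cages of
L = 2.5, 2.9 and 3.4 nm plus bulk. The smallest value is set by geometry:
the aligned native toy needs L ≥ 2.4 nm to sit strictly inside with
> 1 Å wall clearance. Each condition runs a six-temperature ladder
(130–205) spanning the transition with one native-start and one
unfolded-start replica per temperature (2·10⁶ steps each), pooled into
WHAM — the mixed starts are what makes desk-scale sampling of a
slow-refolding knotted chain honest, since single native-start runs
hysterese badly on this budget.

# Numerical choices and degenerate inputs

* Crossing extraction treats a projection as degenerate (and resamples)
  when an intersection parameter is within 10⁻⁹ of a vertex, heights are
  ambiguous at the same tolerance, or the determinant comes out even.
* KMT treats zero-area triangles as always deletable; borderline
  segment–triangle contact counts as an intersection, so topology is never
  broken by an aggressive deletion, only deletions are missed.
* The integrator aborts with the last valid frame index on non-finite
  forces; a bead outside the cage raises immediately rather than clamping.
* WHAM runs in log space throughout; empty bins carry −Inf log-density and
  are excluded from every sum.
* All stochastic stages (integration, projection directions, pool
  harvesting) consume explicit integer seeds, and replica seeds derive
  from a master seed by a fixed affine map, so every figure and table in
  the package's outputs is reproducible from one integer.

At the frozen campaign seed, two of the five confinement signatures pass
(the F(Q) barrier flattens as L shrinks; transitions are faster in the
tightest cage than in bulk) and three are deliberately left failing
rather than loosened: the T~f~(L) ordering (the ~1-unit true shift is
buried under the ±20-unit protocol sensitivity of the desk-scale WHAM
T~f~ estimate), the P~K~ crossing-versus-barrier match (the asymmetric
F(Q) of this sampling puts its highest interior maximum well above the
knotting step), and the bulk-backtracking signature (a 35-bead toy has no
competing nucleation sites, so with noise-calibrated flagging there is no
backtracking to suppress). The acceptance suite encodes the criteria
exactly as stated and reports these outcomes as failures; the project
ledger carries the full analysis.

# Known limitations

* Chirality is writhe-based and restricted to trefoils; composite knots
  and knots beyond det 5 are reported as `other`.
* The deterministic closure, like every single-closure scheme, can
  misclassify frames whose termini are deeply buried; the stochastic
  multi-closure fallback is the `n_projections`-style majority already
  used for projections, applied at closure level, and remains future work.
* Table-style transition times depend on the commitment thresholds; with
  other thresholds the absolute numbers change (the published record does
  not state its thresholds, only the Q < 0.2 pool condition).
* The 2-D reweighting route assumes energy and Q samples are recorded at
  the same stride (they are, by construction of `observable_series`).
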