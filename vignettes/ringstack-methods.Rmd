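---
title: "Methods: geometry, dynamics and binding analysis of stacked ring assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, dynamics and binding analysis of stacked ring assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringstack)
```

# Scope

Sm-superfamily RNA chaperones such as Hfq assemble into cyclic homo-oligomers
(hexamers in the Hfq branch) that can stack head-to-tail into double rings in
crystal lattices and, under some conditions, in solution. `ringstack`
implements the quantitative analyses such an assembly invites: how similar
are the subunits, how are the two rings related as rigid bodies, how much
surface is buried between them, what collective motions does an elastic
network predict, what conformation do bound nucleotides adopt, and how
tightly does the ring bind RNA in a fluorescence-polarization (FP) assay.
Every analysis can be exercised end to end on synthetic inputs produced by
the package's own generators, so the whole pipeline is testable without any
external coordinate files.

# Structure input and output

PDB ATOM/HETATM records are parsed through `bio3d`; `ringstack` adds the
pieces that matter here and that the `bio3d` reader discards: `CRYST1` is
mapped to a unit-cell object and `ANISOU` records are merged onto their
atoms using the standard integer convention $U_{ij} = \mathrm{int}/10^4$ Å².
Writing emits `CRYST1`, fixed-width atom records (coordinates to 3 decimals,
occupancy/B to 2) and one `ANISOU` line per atom that carries a tensor, so a
parse–write–parse cycle is a fixed point at those precisions.

Two conventions are applied at read time and are worth stating:

* **Alternate locations.** Only the highest-occupancy conformer of each
  alternate group is kept by default (ties broken by the alt-loc letter);
  `keep_alt = TRUE` retains everything. Downstream analyses assume one
  position per atom, and occupancy-weighted averaging would blur torsions.
* **Model selection.** Multi-model files default to model 1.

Residue numbering is preserved verbatim, including non-positive numbers, so
expression-tag residues numbered ≤ 0 survive a round trip. Rotational
symmetry expansion (`expand_rotational_symmetry()`) applies only pure
rotations about a given axis — enough to rebuild a hexamer from one subunit
deposited with crystallographic 6-fold symmetry — and deliberately stops
short of general space-group operators.

# Subunit superposition and clustering

Pairwise superposition uses the closed-form least-squares (Kabsch) rotation
from the singular value decomposition of the coordinate covariance, with the
determinant-sign correction so the result is always a proper rotation:
a chiral point set is never matched to its mirror image. Atoms are paired by
residue number and atom name within a selection; the presets `"main-chain"`
(N, CA, C, O) and `"CA"` cover the common cases. The test suite checks the
minimized RMSD against an independent quaternion (Horn) closed form to
1e-8 Å.

A multiple alignment is summarized two ways:

* `mean_reference()` iterates "align all structures to the running mean,
  re-average" until the mean moves less than a tolerance; the summed squared
  RMSD to the mean is non-increasing across iterations.
* `rmsd_matrix()` collects all pairwise RMSDs; `hierarchical_cluster()`
  then applies either complete linkage or Ward's variance-minimizing
  criterion. For Ward we use the `ward.D2` form, which is the correct
  variance-minimizing update when the input is a distance matrix. An RMSD
  matrix is not guaranteed to be a Euclidean dissimilarity; consuming it as
  one is a documented convention of this analysis (the common practice for
  conformer ensembles), not a metric theorem. Labels are sorted before
  clustering so merge ties resolve deterministically by label order.

`similarity_edges()` reports the deepest dendrogram levels as a weighted
edge list (weight = 1/RMSD, capped for zero distances) — the circular-graph
view of which subunits resemble which. `sidechain_chi_compare()` computes
side-chain χ1/χ2 by the IUPAC atom quadruples and reports circular
differences; residues with missing atoms are flagged rather than fatal.

# Ring and stack geometry

Each ring is reduced to one anchor point per subunit (by default the
centroid of its CA atoms). Three primitives operate on those anchors:

* `principal_axes()` — eigen-decomposition of the unit-mass inertia tensor
  about the centroid (mass weighting is available but off by default, since
  none of the analyses here requires it), moments ascending, axis signs
  fixed by making each axis's largest component positive.
* `best_fit_plane()` — total-least-squares plane via SVD; the normal is the
  least-variance direction, signed into the +z hemisphere.
* `ring_signed_normal()` — the right-hand-rule normal of the subunit
  traversal order, which (unlike the plane fit) distinguishes a flipped
  ring.

`stack_geometry()` then defines the rigid-body relation of two n-fold rings:

* **tilt (δ)** — angle between the two plane normals, folded to ≤ 90°; the
  same quantity from the largest-moment inertia axes is reported as a
  cross-check (they agree within 0.2° for planar anchor sets).
* **rise** — separation of ring centroids along ring A's normal.
* **in-plane rotation (Δ)** — after rotating ring B's normal onto ring A's
  by the minimal rotation, the circular mean of the azimuthal offsets of
  matched subunit anchors, reported modulo 360°/n and folded into
  (−180°/n, 180°/n]. Because the subunits are equivalent, Δ is only defined
  modulo the ring symmetry; the circular mean is taken on n-times-folded
  angles so that offsets straddling the sector boundary average correctly.
  Subunit correspondence is the azimuth-rank pairing; the traversal sense is
  fixed by the orientation detected from the signed normals (a flipped ring
  runs the azimuth circle backwards). For identical subunits both senses can
  produce self-consistent pairings, which is why the sense is decided by the
  detected orientation rather than searched.

The generator applies, in order: optional flip (180° about x), Δ about z,
δ about x, rise along +z. The two rotations do not commute, so the order is
part of the contract, and `stack_geometry()` recovers a zero-noise generated
stack exactly (numerical tolerance ~1e-12) across a grid of (Δ, δ) values.

# Surface areas

`shrake_rupley()` is the classic surface-dot method: each atom's accessible
sphere (van der Waals radius + probe, default 1.4 Å) is sampled with a
deterministic golden-spiral point set — chosen over random sampling so
results are exactly reproducible at any dot count — and a dot is exposed if
it lies outside every neighbour's accessible sphere. Radii are element-based
(Bondi-style values); an element without a radius is an error naming the
atom, unless an explicit fallback radius is supplied.

Buried surface area follows the standard decomposition
BSA = ASA(A) + ASA(B) − ASA(AB) on identical atom sets. Published interface
areas are often quoted as a consensus over several independent programs;
`buried_surface_area()` emulates that spread with an ensemble over dot
densities (320/640/960/1280/1920 by default) of the one implementation,
reporting the ensemble mean ± SD. This reproduces the *spirit* of a
multi-method consensus (sensitivity of the number to quadrature) while
remaining dependency-free; it does not reproduce the larger between-program
spread caused by different radii sets and algorithms. Heteroatoms are
excluded from BSA by default because a protein-defined ring–ring interface
is the quantity of interest; selections with `class = "all"` include them.

Quadrature accuracy is pinned by analytic oracles: an isolated atom against
the exact sphere area (≤ 0.5% at 960 dots) and an overlapping pair against
the spherical-cap closed form (≤ 1%).

# Elastic network modes

`build_anm()` constructs the standard anisotropic network model on CA nodes:
for every pair within the cutoff (default 15 Å) the 3×3 super-element is
$-\gamma\, \hat r \hat r^{\mathsf T}$ with $\gamma = 1$ by default, diagonal
blocks minus the row sums. The full dense spectrum is attached (the systems
here are a few hundred nodes at most, so dense `eigen()` is the simplest
correct solver). Zero modes are counted with a scale-free threshold
$\lambda < 10^{-6}\lambda_{\max}$: a connected network has exactly six, and
a disconnected one warns with the component count. The suite cross-checks
the Hessian against an independent elastic-network implementation
(`bio3d`'s ANM force field) to 1e-8.

The question asked of the dodecamer — does a soft mode counter-rotate the
two rings? — is answered with an explicit statistic rather than visual
inspection: `ring_rotation_overlap()` reports, per nontrivial mode, the
absolute cosine overlap with the normalized field $+\omega\times r$ on ring
A and $-\omega\times r$ on ring B (each ring about its own centroid). On the
synthetic double ring the best overlap among the 20 softest modes is ~0.7,
comfortably above the 0.5 acceptance line fixed from the oracle run.

`b_eq()` converts an anisotropic ADP tensor to the equivalent isotropic
B-factor, $B_{eq} = 8\pi^2\,\mathrm{tr}(U)/3$, flagging non-positive traces.

# Nucleotide conformation and contacts

Torsions follow the IUPAC sign convention (validated against `bio3d`).
The glycosidic torsion χ uses O4′–C1′–N1–C2 for pyrimidines and
O4′–C1′–N9–C4 for purines, with *anti* defined as |χ| ≥ 90°. Sugar pucker
uses the Altona–Sundaralingam pseudorotation relations in the convention
$\nu_j = \nu_{\max}\cos(P + 144°(j-2))$, so C3′-endo sits near P = 18° and
C2′-endo near 162°; the class comes from the 20 standard 18° bins and the
hemisphere from North = P ∈ [270°, 360°) ∪ [0°, 90°). Rings with amplitude
below 5° are flagged amplitude-undefined instead of being given a class.
Different published conventions (e.g. alternative amplitude definitions) can
shift P by under a degree, which is why the package's own round-trip
tolerance is 2°.

Contact tables are distance-plus-element only: pairs with both atoms N or O
at ≤ 3.5 Å are labelled hydrogen-bond *candidates*. The deposited models
this mirrors carry no hydrogens, so no angle term is possible; the label is
deliberately a candidate, not an assignment. π-stacking uses common-practice
thresholds (centroid ≤ 4.5 Å, plane angle ≤ 30°, lateral offset ≤ 2.5 Å),
all exposed as parameters since no single standard exists.

# Crystallographic bookkeeping

`cell_volume()` implements the triclinic closed form (tested against the
metric-tensor determinant); `matthews()` gives $V_M = V/(ZM)$ and solvent
fraction $1 - 1.23/V_M$. The constant 1.23 Å³/Da corresponds to a partial
specific volume of ~0.74 cm³/g and reproduces the printed solvent contents
of both crystal forms from their printed $V_M$ values, which is the evidence
for adopting it. `protein_mass()` sums standard average (or monoisotopic)
residue masses plus one water; the average table is verified against an
independent proteomics library in the tests. Resolution-dependent Matthews
*probabilities* are out of scope — only the deterministic $V_M$ is computed.

# Binding isotherms

FP data are handled in millipolarization, mP = 1000·(I∥ − I⊥)/(I∥ + I⊥),
with titrant concentrations in hexamer-molar units (the functional unit of
the ring; a ×6 conversion applies if data were recorded per monomer).
Two models are fitted by unweighted Levenberg–Marquardt least squares
(`minpack.lm`), replicate points individually by default:

* **Four-parameter logistic** in $x = \log_{10}[\mathrm{titrant}]$:
  $mP(x) = A_2 + (A_1 - A_2)/(1 + e^{(x - x_0)/dx})$ — plateaus $A_1$
  (dilute) and $A_2$ (saturated), midpoint $x_0 = \log_{10} K_{d,app}$, and
  width $dx$ in decades. The exact algebraic form is reconstructed from the
  stated properties of the curve (sigmoid in log concentration, midpoint at
  $x_0$, width governed by $dx$); since the slope-factor convention varies
  between communities, the slope is always reported both ways, as $dx$ and
  as $n_H = 1/(dx\,\ln 10)$.
* **Single-site depletion isotherm**: the exact 1:1 quadratic solution for
  the bound-probe fraction with probe total $L$,
  $f = \big(T + L + K_d - \sqrt{(T + L + K_d)^2 - 4TL}\big)/(2L)$.
  Its half-saturation point is exactly $T = K_d + L/2$, so fitting the
  logistic (free-ligand) model to depletion-limited data inflates the
  apparent $K_d$ by $L/2$ — the package states the offset in terms of the
  *fixed species'* total, which is the mathematically forced reading of the
  quadratic model even where informal descriptions name the titrated
  "receptor". `compare_fits()` reports both estimates, their percent
  difference, and the predicted $L/2$ offset for context.

Automatic starting values (plateaus from the extreme quartiles, midpoint
from the half-height crossing) make the fits reliable across the simulated
regimes; $K_d$ is parameterized on the log scale for positivity, with the
standard error mapped back by the delta method.

# Synthetic data: what it emulates and what it does not

The generators define the conditions under which the package certifies
itself:

* `make_ring()` / `make_stacked_rings()` place rigid copies of a 10-atom
  asymmetric point-cloud subunit (one CA per pseudo-residue) with exact
  cyclic symmetry, then add i.i.d. Gaussian coordinate noise. The default
  geometry (ring radius 12 Å, rise 12 Å, subunit extent ~10 Å) is scaled
  down from a real hexamer but chosen so the assembly is *contiguous*: one
  connected component at the 15 Å elastic-network cutoff and a nonzero
  ring–ring burial, the two topological features of the real dodecamer the
  downstream analyses depend on. The default relative transform (Δ = 4°,
  δ = 1.5°) is a small rotation-plus-tilt of the kind the stacked rings
  exhibit. The FP simulator defaults mirror the assay design: 5 nM labelled
  probe, 18 two-fold serial dilutions from 5 µM (hexamer), 3 replicates,
  and 5 mP Gaussian read noise (a typical plate-reader scatter; the assay
  description does not state one).
* What passing on synthetic data shows: the geometric, spectral and
  statistical machinery is correct — generators invert analyses to
  tolerance, oracles agree, recovery rates hold.
* What it does not show: behaviour on real side-chain chemistry, crystal
  packing, or non-Gaussian noise. Point clouds have no rotamers, no
  sequence, and no realistic mass distribution; the quantitative reference
  values of the deposited structures (sub-0.3 Å subunit RMSDs, ~3700 Ų of
  inter-ring burial) can only be reproduced from the deposited coordinate
  files, which users must supply.

All generators are pure functions of their arguments and a seed, restore
the global RNG state, and return bit-identical output for the same seed.

# Numerical choices and degenerate inputs

* Collinear point sets are rejected by the inertia/plane fits (singular
  geometry); near-degenerate inertia moments are flagged.
* Zero distances in similarity edges are capped at a documented maximum
  weight (1e6) instead of dividing by zero.
* Angles are reported in (−180°, 180°]; classification bin boundaries are
  closed/open exactly as documented above.
* The sugar generator builds the furanose by sequential placement from
  internal coordinates and then refines the five ring atoms against the
  full bond/angle/torsion target by least squares; a ring-closure residual
  above 0.1 Å is an error rather than a silently strained ring.
* Problem sizes used by the test-suite and the acceptance script — rings of
  6×10 atoms, dodecamers of 120 nodes, 18-point titrations with 3
  replicates, 200-seed recovery runs — were chosen as the smallest sizes at
  which every statistic stabilizes; all complete in a few seconds.

# Known limitations

* PDB only; no mmCIF writing, no space-group symmetry beyond pure
  rotations, no hydrogens.
* SASA is quadrature-based, not analytic; accuracy is bounded by the dot
  count (quantified above).
* Hydrogen-bond detection is a distance/element heuristic.
* The depletion model fixes the Hill slope at 1 by construction; cooperative
  depletion-corrected fitting is out of scope.
* Checks tied to deposited crystal structures run only when the user places
  those files under `tests/testthat/data/`; they are reported as failures,
  not skipped, when absent.
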