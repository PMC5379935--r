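# ringstack

Quantitative analysis of cyclic protein oligomers and head-to-tail stacked
double rings — the quaternary architecture of Sm-superfamily RNA chaperones
such as Hfq — together with the fluorescence-polarization (FP) binding
analysis used to measure their RNA affinities.

The package is aimed at structural biologists who have (or simulate) a ring
assembly and want the standard derived quantities in one place:

* **Coordinate I/O** — PDB reading/writing with anisotropic displacement
  parameters (ANISOU, with B_eq = 8π²·tr(U)/3), unit cells (CRYST1), atom
  selections, and rotational-symmetry expansion of an asymmetric unit.
* **Subunit comparison** — least-squares (Kabsch) superposition with the
  proper-rotation constraint, RMSD distance matrices, an iterative mean
  reference structure, and agglomerative clustering (complete or Ward
  linkage) of ring subunits.
* **Stack geometry** — principal inertia axes, best-fit planes, and the
  inter-ring in-plane rotation Δ, tilt δ and rise of a double ring, with Δ
  defined via matched-subunit azimuths modulo the ring symmetry.
* **Surface burial** — Shrake–Rupley solvent-accessible surface area on a
  deterministic golden-spiral dot set, and the interface burial
  BSA = ASA(A) + ASA(B) − ASA(AB), reported as an ensemble mean ± SD over
  dot densities.
* **Elastic-network modes** — the anisotropic network model (γ = 1,
  15 Å cutoff, CA nodes), its 3N − 6 nontrivial modes, and a cosine-overlap
  statistic for ring counter-rotation (+ω×r on one ring, −ω×r on the
  other).
* **Nucleotide conformation** — glycosidic torsion χ with syn/anti
  classification, Altona–Sundaralingam pseudorotation phase P and amplitude
  (ν_j = ν_max cos(P + 144°(j−2)); C3′-endo ≈ 18°, C2′-endo ≈ 162°), pucker
  classes, protein⋯RNA contact tables and π-stacking checks.
* **Crystallographic bookkeeping** — triclinic cell volume, Matthews
  coefficient V_M = V/(Z·M) with solvent fraction 1 − 1.23/V_M, protein
  masses from sequence, reflections-per-atom ratios.
* **Binding isotherms** — mP = 1000·(I∥−I⊥)/(I∥+I⊥); a four-parameter
  logistic in log₁₀ concentration (midpoint x₀ = log₁₀ K_d,app, width dx,
  Hill slope n_H = 1/(dx·ln 10)) and the exact single-site
  receptor-depletion quadratic, whose half-saturation sits at
  K_d + [probe]/2 — so the package also quantifies the [probe]/2 inflation
  of apparent K_d when depletion is ignored.
* **Synthetic data** — generators for noisy C_n rings, stacked double rings
  with controllable (Δ, δ, rise), furanose rings at any requested pucker and
  χ, and FP titrations from either binding model, so every analysis above is
  testable without downloads.

## Worked example

```r
library(ringstack)

# a synthetic head-to-tail double ring: rotation 4 deg, tilt 1.5 deg,
# rise 12 A, 0.05 A coordinate noise
st <- make_stacked_rings(delta_deg = 4, tilt_deg = 1.5, rise = 12,
                         noise_sigma = 0.05, seed = 1)
stack_geometry(select_atoms(st, chains = LETTERS[1:6]),
               select_atoms(st, chains = LETTERS[7:12]), n_fold = 6)
#> stack geometry (n=6, parallel): delta 3.960 deg, tilt 1.528 deg, rise 12.001 A

# how much surface the two rings bury against each other
bsa <- buried_surface_area(st,
         atom_selection(chains = LETTERS[1:6], class = "polymer"),
         atom_selection(chains = LETTERS[7:12], class = "polymer"))
c(mean = bsa$ensemble_mean, sd = bsa$ensemble_sd)
#>      mean        sd
#> 72.684095  1.177197

# elastic-network modes: is there a soft ring counter-rotation?
anm <- build_anm(st, gamma = 1, cutoff = 15)
ov <- ring_rotation_overlap(anm, which(st$atoms$chain %in% LETTERS[1:6]),
                            which(st$atoms$chain %in% LETTERS[7:12]), k = 20)
max(ov$overlap)
#> [1] 0.7228786   # mode 4 of the 20 softest is 72% counter-rotation

# Matthews coefficient of a triclinic cell with 12 copies of a 9482.9 Da
# monomer
matthews(unit_cell(63.46, 66.06, 66.10, 60.05, 83.94, 77.17),
         z = 12, mass = 9482.9)
#> V = 234099 A^3, Z = 12, M = 9482.9 Da -> V_M = 2.06 A^3/Da, solvent 40.21%

# fit a noisy FP titration (5 nM probe, 18 two-fold dilutions, 3 replicates)
titr <- simulate_fp("logistic4",
                    list(A1 = 50, A2 = 250, x0 = log10(21.3e-9),
                         dx = 1 / (1.3 * log(10))),
                    noise_sd_mP = 5, seed = 1)
fit_model(titr, "logistic4")
#> binding_fit (logistic4): Kd = 2.15e-08 M (se 5.7e-10), rss = 863 over 54 points
#>   dx = 0.3214 decades, n_H = 1.351

# nucleotide conformation round trip at a South pucker
u2 <- make_sugar_ring(P_deg = 163.2, nu_max = 38, chi_deg = -116.8)
pseudorotation(u2)$pucker_class
#> [1] "C2'-endo"
glycosidic_chi(u2)$conformer
#> [1] "anti"
```

The recovered K_d,app of 21.5 nM (generated: 21.3 nM) with n_H = 1.35
(generated: 1.3) shows the fit machinery recovering the generating
parameters through realistic 5 mP read noise; the geometry, burial and mode
numbers likewise come back within tolerance of the generating transform.

`run_full_analysis(analysis_config(...))` chains all of the stages —
clustering, stack geometry, burial, modes, nucleotide tables, contacts,
Matthews, binding — into a single deterministic report object.

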