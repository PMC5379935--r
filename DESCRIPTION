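Package: ringstack
Title: Geometry, Dynamics and Binding Analysis of Stacked Ring Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing cyclic protein oligomers and head-to-tail
    stacked double rings, of the kind formed by Sm-superfamily RNA chaperones
    such as Hfq. Provides PDB coordinate input/output with anisotropic
    displacement parameters, rotational symmetry expansion, least-squares
    (Kabsch) superposition with RMSD distance matrices and hierarchical
    clustering of ring subunits, inter-ring rotation/tilt/rise geometry from
    inertia tensors and best-fit planes, Shrake-Rupley solvent-accessible and
    buried surface areas, anisotropic network model normal modes with ring
    counter-rotation overlaps, nucleotide pseudorotation and glycosidic
    torsion analysis with contact and stacking tables, crystallographic
    bookkeeping (cell volume, Matthews coefficient, sequence masses), and
    fluorescence-polarization binding isotherm fitting with receptor-depletion
    correction. Includes generators for synthetic rings, stacked rings,
    furanose geometry and titration data so every analysis is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
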