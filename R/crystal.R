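# Crystallographic bookkeeping: triclinic cell volume, Matthews coefficient
# and solvent content, protein mass from sequence, data-to-parameter ratios.

#' Unit-cell volume
#'
#' General triclinic formula
#' `V = abc sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g)`.
#'
#' @param cell a [unit_cell()].
#' @return volume in Angstrom^3.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("invalid cell: non-positive volume discriminant")
  cell$a * cell$b * cell$c * sqrt(disc)
}

#' Matthews coefficient and solvent content
#'
#' `V_M = V_cell / (Z * M)` (Angstrom^3 per Dalton) and solvent fraction
#' `1 - solvent_constant / V_M`, clamped to [0, 1]. The default constant
#' 1.23 Angstrom^3/Da corresponds to a protein partial specific volume of
#' about 0.74 cm^3/g.
#'
#' @param cell a [unit_cell()].
#' @param z number of protein copies per unit cell (>= 1).
#' @param mass molecular mass of one copy, Da.
#' @param solvent_constant Angstrom^3/Da.
#' @return a `matthews_result`: list with `cell_volume`, `z`, `mass`, `v_m`,
#'   `solvent_fraction`.
#' @export
matthews <- function(cell, z, mass, solvent_constant = 1.23) {
  stopifnot(z >= 1, mass > 0)
  v <- cell_volume(cell)
  v_m <- v / (z * mass)
  if (v_m < 1.0)
    warning("implausible Matthews coefficient (", signif(v_m, 3),
            " < 1.0 A^3/Da)")
  solv <- min(1, max(0, 1 - solvent_constant / v_m))
  structure(list(cell_volume = v, z = as.integer(z), mass = mass,
                 v_m = v_m, solvent_fraction = solv),
            class = "matthews_result")
}

#' @export
print.matthews_result <- function(x, ...) {
  cat(sprintf("V = %.0f A^3, Z = %d, M = %.1f Da -> V_M = %.2f A^3/Da, solvent %.2f%%\n",
              x$cell_volume, x$z, x$mass, x$v_m, 100 * x$solvent_fraction))
  invisible(x)
}

# residue (amino-acid minus water) masses, Da
aa_masses_average <- c(
  G = 57.0513, A = 71.0779, S = 87.0773, P = 97.1152, V = 99.1311,
  T = 101.1039, C = 103.1429, L = 113.1576, I = 113.1576, N = 114.1026,
  D = 115.0874, Q = 128.1292, K = 128.1723, E = 129.1155, M = 131.1961,
  H = 137.1393, F = 147.1739, R = 156.1857, Y = 163.1733, W = 186.2099)
aa_masses_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
water_mass <- c(average = 18.01528, monoisotopic = 18.010565)

#' Protein mass from a one-letter sequence
#'
#' Sum of standard residue masses plus one water; average masses by
#' default. Additive up to the water term:
#' `protein_mass(xy) = protein_mass(x) + protein_mass(y) - water`.
#'
#' @param sequence one-letter amino-acid string (20 standard letters;
#'   whitespace ignored).
#' @param kind `"average"` or `"monoisotopic"`.
#' @return mass in Da.
#' @export
protein_mass <- function(sequence, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  letters_ <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  if (length(letters_) == 0) stop("empty sequence")
  tab <- if (kind == "average") aa_masses_average else aa_masses_mono
  m <- tab[letters_]
  if (any(is.na(m)))
    stop("unknown residue letter: ", letters_[which(is.na(m))[1]])
  sum(m) + unname(water_mass[if (kind == "average") "average"
                             else "monoisotopic"])
}

#' Data-to-parameter ratio: unique reflections per atom
#'
#' @param n_unique_reflections number of unique reflections (> 0).
#' @param n_atoms number of refined atoms (> 0).
#' @return the quotient (full precision; display rounds to 1 decimal).
#' @export
reflections_per_atom <- function(n_unique_reflections, n_atoms) {
  if (n_atoms <= 0) stop("atom count must be positive")
  if (n_unique_reflections <= 0) stop("reflection count must be positive")
  structure(n_unique_reflections / n_atoms, class = "refl_per_atom")
}

#' @export
print.refl_per_atom <- function(x, ...) {
  cat(sprintf("%.1f reflections per atom\n", unclass(x)))
  invisible(x)
}
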