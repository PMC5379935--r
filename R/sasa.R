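# Solvent-accessible surface area by the Shrake-Rupley surface-dot method,
# and buried surface area between two parts of a complex, with an ensemble
# over dot densities standing in for a multi-program consensus.

# element-based van der Waals radii (Angstrom); Bondi-style values
vdw_radii_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  FE = 1.80, ZN = 1.39, MG = 1.73, MN = 1.73, "NA" = 2.27, K = 2.75,
  CA = 2.31)

#' Van der Waals radii for a model's atoms
#' @param model a [structure_model()].
#' @param default_radius radius used for elements absent from the table;
#'   `NA` (the default) raises an error naming the first offending atom.
#' @return numeric vector of radii, Angstrom.
#' @export
vdw_radii <- function(model, default_radius = NA) {
  elt <- toupper(model$atoms$elt)
  r <- vdw_radii_table[elt]
  miss <- which(is.na(r))
  if (length(miss) > 0) {
    if (is.na(default_radius))
      stop("no van der Waals radius for atom ",
           atom_id(model$atoms[miss[1], ]), " (element '",
           elt[miss[1]], "')")
    r[miss] <- default_radius
  }
  unname(r)
}

#' Deterministic unit-sphere dot set (golden spiral)
#' @param n number of dots (>= 92 recommended).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_dots <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic surface-dot counting: each atom's solvent-accessible sphere
#' (vdW radius + probe) is sampled with a deterministic golden-spiral dot
#' set; a dot is exposed when it lies outside every neighbouring atom's
#' accessible sphere. Per-atom area = exposed fraction x sphere area.
#'
#' @param model a [structure_model()].
#' @param probe_radius solvent probe radius, Angstrom.
#' @param n_dots dots per atom (>= 92).
#' @param default_radius see [vdw_radii()].
#' @return a `sasa_result`: list with `per_atom` (Angstrom^2, named by atom
#'   serial), `total`, `probe_radius`, `n_dots`.
#' @export
shrake_rupley <- function(model, probe_radius = 1.4, n_dots = 960,
                          default_radius = NA) {
  stopifnot(n_dots >= 92)
  n <- n_atoms(model)
  if (n == 0) stop("empty model")
  rad <- vdw_radii(model, default_radius) + probe_radius
  xyz <- xyz_matrix(model)
  dots <- sphere_dots(n_dots)
  # neighbour lists from the full pairwise distance matrix
  d2 <- as.matrix(stats::dist(xyz))^2
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      per_atom[i] <- 4 * pi * rad[i]^2
      next
    }
    pts <- sweep(dots * rad[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_dots)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 >= rad[j]^2
    }
    per_atom[i] <- 4 * pi * rad[i]^2 * sum(exposed) / n_dots
  }
  names(per_atom) <- model$atoms$serial
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe_radius = probe_radius, n_dots = n_dots),
            class = "sasa_result")
}

default_bsa_ensemble <- function(probe = 1.4) {
  lapply(c(320, 640, 960, 1280, 1920), function(d)
    list(probe = probe, n_dots = d))
}

#' Buried surface area between two parts of a complex
#'
#' BSA = ASA(A) + ASA(B) - ASA(AB) on identical atom sets. The common
#' consensus over several area programs is emulated by an ensemble over dot
#' densities of the one Shrake-Rupley implementation; the mean and standard
#' deviation over the ensemble are reported. Heteroatoms are excluded by
#' default (the ring-ring interface is protein-defined); pass selections
#' with `class = "all"` to include them.
#'
#' @param complex_model a [structure_model()] containing both parts.
#' @param part_a,part_b [atom_selection()]s; must select disjoint atom sets.
#' @param ensemble list of `list(probe, n_dots)` settings; default dot
#'   densities 320/640/960/1280/1920 at probe 1.4.
#' @param reference_setting index of the ensemble entry whose ASA components
#'   are reported in the result (default: the middle one).
#' @param default_radius see [vdw_radii()].
#' @return a `bsa_result`: list with `asa_a`, `asa_b`, `asa_ab`, `bsa`
#'   (reference setting), `ensemble_mean`, `ensemble_sd`, `ensemble`
#'   (per-setting table).
#' @export
buried_surface_area <- function(complex_model, part_a, part_b,
                                ensemble = default_bsa_ensemble(),
                                reference_setting = NULL,
                                default_radius = NA) {
  stopifnot(length(ensemble) >= 1)
  a <- select_atoms(complex_model, part_a)
  b <- select_atoms(complex_model, part_b)
  if (n_atoms(a) == 0 || n_atoms(b) == 0) stop("empty part selection")
  if (length(intersect(a$atoms$serial, b$atoms$serial)) > 0)
    stop("part definitions overlap")
  ab <- structure_model(rbind(a$atoms, b$atoms), cell = complex_model$cell,
                        title = complex_model$title)
  if (is.null(reference_setting))
    reference_setting <- ceiling(length(ensemble) / 2)
  rows <- lapply(ensemble, function(s) {
    asa_a <- shrake_rupley(a, s$probe, s$n_dots, default_radius)$total
    asa_b <- shrake_rupley(b, s$probe, s$n_dots, default_radius)$total
    asa_ab <- shrake_rupley(ab, s$probe, s$n_dots, default_radius)$total
    data.frame(probe = s$probe, n_dots = s$n_dots, asa_a = asa_a,
               asa_b = asa_b, asa_ab = asa_ab,
               bsa = asa_a + asa_b - asa_ab)
  })
  tab <- do.call(rbind, rows)
  ref <- tab[reference_setting, ]
  structure(list(asa_a = ref$asa_a, asa_b = ref$asa_b, asa_ab = ref$asa_ab,
                 bsa = ref$bsa,
                 ensemble_mean = mean(tab$bsa),
                 ensemble_sd = if (nrow(tab) > 1) stats::sd(tab$bsa) else 0,
                 ensemble = tab),
            class = "bsa_result")
}
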