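# Nucleotide conformational descriptors (glycosidic chi, pseudorotation
# phase/amplitude, pucker class) and protein...RNA contact / stacking tables.

#' Signed torsion angle of four points
#'
#' IUPAC sign convention: looking down the p2-p3 bond, a clockwise rotation
#' of the far bond is positive. Result in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return torsion in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b2^2) < 1e-12 || sum(b1^2) < 1e-12 || sum(b3^2) < 1e-12)
    stop("degenerate geometry: coincident points in torsion")
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("degenerate geometry: collinear points in torsion")
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

residue_atoms <- function(nucleotide) {
  at <- if (inherits(nucleotide, "structure_model")) nucleotide$atoms
        else nucleotide
  if (length(unique(paste(at$chain, at$resi, at$icode))) != 1)
    stop("expected a single-residue view")
  at
}

atom_xyz <- function(at, name) {
  i <- which(at$name == name)
  if (length(i) == 0) return(NULL)
  c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
}

#' Glycosidic torsion chi of a nucleotide
#'
#' chi is computed over O4'-C1'-N1-C2 for pyrimidines and O4'-C1'-N9-C4 for
#' purines (detected by the presence of N9). The syn/anti label follows the
#' |chi| >= 90 degree convention for anti.
#'
#' @param nucleotide single-residue [structure_model()] or atom table.
#' @return a `chi_result`: list with `chi` (degrees, (-180, 180]) and
#'   `conformer` (`"syn"` or `"anti"`).
#' @export
glycosidic_chi <- function(nucleotide) {
  at <- residue_atoms(nucleotide)
  purine <- !is.null(atom_xyz(at, "N9"))
  quad <- if (purine) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
  pts <- lapply(quad, atom_xyz, at = at)
  missing <- quad[vapply(pts, is.null, logical(1))]
  if (length(missing) > 0)
    stop("missing atoms for chi: ", paste(missing, collapse = ", "))
  chi <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  structure(list(chi = chi,
                 conformer = if (abs(chi) >= 90) "anti" else "syn"),
            class = "chi_result")
}

pucker_class_names <- c(
  "3T2", "C3'-endo", "3T4", "C4'-exo", "0T4",
  "O4'-endo", "0T1", "C1'-exo", "2T1", "C2'-endo",
  "2T3", "C3'-exo", "4T3", "C4'-endo", "4T0",
  "O4'-exo", "1T0", "C1'-endo", "1T2", "C2'-exo")

#' Furanose pseudorotation analysis
#'
#' Computes the five endocyclic torsions nu0..nu4 of the ribose ring
#' (cycle O4'-C1'-C2'-C3'-C4'), the pseudorotation phase P and amplitude
#' nu_max in the convention `nu_j = nu_max cos(P + 144 (j - 2))` (so
#' `nu_2 = nu_max cos P` and C3'-endo sits near P = 18 degrees), the pucker
#' class from the 20 standard 18-degree bins, and the N/S hemisphere
#' (North: P in [270, 360) or [0, 90)).
#'
#' @param nucleotide single-residue [structure_model()] or atom table with
#'   the furanose atoms O4', C1', C2', C3', C4'.
#' @return a `pucker_result`: list with `nu` (degrees), `P` ([0, 360)),
#'   `nu_max`, `pucker_class` (NA with `amplitude_undefined = TRUE` for a
#'   near-planar ring, nu_max < 5 degrees) and `hemisphere`.
#' @export
pseudorotation <- function(nucleotide) {
  at <- residue_atoms(nucleotide)
  ring <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  pts <- lapply(ring, atom_xyz, at = at)
  missing <- ring[vapply(pts, is.null, logical(1))]
  if (length(missing) > 0)
    stop("missing furanose atoms: ", paste(missing, collapse = ", "))
  p <- do.call(rbind, pts)
  # nu_j is the torsion about bond A_j - A_{j+1} of the cycle
  nu <- vapply(0:4, function(j) {
    i <- function(k) (k %% 5) + 1
    dihedral(p[i(j - 1), ], p[i(j), ], p[i(j + 1), ], p[i(j + 2), ])
  }, numeric(1))
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  P <- atan2(num, den) * 180 / pi
  if (nu[3] < 0) P <- P  # atan2 already handles the quadrant via den sign
  P <- P %% 360
  nu_max <- nu[3] / cos(P * pi / 180)
  res <- list(nu = nu, P = P, nu_max = abs(nu_max))
  if (abs(nu_max) < 5) {
    res$pucker_class <- NA_character_
    res$hemisphere <- NA_character_
    res$amplitude_undefined <- TRUE
  } else {
    res$pucker_class <- pucker_class_names[(round(P / 18) %% 20) + 1]
    res$hemisphere <- if (P < 90 || P >= 270) "North" else "South"
    res$amplitude_undefined <- FALSE
  }
  class(res) <- "pucker_result"
  res
}

atom_id <- function(at) {
  sprintf("%s/%s%d%s/%s", at$chain, at$resn, at$resi,
          ifelse(nzchar(at$icode), at$icode, ""), at$name)
}

#' Inter-group atom contact table
#'
#' Lists all atom pairs, one atom from each (disjoint) group, within
#' `cutoff` Angstrom. Pairs where both atoms are nitrogen or oxygen at
#' <= 3.5 Angstrom are labelled `hbond-candidate` (a distance-plus-element
#' heuristic; the models carry no hydrogens), all others `vdw`. Sorted by
#' distance.
#'
#' @param model a [structure_model()].
#' @param group_a,group_b [atom_selection()]s; must select disjoint atoms.
#' @param cutoff distance cutoff, Angstrom.
#' @param hbond_cutoff hydrogen-bond candidate distance, Angstrom.
#' @return data.frame with columns `atom_a`, `atom_b`, `distance`, `class`.
#' @export
contact_table <- function(model, group_a, group_b, cutoff = 3.6,
                          hbond_cutoff = 3.5) {
  a <- suppressWarnings(select_atoms(model, group_a))
  b <- suppressWarnings(select_atoms(model, group_b))
  empty <- data.frame(atom_a = character(0), atom_b = character(0),
                      distance = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (n_atoms(a) == 0 || n_atoms(b) == 0) {
    warning("empty contact group")
    return(empty)
  }
  if (length(intersect(a$atoms$serial, b$atoms$serial)) > 0)
    stop("contact groups must be disjoint")
  xa <- xyz_matrix(a); xb <- xyz_matrix(b)
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  dist <- sqrt(d2[hit])
  ea <- a$atoms$elt[hit[, 1]]; eb <- b$atoms$elt[hit[, 2]]
  cls <- ifelse(ea %in% c("N", "O") & eb %in% c("N", "O") &
                  dist <= hbond_cutoff, "hbond-candidate", "vdw")
  out <- data.frame(atom_a = atom_id(a$atoms[hit[, 1], ]),
                    atom_b = atom_id(b$atoms[hit[, 2], ]),
                    distance = dist, class = cls, stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Aromatic-ring stacking check
#'
#' Classifies two approximately planar ring atom sets as pi-stacked when the
#' ring centroids are within `max_centroid` Angstrom, the inter-plane angle
#' (folded to <= 90 degrees) is at most `max_angle`, and the lateral centroid
#' offset in ring A's plane is at most `max_offset`. Thresholds are common
#' practice, exposed as parameters. Rings with plane rms residual above
#' `planarity_rms` are flagged non-planar.
#'
#' @param ring_a_atoms,ring_b_atoms n x 3 coordinate matrices (n >= 5).
#' @param max_centroid,max_angle,max_offset,planarity_rms thresholds.
#' @return list with `centroid_distance`, `plane_angle`, `offset`,
#'   `is_stacked`, `nonplanar`.
#' @export
stacking_check <- function(ring_a_atoms, ring_b_atoms, max_centroid = 4.5,
                           max_angle = 30, max_offset = 2.5,
                           planarity_rms = 0.3) {
  ring_a_atoms <- as.matrix(ring_a_atoms)
  ring_b_atoms <- as.matrix(ring_b_atoms)
  stopifnot(nrow(ring_a_atoms) >= 5, nrow(ring_b_atoms) >= 5)
  pa <- best_fit_plane(ring_a_atoms)
  pb <- best_fit_plane(ring_b_atoms)
  nonplanar <- pa$rms_residual > planarity_rms || pb$rms_residual > planarity_rms
  dvec <- pb$centroid - pa$centroid
  cdist <- sqrt(sum(dvec^2))
  ang <- vec_angle(pa$normal, pb$normal)
  ang <- min(ang, 180 - ang)
  vertical <- abs(sum(dvec * pa$normal))
  offset <- sqrt(max(0, cdist^2 - vertical^2))
  list(centroid_distance = cdist, plane_angle = ang, offset = offset,
       is_stacked = !nonplanar && cdist <= max_centroid &&
         ang <= max_angle && offset <= max_offset,
       nonplanar = nonplanar)
}
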