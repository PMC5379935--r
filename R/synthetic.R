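# Generators for the idealized inputs the analyses assume: C-n symmetric
# rings, stacked double rings with controllable rotation/tilt/rise, furanose
# nucleotide geometry with requested pucker and glycosidic torsion, and
# sigmoidal fluorescence-polarization titrations. All are pure functions of
# their arguments and a seed.

with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  fn()
}

#' Default rigid subunit template
#'
#' A 10-atom asymmetric (chiral) point cloud standing in for a protein
#' subunit: ten pseudo-residues, one CA atom each, chain A. Rigid-body
#' analyses (superposition, clustering, ring geometry, elastic network
#' modes) only need an asymmetric rigid shape, not side-chain chemistry.
#'
#' @return a [structure_model()] with 10 atoms.
#' @export
subunit_template <- function() {
  # fixed, deliberately chiral coordinates (Angstrom)
  xyz <- matrix(c(
     0.0,  0.0,  0.0,
     3.8,  0.5,  1.2,
     6.9,  2.6, -2.4,
     9.1,  0.2,  4.8,
     7.4, -3.0,  2.7,
     4.2, -3.4, -3.6,
     2.0, -5.9,  0.9,
    -1.3, -4.6,  3.3,
    -2.4, -1.5, -2.7,
     1.0,  2.9,  6.6), ncol = 3, byrow = TRUE)
  at <- empty_atoms(10)
  at$serial <- 1:10
  at$name <- "CA"; at$elt <- "C"; at$alt <- ""; at$icode <- ""
  at$resn <- "ALA"; at$chain <- "A"; at$resi <- 1:10
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at$occ <- 1; at$b <- 0; at$het <- FALSE
  structure_model(at, title = "synthetic subunit template")
}

place_subunit <- function(template_xyz, k, n, radius) {
  # subunit centroid on a circle of the given radius in z = 0,
  # the subunit rotated rigidly with its position
  ctr <- colMeans(template_xyz)
  local <- sweep(template_xyz, 2, ctr)
  R <- rotation_about_axis(c(0, 0, 1), 360 * k / n)
  sweep(local %*% t(R), 2, c(radius, 0, 0) %*% t(R), "+")
}

#' Generate a synthetic C-n symmetric ring
#'
#' Places `n_subunits` rigid copies of the template around the z axis at the
#' given radius (exact cyclic symmetry), then adds i.i.d. Gaussian noise of
#' standard deviation `noise_sigma` to every coordinate. Chains are labelled
#' A, B, C, ... in placement order; residue numbering of the template is
#' preserved within each chain.
#'
#' @param n_subunits number of subunits (>= 3).
#' @param radius ring radius in Angstrom (> 0).
#' @param template subunit [structure_model()]; default [subunit_template()].
#' @param noise_sigma per-coordinate Gaussian noise sd, Angstrom (>= 0).
#' @param seed RNG seed; same seed gives bit-identical output.
#' @return a [structure_model()] of the ring, centred on the z axis.
#' @export
make_ring <- function(n_subunits = 6, radius = 12, template = NULL,
                      noise_sigma = 0, seed = 1) {
  stopifnot(n_subunits >= 3, radius > 0, noise_sigma >= 0)
  if (is.null(template)) template <- subunit_template()
  txyz <- xyz_matrix(template)
  out <- vector("list", n_subunits)
  for (k in seq_len(n_subunits) - 1) {
    ak <- template$atoms
    xyz <- place_subunit(txyz, k, n_subunits, radius)
    ak$x <- xyz[, 1]; ak$y <- xyz[, 2]; ak$z <- xyz[, 3]
    ak$chain <- chain_label_pool[k + 1]
    out[[k + 1]] <- ak
  }
  atoms <- do.call(rbind, out)
  atoms$serial <- seq_len(nrow(atoms))
  if (noise_sigma > 0) {
    noise <- with_seed(seed, function()
      matrix(stats::rnorm(3 * nrow(atoms), sd = noise_sigma), ncol = 3))
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  rownames(atoms) <- NULL
  structure_model(atoms, title = sprintf("synthetic C%d ring", n_subunits))
}

#' Generate a stacked double ring
#'
#' Builds an ideal ring A (see [make_ring()]), then derives ring B from it by
#' applying, in order: an optional flip (180 degrees about x, making the ring
#' normals anti-parallel, as in a head-to-head arrangement), the in-plane
#' rotation `delta_deg` about z, the tilt `tilt_deg` about x, and a
#' translation of `rise` along +z. The two rotations do not commute; the
#' order (flip, then delta, then tilt) is part of the contract. Gaussian
#' noise is then added to both rings independently. Ring A occupies the
#' first `n_subunits` chain labels, ring B the next ones.
#'
#' @inheritParams make_ring
#' @param delta_deg inter-ring in-plane rotation, degrees.
#' @param tilt_deg inter-ring tilt about x, degrees (|tilt| < 30).
#' @param rise axial separation of ring centroids, Angstrom (> 0).
#' @param flip_second_ring flip ring B so the plane normals are
#'   anti-parallel before the tilt is applied?
#' @return a [structure_model()] holding both rings.
#' @export
make_stacked_rings <- function(n_subunits = 6, radius = 12, template = NULL,
                               delta_deg = 4, tilt_deg = 1.5, rise = 12,
                               flip_second_ring = FALSE,
                               noise_sigma = 0, seed = 1) {
  stopifnot(rise > 0, abs(tilt_deg) < 30)
  ring_a <- make_ring(n_subunits, radius, template, noise_sigma = 0)
  xyz_a <- xyz_matrix(ring_a)
  M <- rotation_about_axis(c(1, 0, 0), tilt_deg) %*%
    rotation_about_axis(c(0, 0, 1), delta_deg)
  if (flip_second_ring) M <- M %*% rotation_about_axis(c(1, 0, 0), 180)
  xyz_b <- sweep(xyz_a %*% t(M), 2, c(0, 0, rise), "+")
  atoms_b <- ring_a$atoms
  atoms_b$x <- xyz_b[, 1]; atoms_b$y <- xyz_b[, 2]; atoms_b$z <- xyz_b[, 3]
  atoms_b$chain <- chain_label_pool[match(atoms_b$chain, chain_label_pool) +
                                      n_subunits]
  atoms <- rbind(ring_a$atoms, atoms_b)
  atoms$serial <- seq_len(nrow(atoms))
  if (noise_sigma > 0) {
    noise <- with_seed(seed, function()
      matrix(stats::rnorm(3 * nrow(atoms), sd = noise_sigma), ncol = 3))
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  rownames(atoms) <- NULL
  m <- structure_model(atoms, title = sprintf(
    "synthetic stacked rings (delta=%g, tilt=%g, rise=%g, flip=%s)",
    delta_deg, tilt_deg, rise, flip_second_ring))
  attr(m, "stack_params") <- list(delta_deg = delta_deg, tilt_deg = tilt_deg,
                                  rise = rise,
                                  flip_second_ring = flip_second_ring,
                                  n_subunits = n_subunits)
  m
}

# ---- furanose / nucleoside geometry -------------------------------------

#' Place an atom from internal coordinates (bond, angle, torsion)
#' @param a,b,c reference positions (the new atom bonds to `c`).
#' @param bond bond length c-new, Angstrom.
#' @param angle_deg angle b-c-new, degrees.
#' @param torsion_deg torsion a-b-c-new, degrees.
#' @return position 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  ab <- ab / sqrt(sum(ab^2))
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d[1] * bc + d[2] * m + d[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# target internal coordinates of the ribofuranose ring, cycle order
# O4' -> C1' -> C2' -> C3' -> C4' -> (O4')
ribose_bonds  <- c(1.414, 1.528, 1.525, 1.524, 1.453)  # A_j - A_{j+1}
ribose_angles <- c(109.6, 106.4, 101.5, 102.7, 105.5)  # at A_j

#' Endocyclic torsion targets for a given pucker
#'
#' Standard pseudorotation description of a five-membered ring:
#' `nu_j = nu_max * cos(P + 144 * (j - 2))` degrees, j = 0..4, in the
#' convention where `nu_2 = nu_max * cos(P)` and C3'-endo sits near P = 18.
#'
#' @param P_deg pseudorotation phase, degrees.
#' @param nu_max pucker amplitude, degrees.
#' @return numeric vector nu0..nu4, degrees.
#' @export
pucker_torsions <- function(P_deg, nu_max) {
  j <- 0:4
  nu_max * cos((P_deg + 144 * (j - 2)) * pi / 180)
}

#' Generate a ribonucleoside with a requested sugar pucker and chi
#'
#' Builds one uridine nucleoside: the furanose ring is constructed so its
#' endocyclic torsions match the pseudorotation targets
#' `nu_j = nu_max cos(P + 144 (j - 2))` (see [pucker_torsions()]), using
#' sequential placement from internal coordinates followed by a least-squares
#' refinement of the five ring atoms against the target bonds, angles and all
#' five torsions; the uracil base is then attached with the requested
#' glycosidic torsion chi (O4'-C1'-N1-C2).
#'
#' @param P_deg requested pseudorotation phase, degrees.
#' @param nu_max pucker amplitude, degrees, in (20, 50).
#' @param chi_deg requested glycosidic torsion, degrees.
#' @return a [structure_model()] of one residue (resn U).
#' @export
make_sugar_ring <- function(P_deg, nu_max = 38, chi_deg = -160) {
  stopifnot(nu_max > 20, nu_max < 50)
  nu <- pucker_torsions(P_deg, nu_max)
  # sequential build: O4', C1', C2' seeded, C3' by nu1, C4' by nu2
  p <- matrix(0, 5, 3)
  p[1, ] <- c(0, 0, 0)                               # O4'
  p[2, ] <- c(ribose_bonds[1], 0, 0)                 # C1'
  th <- ribose_angles[2] * pi / 180
  p[3, ] <- p[2, ] + ribose_bonds[2] *
    c(-cos(th), sin(th), 0)                          # C2'
  p[4, ] <- place_atom(p[1, ], p[2, ], p[3, ],
                       ribose_bonds[3], ribose_angles[3], nu[2])  # C3'
  p[5, ] <- place_atom(p[2, ], p[3, ], p[4, ],
                       ribose_bonds[4], ribose_angles[4], nu[3])  # C4'

  # refine all 15 coordinates against the full internal-coordinate target
  objective <- function(v) {
    q <- matrix(v, 5, 3)
    err <- 0
    for (j in 1:5) {
      jn <- j %% 5 + 1
      d <- sqrt(sum((q[jn, ] - q[j, ])^2))
      err <- err + (d - ribose_bonds[j])^2
      jp <- (j - 2) %% 5 + 1
      ang <- vec_angle(q[jp, ] - q[j, ], q[jn, ] - q[j, ])
      err <- err + ((ang - ribose_angles[j]) * pi / 180)^2
      jnn <- jn %% 5 + 1
      tors <- dihedral(q[jp, ], q[j, ], q[jn, ], q[jnn, ])
      err <- err + 2 * (ang_diff(tors, nu[j]) * pi / 180)^2
    }
    err
  }
  opt <- stats::optim(as.vector(p), objective, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  p <- matrix(opt$par, 5, 3)
  closure <- abs(sqrt(sum((p[1, ] - p[5, ])^2)) - ribose_bonds[5])
  if (closure > 0.1)
    stop("sugar-ring generation failed: closure residual ",
         signif(closure, 3), " Angstrom")

  o4 <- p[1, ]; c1 <- p[2, ]; c2s <- p[3, ]; c3s <- p[4, ]; c4s <- p[5, ]
  # base attachment: N1 on C1' (beta face), then C2 fixing chi exactly
  n1 <- place_atom(c2s, o4, c1, 1.48, 108.2, -122)
  c2b <- place_atom(o4, c1, n1, 1.383, 117.7, chi_deg)
  o2 <- place_atom(c1, n1, c2b, 1.22, 122.8, 0)
  n3 <- place_atom(c1, n1, c2b, 1.373, 114.8, 180)
  c4b <- place_atom(n1, c2b, n3, 1.382, 127.0, 0)
  o4b <- place_atom(c2b, n3, c4b, 1.23, 119.8, 180)
  c5b <- place_atom(c2b, n3, c4b, 1.44, 114.6, 0)
  c6b <- place_atom(n3, c4b, c5b, 1.34, 119.7, 0)

  names_ <- c("O4'", "C1'", "C2'", "C3'", "C4'",
              "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
  elts <- c("O", "C", "C", "C", "C", "N", "C", "O", "N", "C", "O", "C", "C")
  xyz <- rbind(p, n1, c2b, o2, n3, c4b, o4b, c5b, c6b)
  at <- empty_atoms(length(names_))
  at$serial <- seq_along(names_)
  at$name <- names_; at$elt <- elts; at$alt <- ""; at$icode <- ""
  at$resn <- "U"; at$chain <- "A"; at$resi <- 1L
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at$occ <- 1; at$b <- 0; at$het <- FALSE
  structure_model(at, title = sprintf(
    "synthetic uridine (P=%g, nu_max=%g, chi=%g)", P_deg, nu_max, chi_deg))
}

# ---- fluorescence-polarization titrations -------------------------------

#' Default hexamer-equivalent titration grid
#'
#' Eighteen two-fold serial dilutions from a 5 micromolar top concentration
#' (a 30 micromolar monomer stock expressed per hexamer), molar.
#' @return numeric vector, ascending.
#' @export
fp_default_grid <- function() sort(5e-6 / 2^(0:17))

#' Simulate a fluorescence-polarization titration
#'
#' Evaluates the chosen binding model on a concentration grid and adds
#' Gaussian read noise per replicate, reproducing the structure of a
#' plate-reader titration: `n_reps` replicate series over the same serial
#' dilution. Deterministic for a given seed.
#'
#' @param model_kind `"logistic4"` (four-parameter sigmoid in log10
#'   concentration) or `"depletion"` (single-site quadratic isotherm).
#' @param true_params named list of generating parameters. For
#'   `"logistic4"`: `A1`, `A2`, `x0` (log10 M), `dx` (decades). For
#'   `"depletion"`: `A1`, `A2`, `Kd` (M).
#' @param conc_grid titrant (hexamer) concentrations, M, strictly positive
#'   and sorted ascending; default [fp_default_grid()].
#' @param n_reps replicates per concentration (>= 1).
#' @param noise_sd_mP Gaussian noise sd in mP units.
#' @param probe_total fixed (labelled probe) concentration, M.
#' @param seed RNG seed.
#' @return an `fp_dataset`: data.frame with columns `conc_M`, `replicate`,
#'   `mP`, plus attributes `probe_total`, `model_kind`, `true_params`.
#' @export
simulate_fp <- function(model_kind = c("depletion", "logistic4"),
                        true_params = NULL, conc_grid = fp_default_grid(),
                        n_reps = 3, noise_sd_mP = 5, probe_total = 5e-9,
                        seed = 1) {
  model_kind <- match.arg(model_kind)
  stopifnot(all(conc_grid > 0), !is.unsorted(conc_grid), n_reps >= 1)
  if (is.null(true_params)) {
    true_params <- if (model_kind == "logistic4") {
      list(A1 = 50, A2 = 250, x0 = log10(21.3e-9), dx = 1 / (1.3 * log(10)))
    } else {
      list(A1 = 50, A2 = 250, Kd = 21.3e-9)
    }
  }
  mean_mP <- if (model_kind == "logistic4") {
    eval_logistic4(log10(conc_grid), true_params)
  } else {
    eval_depletion(conc_grid, c(true_params, list(probe_total = probe_total)))
  }
  df <- data.frame(conc_M = rep(conc_grid, times = n_reps),
                   replicate = rep(seq_len(n_reps), each = length(conc_grid)),
                   mP = rep(mean_mP, times = n_reps))
  if (noise_sd_mP > 0) {
    df$mP <- df$mP + with_seed(seed, function()
      stats::rnorm(nrow(df), sd = noise_sd_mP))
  }
  attr(df, "probe_total") <- probe_total
  attr(df, "model_kind") <- model_kind
  attr(df, "true_params") <- true_params
  class(df) <- c("fp_dataset", "data.frame")
  df
}
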