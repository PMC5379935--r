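# Pairwise and multiple rigid-body superposition, RMSD distance matrices,
# iterative mean-reference alignment, hierarchical clustering of subunits,
# and side-chain rotamer (chi) comparison.

#' Split a model into per-chain models
#' @param model a [structure_model()].
#' @return named list of single-chain [structure_model()]s, in order of
#'   first appearance.
#' @export
chain_models <- function(model) {
  chains <- unique(model$atoms$chain)
  out <- lapply(chains, function(ch)
    structure_model(model$atoms[model$atoms$chain == ch, , drop = FALSE],
                    cell = model$cell, title = model$title))
  names(out) <- chains
  out
}

atom_key <- function(at) paste(at$resi, at$icode, at$name, sep = "|")

# Match atoms of two single-selection tables by (res_seq, insertion code,
# atom name); falls back to positional matching when keys are not unique
# (e.g. multi-chain selections), requiring identical ordered atom names.
matched_indices <- function(at_a, at_b) {
  ka <- atom_key(at_a); kb <- atom_key(at_b)
  if (!anyDuplicated(ka) && !anyDuplicated(kb)) {
    common <- intersect(ka, kb)
    return(list(a = match(common, ka), b = match(common, kb)))
  }
  if (nrow(at_a) != nrow(at_b))
    stop("cannot match atoms positionally: ", nrow(at_a), " vs ",
         nrow(at_b), " atoms")
  bad <- which(at_a$name != at_b$name)
  if (length(bad) > 0)
    stop("atom name mismatch at position ", bad[1], ": ",
         at_a$name[bad[1]], " vs ", at_b$name[bad[1]])
  list(a = seq_len(nrow(at_a)), b = seq_len(nrow(at_b)))
}

kabsch <- function(xm, xr) {
  # proper least-squares rotation taking xm onto xr (rows = points)
  cm <- colMeans(xm); cr <- colMeans(xr)
  am <- sweep(xm, 2, cm); ar <- sweep(xr, 2, cr)
  H <- crossprod(am, ar)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cr - as.vector(R %*% cm)
  fit <- sweep(am %*% t(R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fit - xr)^2)))
  list(rotation = R, translation = tvec, rmsd = rmsd)
}

#' Least-squares pairwise superposition
#'
#' Optimal rigid-body (Kabsch) superposition of `mobile` onto `reference`
#' over a matched atom set. Atoms are matched by residue number, insertion
#' code and atom name within the given selection; reflections are excluded
#' by the determinant sign correction, so the returned rotation is always
#' proper.
#'
#' @param mobile,reference [structure_model()]s.
#' @param selection optional [atom_selection()] applied to both models.
#' @return a `superposition_result`: list with `rotation` (3x3, det +1),
#'   `translation` (Angstrom), `rmsd` (Angstrom) and `n_atoms`.
#' @export
superpose_pair <- function(mobile, reference, selection = NULL) {
  if (!is.null(selection)) {
    mobile <- select_atoms(mobile, selection)
    reference <- select_atoms(reference, selection)
  }
  idx <- matched_indices(mobile$atoms, reference$atoms)
  if (length(idx$a) < 3)
    stop("need at least 3 matched atoms, got ", length(idx$a))
  k <- kabsch(xyz_matrix(mobile)[idx$a, , drop = FALSE],
              xyz_matrix(reference)[idx$b, , drop = FALSE])
  structure(list(rotation = k$rotation, translation = k$translation,
                 rmsd = k$rmsd, n_atoms = length(idx$a)),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("superposition: rmsd %.4f Angstrom over %d atoms (rotation %.2f deg)\n",
              x$rmsd, x$n_atoms, ang))
  invisible(x)
}

#' Rotation angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return angle in degrees, in [0, 180].
#' @export
rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Apply a superposition to a model
#' @param model a [structure_model()].
#' @param sp a `superposition_result` from [superpose_pair()].
#' @return the transformed [structure_model()].
#' @export
apply_superposition <- function(model, sp) {
  xyz <- xyz_matrix(model) %*% t(sp$rotation)
  set_xyz(model, sweep(xyz, 2, sp$translation, "+"))
}

#' Pairwise RMSD distance matrix
#'
#' Superposes every pair of models over the selection and collects the
#' minimized RMSDs into a symmetric zero-diagonal matrix.
#'
#' @param models list of [structure_model()]s (length >= 2); names are used
#'   as labels, otherwise M1, M2, ...
#' @param selection optional [atom_selection()].
#' @return a `distance_matrix`: list with `labels` and symmetric matrix `d`.
#' @export
rmsd_matrix <- function(models, selection = NULL) {
  n <- length(models)
  stopifnot(n >= 2)
  labels <- names(models)
  if (is.null(labels)) labels <- paste0("M", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- tryCatch(superpose_pair(models[[i]], models[[j]], selection),
                   error = function(e)
                     stop("superposition failed for pair (", labels[i], ", ",
                          labels[j], "): ", conditionMessage(e)))
    d[i, j] <- d[j, i] <- sp$rmsd
  }
  structure(list(labels = labels, d = d), class = "distance_matrix")
}

#' Iterative mean-reference structure
#'
#' Aligns all models to a running mean and re-averages coordinates until the
#' mean moves by less than `tol` (RMSD between successive means). The sum of
#' squared RMSDs to the mean is non-increasing across iterations.
#'
#' @param models list of [structure_model()]s.
#' @param selection optional [atom_selection()].
#' @param max_iter maximum iterations (>= 1).
#' @param tol convergence threshold on the mean shift, Angstrom.
#' @return the converged mean as a [structure_model()] (atom identifiers
#'   from the first model), with attributes `iterations`, `converged`, and
#'   `objective` (sum of squared RMSDs per iteration).
#' @export
mean_reference <- function(models, selection = NULL, max_iter = 20,
                           tol = 1e-4) {
  stopifnot(length(models) >= 1, max_iter >= 1)
  sel <- lapply(models, function(m)
    if (is.null(selection)) m else select_atoms(m, selection))
  ref <- sel[[1]]
  if (length(models) == 1) {
    attr(ref, "iterations") <- 1L
    attr(ref, "converged") <- TRUE
    attr(ref, "objective") <- 0
    return(ref)
  }
  # common atom set across all models, in first-model order
  keys <- lapply(sel, function(m) atom_key(m$atoms))
  common <- Reduce(intersect, keys)
  if (length(common) < 3) stop("fewer than 3 atoms common to all models")
  coords <- lapply(seq_along(sel), function(i)
    xyz_matrix(sel[[i]])[match(common, keys[[i]]), , drop = FALSE])
  mean_xyz <- coords[[1]]
  objective <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    fits <- lapply(coords, function(x) {
      k <- kabsch(x, mean_xyz)
      sweep(sweep(x, 2, colMeans(x)) %*% t(k$rotation), 2,
            colMeans(mean_xyz), "+")
    })
    new_mean <- Reduce(`+`, fits) / length(fits)
    objective <- c(objective, sum(vapply(fits, function(f)
      mean(rowSums((f - new_mean)^2)), numeric(1))))
    shift <- sqrt(mean(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < tol) { converged <- TRUE; break }
  }
  base <- sel[[1]]
  base$atoms <- base$atoms[match(common, keys[[1]]), , drop = FALSE]
  rownames(base$atoms) <- NULL
  out <- set_xyz(base, mean_xyz)
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  attr(out, "objective") <- objective
  out
}

# ---- clustering ----------------------------------------------------------

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Clusters with either the complete-linkage criterion or Ward's
#' variance-minimization (the `ward.D2` form appropriate for a distance
#' matrix). The input RMSD matrix is consumed as a Euclidean-style
#' dissimilarity; labels are sorted lexicographically beforehand so merge
#' ties resolve deterministically by label order.
#'
#' @param dm a `distance_matrix` from [rmsd_matrix()], or a plain symmetric
#'   matrix with dimnames.
#' @param linkage `"complete"` or `"ward"`.
#' @return a `cluster_tree`: list with `merge`, `height`, `labels`,
#'   `linkage` and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(dm, linkage = c("complete", "ward")) {
  linkage <- match.arg(linkage)
  if (inherits(dm, "distance_matrix")) {
    d <- dm$d
  } else {
    d <- as.matrix(dm)
  }
  if (any(is.na(d)) || any(!is.finite(d)))
    stop("distance matrix contains NA or non-finite entries")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("M", seq_len(nrow(d)))
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d),
                      method = if (linkage == "ward") "ward.D2" else "complete")
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 linkage = linkage, hclust = hc),
            class = "cluster_tree")
}

#' Cut a cluster tree into k groups
#' @param tree a `cluster_tree`.
#' @param k number of groups, 1 <= k <= number of leaves.
#' @return named integer vector of group assignments.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  stats::cutree(tree$hclust, k = k)
}

#' Similarity edges from the deepest dendrogram levels
#'
#' Edge list for the `levels` lowest merges of the complete-linkage
#' dendrogram of `dm`: each merge contributes the closest cross-pair of the
#' two clusters it joins, weighted by 1/rmsd (capped at `max_weight` for
#' zero distances).
#'
#' @param dm a `distance_matrix`.
#' @param levels number of deepest merge levels to report.
#' @param max_weight weight assigned when a distance is exactly zero.
#' @return data.frame with columns `from`, `to`, `rmsd`, `weight`, `level`.
#' @export
similarity_edges <- function(dm, levels = 2, max_weight = 1e6) {
  tree <- hierarchical_cluster(dm, "complete")
  hc <- tree$hclust
  d <- dm$d[tree$labels, tree$labels]
  levels <- min(levels, nrow(hc$merge))
  members <- function(node) {
    if (node < 0) return(-node)
    c(members(hc$merge[node, 1]), members(hc$merge[node, 2]))
  }
  out <- list()
  for (lv in seq_len(levels)) {
    g1 <- members(hc$merge[lv, 1])
    g2 <- members(hc$merge[lv, 2])
    sub <- d[g1, g2, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- g1[ij[1]]; j <- g2[ij[2]]
    rmsd <- d[i, j]
    out[[lv]] <- data.frame(from = tree$labels[i], to = tree$labels[j],
                            rmsd = rmsd,
                            weight = if (rmsd > 0) min(1 / rmsd, max_weight)
                                     else max_weight,
                            level = lv, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- side-chain rotamers -------------------------------------------------

chi_atom_table <- function() {
  g <- function(res, chi1, chi2 = NA) list(chi1 = chi1, chi2 = chi2)
  list(
    SER = g("SER", c("N", "CA", "CB", "OG")),
    THR = g("THR", c("N", "CA", "CB", "OG1")),
    CYS = g("CYS", c("N", "CA", "CB", "SG")),
    VAL = g("VAL", c("N", "CA", "CB", "CG1")),
    ILE = g("ILE", c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
    LEU = g("LEU", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    ASP = g("ASP", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
    ASN = g("ASN", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
    HIS = g("HIS", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
    PHE = g("PHE", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    TYR = g("TYR", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    TRP = g("TRP", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    MET = g("MET", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD")),
    GLU = g("GLU", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
    GLN = g("GLN", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
    LYS = g("LYS", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
    ARG = g("ARG", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
    PRO = g("PRO", c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"))
  )
}

residue_torsion <- function(atoms, resi, quad) {
  rows <- atoms[atoms$resi == resi, , drop = FALSE]
  idx <- match(quad, rows$name)
  if (any(is.na(idx))) return(NA_real_)
  p <- as.matrix(rows[idx, c("x", "y", "z")])
  dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
}

#' Compare side-chain chi angles between two models
#'
#' Computes chi1/chi2 by the standard IUPAC atom quadruples for the listed
#' residues in both models and reports circular differences in
#' (-180, 180]. Residues with missing side-chain atoms are flagged in the
#' `complete` column rather than raising an error.
#'
#' @param model_a,model_b [structure_model()]s (single chain each, or
#'   restrict with `chain_a`/`chain_b`).
#' @param residues integer vector of residue numbers to compare.
#' @param chain_a,chain_b chain to use in each model (default: first).
#' @return data.frame with per-residue chi1/chi2 values and differences.
#' @export
sidechain_chi_compare <- function(model_a, model_b, residues,
                                  chain_a = NULL, chain_b = NULL) {
  tab <- chi_atom_table()
  pick <- function(m, ch) {
    if (is.null(ch)) ch <- m$atoms$chain[1]
    m$atoms[m$atoms$chain == ch & !m$atoms$het, , drop = FALSE]
  }
  at_a <- pick(model_a, chain_a)
  at_b <- pick(model_b, chain_b)
  rows <- lapply(residues, function(r) {
    resn <- at_a$resn[at_a$resi == r][1]
    spec <- tab[[resn]]
    if (is.null(spec))
      return(data.frame(resi = r, resn = resn, chi1_a = NA, chi1_b = NA,
                        dchi1 = NA, chi2_a = NA, chi2_b = NA, dchi2 = NA,
                        complete = FALSE))
    c1a <- residue_torsion(at_a, r, spec$chi1)
    c1b <- residue_torsion(at_b, r, spec$chi1)
    has2 <- !all(is.na(spec$chi2))
    c2a <- if (has2) residue_torsion(at_a, r, spec$chi2) else NA_real_
    c2b <- if (has2) residue_torsion(at_b, r, spec$chi2) else NA_real_
    data.frame(resi = r, resn = resn,
               chi1_a = c1a, chi1_b = c1b, dchi1 = ang_diff(c1a, c1b),
               chi2_a = c2a, chi2_b = c2b, dchi2 = ang_diff(c2a, c2b),
               complete = !is.na(c1a) && !is.na(c1b) &&
                 (!has2 || (!is.na(c2a) && !is.na(c2b))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
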