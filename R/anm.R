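# Anisotropic network model (ANM) normal modes on a coarse-grained
# (CA-only) representation, plus utilities for anisotropic displacement
# parameters (B_eq from the ADP tensor trace).

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Build an anisotropic network model
#'
#' Standard ANM super-element Hessian on the CA nodes of a model: for every
#' node pair within the interaction cutoff, the off-diagonal 3x3 block is
#' `-gamma (r_ij r_ij^T) / |r_ij|^2`; diagonal blocks are minus the row sums.
#' The full (dense, symmetric) eigen-decomposition is attached, eigenvalues
#' ascending. A connected contact graph has exactly six near-zero
#' (rigid-body) eigenvalues; a disconnected one raises a warning with the
#' component count.
#'
#' @param model a [structure_model()] (CA atoms are extracted; a model with
#'   no CA-named atoms uses all atoms as nodes).
#' @param gamma spring force constant (arbitrary units, default 1).
#' @param cutoff pairwise interaction cutoff, Angstrom (default 15).
#' @param zero_tol_factor zero-mode threshold as a fraction of the largest
#'   eigenvalue.
#' @return an `anm_model`: list with `nodes` (N x 3), `gamma`, `cutoff`,
#'   `hessian` (3N x 3N), `eigenvalues` (ascending), `eigenvectors`
#'   (columns), `n_zero`, `n_components`.
#' @export
build_anm <- function(model, gamma = 1, cutoff = 15,
                      zero_tol_factor = 1e-6) {
  ca <- suppressWarnings(select_atoms(model, atom_selection(preset = "CA")))
  if (n_atoms(ca) == 0) ca <- model
  nodes <- xyz_matrix(ca)
  n <- nrow(nodes)
  if (n < 2) stop("need at least 2 CA nodes")
  d2 <- as.matrix(stats::dist(nodes))^2
  contact <- d2 <= cutoff^2 & upper.tri(d2)
  H <- matrix(0, 3 * n, 3 * n)
  idx <- function(i) (3 * (i - 1) + 1):(3 * i)
  pairs <- which(contact, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    r <- nodes[j, ] - nodes[i, ]
    blk <- -gamma * tcrossprod(r) / sum(r^2)
    H[idx(i), idx(j)] <- blk
    H[idx(j), idx(i)] <- blk
    H[idx(i), idx(i)] <- H[idx(i), idx(i)] - blk
    H[idx(j), idx(j)] <- H[idx(j), idx(j)] - blk
  }
  adj <- d2 <= cutoff^2
  diag(adj) <- FALSE
  comp <- graph_components(adj)
  n_comp <- max(comp)
  e <- eigen(H, symmetric = TRUE)
  ev <- rev(e$values)
  vec <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  n_zero <- sum(ev < zero_tol_factor * max(ev))
  if (n_comp > 1)
    warning("disconnected contact graph: ", n_comp,
            " components (expect ", 3 + 3 * n_comp,
            " or more zero modes)")
  structure(list(nodes = nodes, gamma = gamma, cutoff = cutoff,
                 hessian = H, eigenvalues = ev, eigenvectors = vec,
                 n_zero = n_zero, n_components = n_comp),
            class = "anm_model")
}

#' Displacement shapes of the softest nontrivial modes
#'
#' @param anm an `anm_model`.
#' @param k number of nontrivial modes (ordered by ascending nonzero
#'   eigenvalue); `k <= 3N - n_zero`.
#' @return array of dim (N, 3, k) of unit-normalized per-node displacement
#'   vectors, with the corresponding eigenvalues as attribute `eigenvalues`.
#' @export
mode_shapes <- function(anm, k) {
  n <- nrow(anm$nodes)
  avail <- 3 * n - anm$n_zero
  if (k < 1 || k > avail)
    stop("k must lie in [1, ", avail, "]")
  cols <- anm$n_zero + seq_len(k)
  shapes <- array(0, dim = c(n, 3, k))
  for (m in seq_len(k)) {
    v <- anm$eigenvectors[, cols[m]]
    v <- v / sqrt(sum(v^2))
    shapes[, , m] <- matrix(v, ncol = 3, byrow = TRUE)
  }
  attr(shapes, "eigenvalues") <- anm$eigenvalues[cols]
  shapes
}

#' Overlap of ANM modes with an antisymmetric ring counter-rotation
#'
#' For each nontrivial mode, the absolute cosine overlap with the normalized
#' rigid counter-rotation field: `+omega x r` on ring A nodes and
#' `-omega x r` on ring B nodes, with `omega` along the given axis and `r`
#' measured from each ring's own centroid.
#'
#' @param anm an `anm_model`.
#' @param ring_a_nodes,ring_b_nodes index sets partitioning the nodes.
#' @param axis rotation axis 3-vector.
#' @param k number of softest nontrivial modes to report (default 20).
#' @return data.frame with columns `mode`, `eigenvalue`, `overlap`.
#' @export
ring_rotation_overlap <- function(anm, ring_a_nodes, ring_b_nodes,
                                  axis = c(0, 0, 1), k = 20) {
  if (sum(axis^2) == 0) stop("axis must be nonzero")
  n <- nrow(anm$nodes)
  if (!setequal(c(ring_a_nodes, ring_b_nodes), seq_len(n)) ||
      length(intersect(ring_a_nodes, ring_b_nodes)) > 0)
    stop("ring node sets must partition the nodes")
  u <- axis / sqrt(sum(axis^2))
  field <- matrix(0, n, 3)
  for (set in list(list(ring_a_nodes, 1), list(ring_b_nodes, -1))) {
    ctr <- colMeans(anm$nodes[set[[1]], , drop = FALSE])
    for (i in set[[1]]) {
      r <- anm$nodes[i, ] - ctr
      field[i, ] <- set[[2]] * pracma_cross(u, r)
    }
  }
  f <- as.vector(t(field))
  f <- f / sqrt(sum(f^2))
  k <- min(k, 3 * n - anm$n_zero)
  cols <- anm$n_zero + seq_len(k)
  ov <- vapply(cols, function(cidx)
    abs(sum(anm$eigenvectors[, cidx] * f)), numeric(1))
  data.frame(mode = seq_len(k), eigenvalue = anm$eigenvalues[cols],
             overlap = ov)
}

#' Equivalent isotropic B factor from an anisotropic ADP tensor
#'
#' `B_eq = 8 pi^2 (U11 + U22 + U33) / 3`, with U in Angstrom^2 (the PDB
#' ANISOU integer convention is U * 1e4).
#'
#' @param u numeric 6-vector `(U11, U22, U33, U12, U13, U23)` or a matrix
#'   with those six columns (e.g. the `u11`..`u23` columns of a model's
#'   atom table).
#' @return numeric B_eq in Angstrom^2; values from a non-positive trace are
#'   returned with attribute `flagged` marking them.
#' @export
b_eq <- function(u) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  u <- as.matrix(u)
  if (ncol(u) != 6) stop("expected 6 ADP components")
  if (any(!is.finite(u))) stop("non-finite ADP tensor")
  tr <- rowSums(u[, 1:3, drop = FALSE])
  out <- 8 * pi^2 * tr / 3
  bad <- tr <= 0
  if (any(bad)) attr(out, "flagged") <- which(bad)
  if (length(out) == 1 && is.null(attr(out, "flagged"))) out <- as.numeric(out)
  out
}
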