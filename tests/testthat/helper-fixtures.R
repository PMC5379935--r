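# Shared fixtures and independent oracles for the test suite.

# quick structure_model from a coordinate matrix
mk_model <- function(xyz, name = "CA", elt = "C", chain = "A",
                     resn = "ALA", resi = NULL, het = FALSE) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  at <- ringstack:::empty_atoms(n)
  at$serial <- seq_len(n)
  at$name <- rep_len(name, n)
  at$elt <- rep_len(elt, n)
  at$alt <- ""; at$icode <- ""
  at$resn <- rep_len(resn, n)
  at$chain <- rep_len(chain, n)
  at$resi <- if (is.null(resi)) seq_len(n) else rep_len(resi, n)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at$occ <- 1; at$b <- 0
  at$het <- rep_len(het, n)
  structure_model(at)
}

rigid_transform <- function(model, axis = c(1, 2, 3), angle = 25,
                            shift = c(4, -7, 2)) {
  R <- rotation_about_axis(axis, angle)
  set_xyz_ <- ringstack:::set_xyz
  set_xyz_(model, sweep(xyz_matrix(model) %*% t(R), 2, shift, "+"))
}

# Horn's quaternion closed-form minimum RMSD (independent of the Kabsch path)
quaternion_rmsd <- function(xm, xr) {
  am <- sweep(xm, 2, colMeans(xm))
  ar <- sweep(xr, 2, colMeans(xr))
  S <- crossprod(am, ar)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  sqrt(max(0, (sum(am^2) + sum(ar^2) - 2 * lam) / nrow(xm)))
}

# brute-force agglomerative complete-linkage oracle: returns merge heights
# (ascending) and the partition at every k
brute_complete_linkage <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  partitions <- list()
  partitions[[length(clusters)]] <- clusters
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
    }
    heights <- c(heights, best$h)
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    partitions[[length(clusters)]] <- clusters
  }
  list(heights = heights, partitions = partitions, labels = labels)
}

partition_signature <- function(groups, labels) {
  sets <- vapply(groups, function(g)
    paste(sort(labels[g]), collapse = ","), character(1))
  paste(sort(sets), collapse = ";")
}

cutree_signature <- function(assign) {
  labels <- names(assign)
  sets <- vapply(split(labels, assign), function(g)
    paste(sort(g), collapse = ","), character(1))
  paste(sort(sets), collapse = ";")
}

# exposed area of sphere 1 (radius r1) partially occluded by sphere 2
# (radius r2) at centre distance d: analytic spherical-cap formula
two_sphere_exposed <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  x <- (d^2 + r1^2 - r2^2) / (2 * d)
  h <- r1 - x
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# a small two-record PDB text fixture with cell and one ANISOU
write_two_atom_pdb <- function(path) {
  writeLines(c(
    "CRYST1   63.460   66.060   66.100  60.05  83.94  77.17 P 1",
    "ATOM      1  CA  ALA A   1      11.104   6.134   2.100  1.00 10.00           C",
    "ANISOU    1  CA  ALA A   1      100    200    300     10    -20      0       C",
    "HETATM    2  O1  MPD A 101       8.000   1.500  -3.250  0.50 20.00           O",
    "END"), path)
  path
}

# a tiny polymer chain with N/CA/C/O per residue (for main-chain selections)
mk_backbone_chain <- function(n_res, chain = "A") {
  rows <- list()
  for (r in seq_len(n_res)) {
    base <- c(3.8 * r, 0, 0)
    rows[[r]] <- data.frame(
      name = c("N", "CA", "C", "O"),
      x = base[1] + c(0, 1.2, 2.2, 2.8),
      y = c(0.2, 0.8, 0.1, -1.0),
      z = c(0, 0.4, -0.3, 0.2),
      resi = r)
  }
  df <- do.call(rbind, rows)
  m <- mk_model(df[, c("x", "y", "z")], name = df$name, chain = chain,
                resi = df$resi)
  m$atoms$elt <- substr(df$name, 1, 1)
  m
}

# synthetic side-chain residue (LEU-like) with a controllable chi1
mk_chi_residue <- function(chi1, resi = 1, chain = "A") {
  pa <- ringstack:::place_atom
  n  <- c(0, 0, 0)
  ca <- c(1.46, 0, 0)
  cb <- ca + 1.53 * c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  cg <- pa(n, ca, cb, 1.53, 114, chi1)
  cd1 <- pa(ca, cb, cg, 1.53, 112, 175)
  xyz <- rbind(n, ca, cb, cg, cd1)
  mk_model(xyz, name = c("N", "CA", "CB", "CG", "CD1"),
           elt = c("N", "C", "C", "C", "C"), chain = chain,
           resn = "LEU", resi = resi)
}
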