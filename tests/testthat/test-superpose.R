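test_that("superposition recovers exact rigid transforms", {
  m <- chain_models(make_ring())[["A"]]
  sp <- superpose_pair(m, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  moved <- rigid_transform(m, axis = c(0, 0, 1), angle = 30,
                           shift = c(1, 2, 3))
  sp <- superpose_pair(moved, m)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(rotation_angle(sp$rotation), 30, tolerance = 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
})

test_that("reflections are excluded for chiral point sets", {
  xyz <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.2, 0, 0.3, 0.4, 1.7),
                4, 3, byrow = TRUE)
  mirror <- xyz %*% diag(c(1, 1, -1))
  sp <- superpose_pair(mk_model(xyz), mk_model(mirror))
  expect_gt(sp$rmsd, 0.1)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  # oracle: no proper rotation can better the quaternion closed-form optimum
  expect_equal(sp$rmsd, quaternion_rmsd(xyz, mirror), tolerance = 1e-8)
})

test_that("Kabsch RMSD equals the quaternion closed-form oracle", {
  set.seed(101)
  for (i in 1:10) {
    xm <- matrix(rnorm(30, sd = 3), 10, 3)
    xr <- matrix(rnorm(30, sd = 3), 10, 3)
    sp <- superpose_pair(mk_model(xm), mk_model(xr))
    expect_equal(sp$rmsd, quaternion_rmsd(xm, xr), tolerance = 1e-8)
  }
})

test_that("superposition matching validates atom correspondence", {
  too_few <- mk_model(matrix(rnorm(6), 2, 3))
  expect_error(superpose_pair(too_few, too_few), "at least 3")
  # multi-chain selections fall back to positional matching, which must
  # report the first name mismatch
  two_chain <- function(nm) {
    m1 <- mk_model(matrix(rnorm(12), 4, 3), name = nm, chain = "A",
                   resi = c(1, 1, 2, 2))
    m2 <- m1; m2$atoms$chain <- "B"
    structure_model(rbind(m1$atoms, m2$atoms))
  }
  a <- two_chain(c("N", "CA", "N", "CA"))
  b <- two_chain(c("N", "CB", "N", "CA"))
  expect_error(superpose_pair(a, b), "CA vs CB")
})

test_that("rmsd_matrix is symmetric, zero-diagonal and rigid-motion invariant", {
  cm <- chain_models(make_ring(noise_sigma = 0.15, seed = 3))
  expect_equal(max(rmsd_matrix(list(a = cm[[1]], b = cm[[1]]))$d), 0,
               tolerance = 1e-10)
  dm <- rmsd_matrix(cm)
  expect_equal(dm$d, t(dm$d))
  expect_equal(diag(dm$d), setNames(rep(0, 6), names(cm)))
  moved <- lapply(cm, rigid_transform)
  dm2 <- rmsd_matrix(moved)
  expect_equal(dm2$d, dm$d, tolerance = 1e-8)
})

test_that("mean reference converges with a non-increasing objective", {
  m <- chain_models(make_ring())[["A"]]
  solo <- mean_reference(list(m))
  expect_equal(xyz_matrix(solo), xyz_matrix(m))
  expect_equal(attr(solo, "iterations"), 1L)

  rot <- rigid_transform(m, angle = 40)
  mr <- mean_reference(list(m, rot))
  ra <- superpose_pair(m, mr)$rmsd
  rb <- superpose_pair(rot, mr)$rmsd
  expect_equal(ra, rb, tolerance = 1e-6)

  cm <- chain_models(make_stacked_rings(noise_sigma = 0.2, seed = 9))
  mr12 <- mean_reference(cm, tol = 1e-4)
  expect_true(attr(mr12, "converged"))
  expect_lte(attr(mr12, "iterations"), 5)
  obj <- attr(mr12, "objective")
  expect_true(all(diff(obj) <= 1e-9))
})

test_that("hierarchical clustering separates well-separated blocks", {
  d <- matrix(1, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  for (lk in c("complete", "ward")) {
    tr <- hierarchical_cluster(d, lk)
    expect_equal(cutree_signature(cut_tree(tr, 2)), "a,b;c,d")
  }
  # two leaves merge at exactly their distance
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- hierarchical_cluster(d2, "complete")
  expect_equal(tr2$height, 0.7)
  dn <- d; dn[1, 2] <- NA
  expect_error(hierarchical_cluster(dn), "NA")
})

test_that("complete linkage reproduces a brute-force agglomeration oracle", {
  set.seed(7)
  for (n in c(5, 6, 7)) {
    x <- matrix(rnorm(2 * n), n, 2)
    d <- as.matrix(stats::dist(x))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tr <- hierarchical_cluster(d, "complete")
    oracle <- brute_complete_linkage(d)
    expect_equal(tr$height, oracle$heights, tolerance = 1e-12)
    for (k in seq_len(n)) {
      expect_equal(cutree_signature(cut_tree(tr, k)),
                   partition_signature(oracle$partitions[[k]], oracle$labels))
    }
  }
})

test_that("clustering recovers the two ring conformations of a dodecamer", {
  # emulate two rings whose subunits differ more between rings than within
  tmpl_a <- subunit_template()
  tmpl_b <- tmpl_a
  tmpl_b$atoms$x <- tmpl_b$atoms$x + c(0.6, rep(0, 8), -0.6)
  tmpl_b$atoms$z <- tmpl_b$atoms$z + c(0, 0.5, rep(0, 8))
  ra <- make_ring(template = tmpl_a, noise_sigma = 0.05, seed = 21)
  rb <- make_ring(template = tmpl_b, noise_sigma = 0.05, seed = 22)
  rb$atoms$chain <- LETTERS[7:12][match(rb$atoms$chain, LETTERS[1:6])]
  subunits <- c(chain_models(ra), chain_models(rb))
  dm <- rmsd_matrix(subunits)
  for (lk in c("complete", "ward")) {
    cut <- cut_tree(hierarchical_cluster(dm, lk), 2)
    expect_equal(cutree_signature(cut), "A,B,C,D,E,F;G,H,I,J,K,L")
  }
})

test_that("cut_tree validates k and returns trivial cuts", {
  dm <- rmsd_matrix(chain_models(make_ring(noise_sigma = 0.1, seed = 2)))
  tr <- hierarchical_cluster(dm, "complete")
  expect_equal(unname(cut_tree(tr, 1)), rep(1L, 6))
  expect_equal(length(unique(cut_tree(tr, 6))), 6)
  expect_error(cut_tree(tr, 0), "k must")
  expect_error(cut_tree(tr, 7), "k must")
})

test_that("similarity edges weight close pairs and cap zero distances", {
  d <- matrix(1, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  dm <- structure(list(labels = letters[1:4], d = d),
                  class = "distance_matrix")
  ed <- similarity_edges(dm, levels = 3)
  within <- ed$weight[ed$level <= 2]
  between <- ed$weight[ed$level == 3]
  expect_true(all(within >= 10 * between))

  d2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  dm2 <- structure(list(labels = c("p", "q"), d = d2),
                   class = "distance_matrix")
  ed2 <- similarity_edges(dm2, levels = 1)
  expect_equal(ed2$weight, 2)
  d2[1, 2] <- d2[2, 1] <- 0
  dm2$d <- d2
  expect_equal(similarity_edges(dm2, levels = 1)$weight, 1e6)
})

test_that("chi comparison reports circular rotamer differences", {
  a <- mk_chi_residue(-60)
  same <- sidechain_chi_compare(a, a, residues = 1)
  expect_equal(same$dchi1, 0, tolerance = 1e-10)
  expect_equal(same$dchi2, 0, tolerance = 1e-10)
  b <- mk_chi_residue(60)  # chi1 rotated by 120 degrees
  cmp <- sidechain_chi_compare(b, a, residues = 1)
  expect_equal(cmp$dchi1, 120, tolerance = 1e-6)
  expect_true(cmp$complete)
  # missing atoms flag the residue rather than failing
  trunc <- a
  trunc$atoms <- trunc$atoms[trunc$atoms$name != "CG", ]
  flagged <- sidechain_chi_compare(trunc, a, residues = 1)
  expect_false(flagged$complete)
})
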