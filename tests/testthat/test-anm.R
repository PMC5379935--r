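test_that("the two-body network has the analytic spectrum {2 gamma}", {
  two <- mk_model(rbind(c(0, 0, 0), c(5, 0, 0)))
  anm <- build_anm(two, gamma = 1, cutoff = 15)
  expect_equal(anm$n_zero, 5)
  expect_equal(anm$eigenvalues[6], 2, tolerance = 1e-10)
  # softest nontrivial mode: anti-phase displacement along the bond
  sh <- mode_shapes(anm, 1)[, , 1]
  expect_equal(abs(sh[1, 1]), abs(sh[2, 1]), tolerance = 1e-8)
  expect_equal(sign(sh[1, 1]) * sign(sh[2, 1]), -1)
  expect_lt(max(abs(sh[, 2:3])), 1e-8)
})

test_that("connected networks have exactly six rigid-body zero modes", {
  ring <- make_ring()
  anm <- build_anm(ring, 1, 15)
  expect_equal(anm$n_components, 1)
  expect_equal(anm$n_zero, 6)

  dodeca <- make_stacked_rings()
  anm12 <- build_anm(dodeca, 1, 15)
  expect_equal(anm12$n_zero, 6)
  n <- nrow(anm12$nodes)
  # all 3N - 6 nontrivial modes are available
  sh <- mode_shapes(anm12, 3 * n - 6)
  expect_equal(dim(sh), c(n, 3, 3 * n - 6))
  expect_error(mode_shapes(anm12, 3 * n - 5), "k must")
})

test_that("disconnected graphs warn with the component count", {
  sparse <- mk_model(rbind(c(0, 0, 0), c(2, 0, 0), c(100, 0, 0),
                           c(102, 0, 0)))
  expect_warning(anm <- build_anm(sparse, 1, 15), "2 components")
  expect_gt(anm$n_zero, 6)
})

test_that("modes are unit-normalized and mutually orthogonal", {
  anm <- build_anm(make_ring(), 1, 15)
  sh <- mode_shapes(anm, 5)
  flat <- apply(sh, 3, as.vector)
  g <- crossprod(flat)
  expect_equal(g, diag(5), tolerance = 1e-8)
})

test_that("the Hessian obeys translation invariance and gamma scaling", {
  m <- make_ring(noise_sigma = 0.1, seed = 6)
  anm <- build_anm(m, 1, 15)
  n <- nrow(anm$nodes)
  # blockwise row sums vanish (uniform translation is a null vector)
  for (axis in 1:3) {
    t_vec <- rep(0, 3 * n)
    t_vec[seq(axis, 3 * n, by = 3)] <- 1
    expect_lt(max(abs(anm$hessian %*% t_vec)), 1e-10)
  }
  anm2 <- build_anm(m, 2, 15)
  expect_equal(anm2$eigenvalues, 2 * anm$eigenvalues, tolerance = 1e-10)
  # eigenvalues invariant under rigid rotation of the input
  anm_rot <- build_anm(rigid_transform(m), 1, 15)
  nz <- anm$eigenvalues[anm$eigenvalues > 1e-8]
  nz_rot <- anm_rot$eigenvalues[anm_rot$eigenvalues > 1e-8]
  expect_equal(nz_rot, nz, tolerance = 1e-8)
})

test_that("ANM eigenvalues agree with an independent elastic-network code", {
  # cross-check against bio3d's ANM force field on the same CA set
  ring <- make_ring()
  anm <- build_anm(ring, 1, 15)
  xyz <- as.vector(t(anm$nodes))
  H_ref <- bio3d::build.hessian(xyz, bio3d::load.enmff("anm"), cutoff = 15)
  ev_ref <- sort(eigen(H_ref, symmetric = TRUE)$values)
  expect_equal(anm$eigenvalues, ev_ref, tolerance = 1e-8)
})

test_that("counter-rotation overlap separates rotation from translation fields", {
  st <- make_stacked_rings()
  anm <- build_anm(st, 1, 15)
  ia <- which(st$atoms$chain %in% LETTERS[1:6])
  ib <- which(st$atoms$chain %in% LETTERS[7:12])
  ov <- ring_rotation_overlap(anm, ia, ib, axis = c(0, 0, 1), k = 20)
  expect_equal(nrow(ov), 20)
  expect_true(all(ov$overlap >= 0 & ov$overlap <= 1 + 1e-12))
  # a pure translation is orthogonal to every reported (nontrivial) mode
  n <- nrow(anm$nodes)
  t_vec <- rep(c(0, 0, 1), n) / sqrt(n)
  for (mode in 1:5)
    expect_lt(abs(sum(anm$eigenvectors[, anm$n_zero + mode] * t_vec)), 1e-8)
  expect_error(ring_rotation_overlap(anm, ia, ib, axis = c(0, 0, 0)), "axis")
  expect_error(ring_rotation_overlap(anm, ia[-1], ib, axis = c(0, 0, 1)),
               "partition")
})

test_that("an exact counter-rotation field has overlap one with itself", {
  st <- make_stacked_rings()
  anm <- build_anm(st, 1, 15)
  ia <- which(st$atoms$chain %in% LETTERS[1:6])
  ib <- which(st$atoms$chain %in% LETTERS[7:12])
  # plant the field as a fake mode and confirm the overlap statistic is 1
  u <- c(0, 0, 1)
  field <- matrix(0, nrow(anm$nodes), 3)
  for (set in list(list(ia, 1), list(ib, -1))) {
    ctr <- colMeans(anm$nodes[set[[1]], , drop = FALSE])
    for (i in set[[1]]) {
      r <- anm$nodes[i, ] - ctr
      field[i, ] <- set[[2]] * c(u[2] * r[3] - u[3] * r[2],
                                 u[3] * r[1] - u[1] * r[3],
                                 u[1] * r[2] - u[2] * r[1])
    }
  }
  f <- as.vector(t(field)); f <- f / sqrt(sum(f^2))
  fake <- anm
  fake$eigenvectors[, fake$n_zero + 1] <- f
  ov <- ring_rotation_overlap(fake, ia, ib, axis = u, k = 1)
  expect_equal(ov$overlap, 1, tolerance = 1e-10)
})

test_that("B_eq follows the 8 pi^2 tr(U)/3 definition", {
  expect_equal(b_eq(c(0.01, 0.01, 0.01, 0, 0, 0)), 8 * pi^2 * 0.01,
               tolerance = 1e-12)
  B <- 25
  u_iso <- rep(B / (8 * pi^2), 3)
  expect_equal(b_eq(c(u_iso, 0, 0, 0)), B, tolerance = 1e-12)
  # ANISOU integer 10000 on the diagonals is U = 1.0, so B_eq = 8 pi^2
  expect_equal(b_eq(c(1, 1, 1, 0, 0, 0)), 8 * pi^2, tolerance = 1e-12)
  out <- b_eq(rbind(c(0.01, 0.01, 0.01, 0, 0, 0),
                    c(-0.01, -0.01, -0.01, 0, 0, 0)))
  expect_equal(attr(out, "flagged"), 2L)
})
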