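test_that("torsions follow the IUPAC sign convention", {
  p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(2, 0, 0)
  expect_equal(dihedral(p1, p2, p3, c(2, 1, 0)), 0, tolerance = 1e-10)
  expect_equal(abs(dihedral(p1, p2, p3, c(2, -1, 0))), 180, tolerance = 1e-10)
  set.seed(12)
  for (i in 1:5) {
    q <- matrix(rnorm(12), 4, 3)
    ang <- dihedral(q[1, ], q[2, ], q[3, ], q[4, ])
    mir <- q %*% diag(c(1, 1, -1))
    expect_equal(dihedral(mir[1, ], mir[2, ], mir[3, ], mir[4, ]), -ang,
                 tolerance = 1e-10)
    expect_true(ang > -180 && ang <= 180)
  }
  expect_error(dihedral(p1, p1, p3, c(2, 1, 0)), "degenerate")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "degenerate")
})

test_that("glycosidic chi reproduces requested values with syn/anti labels", {
  for (chi in c(-165.2, -116.8, -90, 45, 170)) {
    res <- glycosidic_chi(make_sugar_ring(17.5, 38, chi))
    expect_lt(abs(ang_diff(res$chi, chi)), 0.5)
    expect_equal(res$conformer, if (abs(chi) >= 90) "anti" else "syn")
  }
  broken <- make_sugar_ring(17.5, 38, -160)
  broken$atoms <- broken$atoms[broken$atoms$name != "C2", ]
  expect_error(glycosidic_chi(broken), "C2")
})

test_that("pseudorotation analysis is self-consistent across the wheel", {
  for (P in seq(0, 324, by = 36)) {
    pk <- pseudorotation(make_sugar_ring(P, 38, -160))
    expect_lt(abs(ang_diff(pk$P, P)), 2)
  }
  # reference pucker states of A-form and B-form-like sugars
  north <- pseudorotation(make_sugar_ring(17.5, 38, -165.2))
  expect_equal(north$pucker_class, "C3'-endo")
  expect_equal(north$hemisphere, "North")
  south <- pseudorotation(make_sugar_ring(163.2, 38, -116.8))
  expect_equal(south$pucker_class, "C2'-endo")
  expect_equal(south$hemisphere, "South")
  east <- pseudorotation(make_sugar_ring(90, 38, -160))
  expect_equal(east$pucker_class, "O4'-endo")
})

test_that("near-planar rings are flagged amplitude-undefined", {
  th <- 2 * pi * (0:4) / 5
  flat <- mk_model(cbind(1.2 * cos(th), 1.2 * sin(th), 0),
                   name = c("O4'", "C1'", "C2'", "C3'", "C4'"),
                   elt = c("O", "C", "C", "C", "C"), resn = "U", resi = 1)
  pk <- pseudorotation(flat)
  expect_true(pk$amplitude_undefined)
  expect_true(is.na(pk$pucker_class))
})

test_that("missing furanose atoms are reported by name", {
  s <- make_sugar_ring(18, 38, -160)
  s$atoms <- s$atoms[s$atoms$name != "C3'", ]
  expect_error(pseudorotation(s), "C3'")
})

test_that("contact tables classify hydrogen-bond candidates and sort by distance", {
  xyz <- rbind(c(0, 0, 0), c(3.0, 0, 0), c(0, 3.4, 0))
  m <- mk_model(xyz, name = c("N", "O", "C"), elt = c("N", "O", "C"),
                resi = c(1, 2, 2))
  tab <- contact_table(m, atom_selection(resi_range = c(1, 1)),
                       atom_selection(resi_range = c(2, 2)), cutoff = 3.6)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$class, c("hbond-candidate", "vdw"))
  expect_equal(tab$distance, c(3.0, 3.4), tolerance = 1e-9)

  # symmetric in group order: same pairs, roles swapped
  rev_tab <- contact_table(m, atom_selection(resi_range = c(2, 2)),
                           atom_selection(resi_range = c(1, 1)),
                           cutoff = 3.6)
  expect_equal(rev_tab$distance, tab$distance)
  expect_equal(rev_tab$atom_a, tab$atom_b)

  far <- mk_model(rbind(c(0, 0, 0), c(50, 0, 0)), name = c("N", "O"),
                  elt = c("N", "O"), resi = c(1, 2))
  expect_equal(nrow(contact_table(far, atom_selection(resi_range = c(1, 1)),
                                  atom_selection(resi_range = c(2, 2)))), 0)
  expect_error(contact_table(m, atom_selection(resi_range = c(1, 2)),
                             atom_selection(resi_range = c(2, 2))),
               "disjoint")
  expect_warning(contact_table(m, atom_selection(chains = "Z"),
                               atom_selection(resi_range = c(2, 2))),
                 "empty")
})

test_that("stacking geometry discriminates parallel, offset and crossed rings", {
  th <- 2 * pi * (0:5) / 6
  hexagon <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
  above <- sweep(hexagon, 2, c(0, 0, 3.5), "+")
  expect_true(stacking_check(hexagon, above)$is_stacked)

  crossed <- sweep(hexagon %*% t(rotation_about_axis(c(1, 0, 0), 90)),
                   2, c(0, 0, 3.5), "+")
  expect_false(stacking_check(hexagon, crossed)$is_stacked)

  slid <- sweep(hexagon, 2, c(4, 0, 3.5), "+")
  res <- stacking_check(hexagon, slid)
  expect_false(res$is_stacked)
  expect_equal(res$offset, 4, tolerance = 1e-9)

  # the generated uridine base stacks on its own translate
  base <- make_sugar_ring(17.5, 38, -160)
  ring_atoms <- c("N1", "C2", "N3", "C4", "C5", "C6")
  b <- xyz_matrix(select_atoms(base, names = ring_atoms))
  pl <- best_fit_plane(b)
  b2 <- sweep(b, 2, 3.4 * pl$normal, "+")
  expect_true(stacking_check(b, b2)$is_stacked)
})
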