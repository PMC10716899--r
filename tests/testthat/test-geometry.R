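cell10 <- unit_cell(c(10, 10, 10))

test_that("minimum image maps displacements into the nearest period", {
  expect_equal(minimum_image(c(6, 0, 0), cell10)[1L], -4)
  expect_equal(minimum_image(c(-7, 0, 0), cell10)[1L], 3)
  # round-half-to-even tie rule keeps exactly L/2 in place
  expect_equal(minimum_image(c(5, 0, 0), cell10)[1L], 5)
  # non-periodic axes pass through
  free <- unit_cell()
  expect_equal(minimum_image(c(123, -4, 9), free), c(123, -4, 9))
  set.seed(5)
  for (k in 1:25) {
    a <- runif(3, 0, 10); b <- runif(3, 0, 10)
    d <- minimum_image(b - a, cell10)
    expect_equal(sqrt(sum(d^2)),
                 oracle_min_image_distance(a, b, rep(10, 3)),
                 tolerance = 1e-12)
  }
})

test_that("center of mass is the mass-weighted mean", {
  fr <- md_frame(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 4, 0)))
  expect_equal(center_of_mass(fr, 0:1), c(1, 0, 0))
  expect_equal(center_of_mass(fr, c(0L, 2L), masses = c(1, 99, 3))[2L], 3)
  expect_error(center_of_mass(fr, integer(0)), "empty")
})

test_that("deperiodization makes split structures whole and is idempotent", {
  # water with O near one face and H wrapped to the other
  top <- topology(atom_labels = c("OW", "HW1", "HW2"),
                  elements = c("O", "H", "H"),
                  residue_ids = rep(1L, 3), residue_names = rep("SOL", 3),
                  chain_ids = rep("A", 3),
                  bonds = rbind(c(0L, 1L), c(0L, 2L)))
  fr <- md_frame(rbind(c(9.9, 5, 5), c(0.05, 5, 5), c(9.6, 5.9, 5)), cell10)
  out <- deperiodize_frame(fr, top)
  d01 <- sqrt(sum((out$coordinates[1, ] - out$coordinates[2, ])^2))
  expect_lt(d01, 1.2)                      # contiguous without wrapping
  expect_gt(out$coordinates[2, 1], out$coordinates[1, 1])
  again <- deperiodize_frame(out, top)
  expect_equal(again$coordinates, out$coordinates, tolerance = 1e-12)

  # an already-whole molecule is untouched
  fr2 <- md_frame(rbind(c(5, 5, 5), c(5.9, 5, 5), c(4.7, 5.6, 5)), cell10)
  expect_equal(deperiodize_frame(fr2, top)$coordinates, fr2$coordinates,
               tolerance = 1e-12)

  # split-molecule fixture: COM lands inside the primary cell
  sm <- make_split_molecule(seed = 3)
  dep <- deperiodize_frame(sm$frames[[1L]], sm$topology)
  com <- center_of_mass(dep, 0:(n_atoms(sm$topology) - 1L),
                        sm$topology$masses)
  expect_true(all(com >= 0 & com <= 10))
  b <- sm$topology$bonds
  dd <- sqrt(rowSums((dep$coordinates[b[, 1L] + 1L, ] -
                      dep$coordinates[b[, 2L] + 1L, ])^2))
  expect_true(all(dd < 2))
})

test_that("recentering puts the set COM at the cell center and preserves geometry", {
  wb <- make_water_box(n_waters = 12, box = 12, n_frames = 3, seed = 9)
  set0 <- 0:2                               # first water
  rec <- recenter_trajectory(wb, set0)
  for (f in seq_len(n_frames(rec))) {
    com <- center_of_mass(rec$frames[[f]], set0, rec$topology$masses)
    expect_equal(com, c(6, 6, 6), tolerance = 1e-9)
  }
  rec2 <- recenter_trajectory(rec, set0)
  for (f in seq_len(n_frames(rec))) {
    expect_equal(rec2$frames[[f]]$coordinates, rec$frames[[f]]$coordinates,
                 tolerance = 1e-9)
  }
  # intra-structure minimum-image pairwise distances are preserved
  cs <- connected_structures(wb$topology)
  for (ctx in cs$contexts[1:4]) {
    pre <- wb$frames[[1L]]
    post <- rec$frames[[1L]]
    for (i in seq_along(ctx)) for (j in seq_len(i - 1L)) {
      d0 <- minimum_image(pre$coordinates[ctx[i] + 1L, ] -
                          pre$coordinates[ctx[j] + 1L, ], pre$cell)
      d1 <- minimum_image(post$coordinates[ctx[i] + 1L, ] -
                          post$coordinates[ctx[j] + 1L, ], post$cell)
      expect_equal(sqrt(sum(d0^2)), sqrt(sum(d1^2)), tolerance = 1e-9)
    }
  }
})

test_that("internal coordinates follow the stated conventions", {
  expect_equal(calc_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(calc_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(calc_angle(c(1, 0, 0), c(0, 0, 0), c(-2, 0, 0)), 180)
  # trans-planar = 180, cis = 0
  expect_equal(calc_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  expect_equal(calc_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  # sign convention: reversing the atom order preserves the torsion angle,
  # mirror reflection flips its sign
  set.seed(3)
  for (k in 1:10) {
    p <- matrix(rnorm(12), 4L)
    expect_equal(calc_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 calc_dihedral(p[4, ], p[3, ], p[2, ], p[1, ]),
                 tolerance = 1e-9)
    m <- p %*% diag(c(1, 1, -1))
    expect_equal(calc_dihedral(m[1, ], m[2, ], m[3, ], m[4, ]),
                 -calc_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  expect_error(calc_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("Kabsch superposition recovers rigid motions and minimizes RMSD", {
  set.seed(8)
  pts <- matrix(rnorm(300), 100L)
  fit0 <- kabsch_superpose(pts, pts)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))   # 90 degrees about z
  moved <- pts %*% t(Rz) + matrix(c(3, -2, 7), 100L, 3L, byrow = TRUE)
  fit <- kabsch_superpose(pts, moved)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$transform(pts), moved, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # noisy copy: minimized RMSD concentrates near sigma * sqrt(3)
  sigma <- 0.1
  noisy <- pts + matrix(rnorm(300, sd = sigma), 100L)
  fitn <- kabsch_superpose(pts, noisy)
  expect_lt(abs(fitn$rmsd - sigma * sqrt(3)), 3 * sigma / sqrt(100))

  # superposed RMSD never exceeds the unsuperposed one
  for (k in 1:5) {
    a <- matrix(rnorm(60), 20L)
    b <- matrix(rnorm(60), 20L)
    raw <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(kabsch_superpose(a, b)$rmsd, raw + 1e-12)
  }
  expect_error(kabsch_superpose(pts[1:5, ], pts[1:6, ]), "mismatch")
})

test_that("shape weights hit the anisotropy triangle corners and are invariant", {
  rod <- md_frame(cbind(seq(0, 9), 0, 0))
  sw <- shape_weights(rod, 0:9)
  expect_equal(c(sw$c_lin, sw$c_plan, sw$c_iso), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(sw$point2d, c(0, 0), tolerance = 1e-9)

  th <- seq(0, 2 * pi, length.out = 201)[-201]
  disc <- md_frame(cbind(cos(th), sin(th), 0))
  sd_ <- shape_weights(disc, 0:199)
  expect_equal(c(sd_$c_lin, sd_$c_plan, sd_$c_iso), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(sd_$point2d, c(1, 0), tolerance = 1e-9)

  sphere <- md_frame(rbind(diag(3), -diag(3)))
  ss <- shape_weights(sphere, 0:5)
  expect_equal(c(ss$c_lin, ss$c_plan, ss$c_iso), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(ss$point2d, c(0.5, 1), tolerance = 1e-9)

  # weights sum to one and are rigid-motion invariant on random clouds
  set.seed(21)
  for (k in 1:8) {
    cloud <- matrix(rnorm(3 * 30), 30L) %*% diag(runif(3, 0.2, 3))
    w1 <- shape_weights(md_frame(cloud), 0:29)
    expect_equal(w1$c_lin + w1$c_plan + w1$c_iso, 1, tolerance = 1e-9)
    M <- qr.Q(qr(matrix(rnorm(9), 3L)))
    if (det(M) < 0) M[, 1L] <- -M[, 1L]
    moved <- cloud %*% t(M) + matrix(rnorm(3), 30L, 3L, byrow = TRUE)
    w2 <- shape_weights(md_frame(moved), 0:29)
    expect_equal(c(w1$c_lin, w1$c_plan, w1$c_iso),
                 c(w2$c_lin, w2$c_plan, w2$c_iso), tolerance = 1e-8)
  }
  expect_error(shape_weights(md_frame(rbind(c(1, 1, 1), c(1, 1, 1))), 0:1),
               "coincident")
})

test_that("covalent growth equals the BFS oracle", {
  sm <- make_split_molecule(n_atoms = 9L, seed = 2)
  top <- sm$topology
  sel <- context_selection(list(4L))
  expect_equal(grow_covalent(sel, top, 0)$contexts[[1L]], 4L)
  expect_equal(grow_covalent(sel, top, 1)$contexts[[1L]], 3:5)
  # steps >= diameter reach the whole component
  expect_equal(grow_covalent(sel, top, 50)$contexts[[1L]], 0:8)
  set.seed(31)
  for (k in 1:6) {
    steps <- sample(0:5, 1L)
    start <- sample(0:8, sample(1:3, 1L))
    got <- grow_covalent(context_selection(list(start)), top, steps)
    expect_equal(got$contexts[[1L]],
                 oracle_grow_covalent(start, top$bonds, steps))
  }
})

test_that("radial growth equals the all-pairs oracle, including across PBC", {
  wb <- make_water_box(n_waters = 20, box = 12, n_frames = 1, seed = 13)
  fr <- wb$frames[[1L]]
  sel0 <- c(0L, 7L)
  for (radius in c(0, 2.5, 5)) {
    got <- grow_radial(context_selection(list(sel0)), fr, radius)
    expect_equal(got$contexts[[1L]],
                 oracle_grow_radial(sel0, fr$coordinates, rep(12, 3), radius))
  }
  # radius covering the box diagonal returns every atom
  all_got <- grow_radial(context_selection(list(0L)), fr, 25)
  expect_equal(all_got$contexts[[1L]], 0:(n_atoms(wb$topology) - 1L))

  # atom just across the boundary is captured
  top <- topology(atom_labels = c("C", "C"), elements = c("C", "C"),
                  residue_ids = 1:2, residue_names = rep("UNK", 2),
                  chain_ids = rep("A", 2))
  fr2 <- md_frame(rbind(c(0.2, 5, 5), c(9.6, 5, 5)), cell10)
  got2 <- grow_radial(context_selection(list(0L)), fr2, 1)
  expect_equal(got2$contexts[[1L]], 0:1)
})
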