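mk_protein_top <- function(resnames, chains = rep("A", length(resnames))) {
  # three backbone atoms per residue suffice for classification tests
  n <- length(resnames)
  topology(atom_labels = rep(c("N", "CA", "C"), n),
           elements = rep(c("N", "C", "C"), n),
           residue_ids = rep(seq_len(n), each = 3L),
           residue_names = rep(resnames, each = 3L),
           chain_ids = rep(chains, each = 3L))
}

test_that("residue classification partitions the four classes", {
  top <- mk_protein_top(c("ALA", "PRO", "GLY", "PRO", "ALA", "GLY", "SER"))
  cls <- classify_residues(top)
  expect_equal(cls$class,
               c("preproline", "proline", "glycine", "proline", "general",
                 "glycine", "general"))
  # GLY before PRO keeps its own identity
  expect_equal(cls$class[3L], "glycine")
  # partition: every protein residue classified exactly once
  expect_equal(nrow(cls), 7L)
  expect_true(all(cls$class %in% c("general", "glycine", "proline",
                                   "preproline")))
  # pre-proline requires same-chain adjacency
  top2 <- mk_protein_top(c("ALA", "PRO"), chains = c("A", "B"))
  expect_equal(classify_residues(top2)$class, c("general", "proline"))
  # non-protein residues are not classified
  top3 <- topology(atom_labels = c("OW"), elements = "O", residue_ids = 1L,
                   residue_names = "SOL", chain_ids = "A")
  expect_equal(nrow(classify_residues(top3)), 0L)
})

test_that("backbone dihedrals round-trip the constructed geometry", {
  traj <- make_alanine_chain(n_res = 15, n_frames = 1, seed = 1,
                             phi = -57, psi = -47, amplitude = 0)
  bb <- backbone_dihedrals(traj, 1L)
  # two termini are omitted
  expect_equal(nrow(bb), 13L)
  expect_equal(bb$phi, rep(-57, 13L), tolerance = 1e-6)
  expect_equal(bb$psi, rep(-47, 13L), tolerance = 1e-6)
  expect_true(all(bb$class == "general"))

  # other target dihedrals round-trip too (beta-sheet-like region)
  traj2 <- make_alanine_chain(n_res = 6, n_frames = 1, seed = 1,
                              phi = -120, psi = 130, amplitude = 0)
  bb2 <- backbone_dihedrals(traj2, 1L)
  expect_equal(bb2$phi, rep(-120, 4L), tolerance = 1e-6)
  expect_equal(bb2$psi, rep(130, 4L), tolerance = 1e-6)

  # a residue with a missing backbone atom is skipped with a warning
  broken <- traj$topology
  keep <- !(residue_index(broken) == 5L & broken$atom_labels == "CA")
  top_b <- topology(atom_labels = broken$atom_labels[keep],
                    elements = broken$elements[keep],
                    residue_ids = broken$residue_ids[keep],
                    residue_names = broken$residue_names[keep],
                    chain_ids = broken$chain_ids[keep])
  traj_b <- trajectory(top_b, list(md_frame(
    traj$frames[[1L]]$coordinates[keep, , drop = FALSE])))
  expect_warning(bb_b <- backbone_dihedrals(traj_b, 1L), "skipped")
  expect_lt(nrow(bb_b), 13L)
})

test_that("smoothed density is periodic, normalized, and separable-exact", {
  d1 <- rama_density(10, -30, grid_size = 64L, sigma = 8)
  expect_equal(sum(d1$grid), 1, tolerance = 1e-12)
  expect_true(all(d1$grid >= 0))

  # a point at phi = 179 wraps onto the phi = -180 side
  dw <- rama_density(179, 0, grid_size = 90L, sigma = 6)
  left_col_mass <- sum(dw$grid[1L, ])     # cells starting at -180
  expect_gt(left_col_mass, 0.01)

  # separable implementation equals the direct 2D convolution oracle
  set.seed(12)
  phi <- runif(40, -180, 180); psi <- runif(40, -180, 180)
  d32 <- rama_density(phi, psi, grid_size = 32L, sigma = 15)
  h_raw <- matrix(0, 32L, 32L)
  w <- 360 / 32
  ip <- (floor((phi + 180) / w) %% 32) + 1L
  is_ <- (floor((psi + 180) / w) %% 32) + 1L
  for (k in seq_along(ip)) h_raw[ip[k], is_[k]] <- h_raw[ip[k], is_[k]] + 1
  expect_equal(d32$grid, oracle_smooth_2d(h_raw, 15), tolerance = 1e-10)

  # mass 1 regardless of sigma/grid; 180-degree rotation symmetry
  for (sg in c(2, 6, 20)) {
    dd <- rama_density(c(-10, 40), c(5, -170), grid_size = 60L, sigma = sg)
    expect_equal(sum(dd$grid), 1, tolerance = 1e-12)
  }
  n <- 40L
  pts <- cbind(runif(10, -180, 180), runif(10, -180, 180))
  da <- rama_density(pts[, 1L], pts[, 2L], n, 10)
  rot <- function(a) ifelse(a + 180 >= 180, a - 180, a + 180)
  db <- rama_density(rot(pts[, 1L]), rot(pts[, 2L]), n, 10)
  shift <- function(m) m[c((n / 2 + 1):n, 1:(n / 2)), c((n / 2 + 1):n, 1:(n / 2))]
  expect_equal(db$grid, shift(da$grid), tolerance = 1e-12)

  expect_error(rama_density(numeric(0), numeric(0)), "non-empty")
  expect_error(rama_density(1, 1, grid_size = 4L), ">= 8")
})

test_that("contour levels enclose the requested percentile mass", {
  # near-uniform density: the threshold encloses p% of mass to one cell
  set.seed(1)
  u <- matrix(1 + runif(400, -1e-6, 1e-6), 20L, 20L)
  u <- u / sum(u)
  t98 <- rama_contour_levels(u, 98)
  expect_equal(rama_enclosed_mass(u, t98), 0.98, tolerance = 1 / 400 + 1e-9)

  # delta-like density: the single peak cell is selected at p = 50
  d <- matrix(1e-9, 20L, 20L)
  d[7L, 3L] <- 1
  d <- d / sum(d)
  t50 <- rama_contour_levels(d, 50)
  expect_equal(sum(d >= t50), 1L)

  # monotonicity: stricter percentile has the lower threshold
  set.seed(3)
  g <- rama_density(rnorm(500, -60, 30), rnorm(500, -45, 30), 90L, 6)
  lv <- rama_contour_levels(g, c(99.95, 98))
  expect_lte(lv[["99.95"]], lv[["98"]])
  expect_error(rama_contour_levels(g, 0), "percentiles")
  expect_error(rama_contour_levels(g, 101), "percentiles")

  # class defaults
  expect_equal(rama_default_percentiles("general"), c(99.95, 98))
  for (cl in c("glycine", "proline", "preproline")) {
    expect_equal(rama_default_percentiles(cl), c(99.5, 98))
  }
})

test_that("layered densities share reference percentiles and round-trip csv", {
  set.seed(8)
  full <- rama_density(rnorm(800, -60, 25), rnorm(800, -45, 25), 60L, 6)
  filt <- rama_density(rnorm(200, -60, 25), rnorm(200, -45, 25), 60L, 6)
  layers <- rama_compare_layers(full, filt)
  expect_named(layers, c("full", "filtered"))
  expect_equal(sum(layers$filtered$density$grid), 1, tolerance = 1e-12)
  same <- rama_compare_layers(full, full)
  expect_identical(same$full$levels, same$filtered$levels)

  path <- tempfile(fileext = ".csv")
  write_rama_density(full, path)
  back <- read_rama_density(path)
  expect_equal(back$grid, full$grid, tolerance = 1e-12)
  expect_equal(back$sigma, 6)
  withref <- rama_compare_layers(full, filt, reference = back)
  expect_length(withref, 3L)
  expect_error(rama_compare_layers(full, rama_density(1, 1, 32L, 6)),
               "grid sizes")
})
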