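write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

test_that("PDB topologies carry elements, cell, and CONECT bonds", {
  traj <- make_alanine_chain(n_res = 3, n_frames = 2, seed = 4)
  path <- tempfile(fileext = ".pdb")
  write_trajectory(traj, path)
  top <- read_topology(path)
  expect_equal(n_atoms(top), n_atoms(traj$topology))
  expect_equal(top$elements, traj$topology$elements)
  expect_equal(top$residue_names, traj$topology$residue_names)
  expect_equal(top$bonds, traj$topology$bonds)

  back <- read_trajectory(top, path)
  expect_equal(n_frames(back), 2L)
  expect_equal(back$frames[[2L]]$coordinates,
               traj$frames[[2L]]$coordinates, tolerance = 1e-3)
})

test_that("malformed and truncated records fail with line numbers", {
  p <- write_tmp(c("ATOM      1  N   ALA A   1      0.000"), "pdb")
  expect_error(read_topology(p), "line 1.*truncated")
  p2 <- write_tmp(c("REMARK nothing"), "pdb")
  expect_error(read_topology(p2), "zero atoms")
  p3 <- write_tmp(character(0), "pdb")
  expect_error(read_topology(p3), "empty file")
  expect_error(read_topology(tempfile(fileext = ".pdb")), "not found")
  # frame with a missing atom names the frame
  traj <- make_alanine_chain(n_res = 2, n_frames = 2, seed = 1)
  path <- tempfile(fileext = ".pdb")
  write_trajectory(traj, path)
  lines <- readLines(path)
  atom2 <- which(startsWith(lines, "ATOM"))
  drop <- atom2[atom2 > which(startsWith(lines, "MODEL"))[2L]][1L]
  writeLines(lines[-drop], path)
  expect_error(read_trajectory(traj$topology, path), "frame 2: expected")
  # triclinic cells are rejected explicitly
  p4 <- write_tmp(c("CRYST1   10.000   10.000   10.000  90.00  90.00 120.00 P 1",
                    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f",
                            1, "C1", "UNK", "A", 1, 1, 1, 1)), "pdb")
  expect_error(read_topology(p4), "triclinic")
})

test_that("GRO files read without elements and convert nm to Angstrom", {
  traj <- make_water_box(n_waters = 5, box = 12, n_frames = 3, seed = 2)
  path <- tempfile(fileext = ".gro")
  write_trajectory(traj, path)
  top <- read_topology(path)
  expect_true(all(is.na(top$elements)))
  expect_equal(top$atom_labels, traj$topology$atom_labels)
  back <- read_trajectory(top, path)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$frames[[1L]]$cell$lengths, rep(12, 3), tolerance = 1e-6)
  expect_equal(back$frames[[2L]]$coordinates,
               traj$frames[[2L]]$coordinates, tolerance = 5e-2)
  p2 <- write_tmp(c("title", "2",
                    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "SOL", "OW", 1, 0.1, 0.1, 0.1),
                    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "SOL", "HW1", 2, 0.2, 0.1, 0.1),
                    "   2.0   2.0   2.0   0.0   0.0   0.0   0.5   0.0   0.0"), "gro")
  expect_error(read_topology(p2), NA)
  expect_error(read_trajectory(read_topology(p2), p2), "triclinic")
})

test_that("multi-frame XYZ reads and counts frames", {
  traj <- make_alanine_chain(n_res = 4, n_frames = 5, seed = 3)
  path <- tempfile(fileext = ".xyz")
  write_trajectory(traj, path)
  back <- read_trajectory(traj$topology, path)
  expect_equal(n_frames(back), 5L)
  expect_equal(back$frames[[3L]]$coordinates,
               traj$frames[[3L]]$coordinates, tolerance = 1e-5)
  bad <- write_tmp(c("3", "comment", "C 0 0 0", "C 1 0 0"), "xyz")
  expect_error(read_trajectory(traj$topology, bad), "truncated")
})

test_that("element inference follows the documented label heuristics", {
  mk <- function(labels, resnames) {
    topology(atom_labels = labels, elements = rep(NA_character_, length(labels)),
             residue_ids = rep(1L, length(labels)),
             residue_names = resnames, chain_ids = rep("A", length(labels)))
  }
  top <- infer_elements(mk(c("OW", "HW1", "1H2", "CA", "CL", "CA"),
                           c("SOL", "SOL", "SOL", "ALA", "ION", "ION")))
  expect_equal(top$elements, c("O", "H", "H", "C", "Cl", "Ca"))
  # idempotent and total
  top2 <- infer_elements(top)
  expect_identical(top2$elements, top$elements)
  weird <- infer_elements(mk("QQ7", "UNK"))
  expect_true(is.na(weird$elements[1L]))
})

test_that("element remapping overrides by label and by atom", {
  top <- infer_elements(
    topology(atom_labels = rep("CA", 5), elements = rep(NA_character_, 5),
             residue_ids = 1:5, residue_names = rep("ION", 5),
             chain_ids = rep("A", 5)))
  out <- remap_elements(top, list(list(label = "CA", element = "Ca")))
  expect_equal(out$elements, rep("Ca", 5))
  expect_equal(out$masses, rep(element_mass("Ca"), 5))
  expect_identical(remap_elements(out, list()), out)
  expect_warning(remap_elements(top, list(list(label = "ZZ", element = "O"))),
                 "absent label")
  expect_error(remap_elements(top, list(list(label = "CA", element = "Xx"))),
               "invalid element")
  one <- remap_elements(top, list(list(atom = 2L, element = "Mg")))
  expect_equal(one$elements[3L], "Mg")
  expect_equal(sum(one$elements == "Mg"), 1L)
})

test_that("csv and xvg tables import with filters and named columns", {
  p <- write_tmp(c("t,e", "0,1.5", "1,1.7"), "csv")
  tab <- import_table(p)
  expect_equal(names(tab$values), c("t", "e"))
  expect_equal(tab$values$e, c(1.5, 1.7))
  filt <- import_table(p, filter = "e")
  expect_equal(names(filt$values), "e")
  expect_error(import_table(p, filter = "nope"), "available.*t, e")

  x <- write_tmp(c("@    title \"demo\"", "# comment",
                   "@ s0 legend \"energy\"", "@ s1 legend \"temp\"",
                   "0.0 1.5 300", "1.0 1.7 301"), "xvg")
  tx <- import_table(x)
  expect_equal(names(tx$values), c("col0", "energy", "temp"))
  expect_equal(tx$values$energy, c(1.5, 1.7))
})

test_that("temporal export round-trips csv and xvg within 1e-9", {
  traj <- make_alanine_chain(n_res = 3, n_frames = 4, seed = 6)
  pt <- evaluate_script('a1 = angle(1, 2, 3) in resname("ALA")', traj)
  v <- pt$entries$a1
  for (fmt in c("csv", "xvg")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_temporal(list(a1 = v), path, fmt)
    back <- import_table(path)
    # time + one column per member + the population mean
    expect_length(back$values, 1L + 3L + 1L)
    for (k in 1:3) {
      expect_equal(back$values[[sprintf("a1[%d]", k)]], v$payload[, k],
                   tolerance = 1e-9)
    }
    expect_equal(back$values[["a1(mean)"]], rowMeans(v$payload),
                 tolerance = 1e-9)
  }
  short <- md_value("series", matrix(1:2, ncol = 1L))
  expect_error(export_temporal(list(a = v, b = short), tempfile(), "csv"),
               "mixed")
})

test_that("cube export is re-read identically by an independent parser", {
  set.seed(9)
  dens <- array(round(runif(2 * 3 * 4) * 10), dim = c(2L, 3L, 4L))
  vol <- volume_grid(c(2L, 3L, 4L), origin = c(-1, -2, -3),
                     axes = diag(c(0.5, 0.5, 0.5)), densities = dens)
  ref <- list(coordinates = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.5, 0)),
              elements = c("O", "H", "H"))
  path <- tempfile(fileext = ".cube")
  export_cube(vol, path, reference = ref)
  got <- oracle_read_cube(path)
  expect_equal(got$natoms, 3L)
  expect_equal(got$dims, c(2L, 3L, 4L))
  bohr <- 1 / 0.52917721092
  expect_equal(got$origin, c(-1, -2, -3) * bohr, tolerance = 1e-5)
  expect_equal(got$steps, diag(c(0.5, 0.5, 0.5)) * bohr, tolerance = 1e-5)
  expect_equal(got$densities, dens, tolerance = 1e-6)

  zero <- volume_grid(c(2L, 2L, 2L), origin = rep(0, 3), axes = diag(3))
  pz <- tempfile(fileext = ".cube")
  export_cube(zero, pz)
  gz <- oracle_read_cube(pz)
  expect_equal(gz$natoms, 0L)
  expect_true(all(gz$densities == 0))
})

test_that("PDB parsing agrees with an independent reader", {
  skip_if_not_installed("bio3d")
  traj <- make_alanine_chain(n_res = 3, n_frames = 1, seed = 2)
  path <- tempfile(fileext = ".pdb")
  write_trajectory(traj, path)
  ours <- read_topology(path)
  theirs <- suppressWarnings(bio3d::read.pdb(path))
  expect_equal(ours$atom_labels, trimws(theirs$atom$elety))
  expect_equal(ours$residue_ids, theirs$atom$resno)
  expect_equal(read_trajectory(ours, path)$frames[[1L]]$coordinates,
               matrix(theirs$xyz[1, ], ncol = 3L, byrow = TRUE),
               tolerance = 1e-6)
})
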