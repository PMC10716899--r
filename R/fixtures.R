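# Deterministic synthetic-system generators.  Every module of the package is
# testable without downloads: a poly-alanine chain with controllable backbone
# dihedrals, an ideal-gas-like box of rigid waters, a ligand/pocket system
# with constructed distances, and a molecule deliberately split across
# periodic boundaries.  Geometry favours testability over physical realism
# (rigid waters, ideal-gas dynamics); no physics claims attach to these
# systems.  All generators are seed-deterministic and never touch the global
# RNG state.

with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Internal-to-Cartesian placement: returns the point x with |x - c| = bond,
# angle(x, c, b) = ang (degrees) and dihedral(a, b, c, x) = tor (degrees).
place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
          -bond * sin(tor) * sin(ang))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Idealised peptide internal coordinates (Angstrom / degrees).
.pep <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_n_h = 1.010, b_ca_ha = 1.090, b_ca_cb = 1.521, b_cb_hb = 1.090,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, omega = 180
)

#' Build a poly-alanine chain trajectory
#'
#' Emulates a small single-chain test system: `n_res` alanine residues with
#' a full backbone (N, H, CA, HA, C, O) plus CB/HB side-chain atoms, built
#' from idealised peptide internal coordinates at the requested backbone
#' dihedrals.  Frames modulate phi/psi smoothly around their base values, so
#' the trajectory exercises per-residue contextual operations, Ramachandran
#' extraction, and temporal properties.  Defaults (15 residues, 500 frames)
#' emulate a 15-alanine reference data set.
#'
#' @param n_res Number of residues (`>= 2`).
#' @param n_frames Number of frames.
#' @param seed RNG seed (phases of the per-residue modulation).
#' @param phi,psi Base backbone dihedrals in degrees (alpha-helical
#'   defaults).
#' @param amplitude Peak dihedral modulation in degrees.
#' @return An [md_trajectory()] with inferred elements, masses and bonds.
#' @export
make_alanine_chain <- function(n_res = 15L, n_frames = 500L, seed = 1L,
                               phi = -57, psi = -47, amplitude = 8) {
  stopifnot(n_res >= 2L, n_frames >= 1L)
  with_fixture_seed(seed, {
    phase <- stats::runif(n_res, 0, 2 * pi)
    build <- function(t_frac) {
      wob <- amplitude * sin(2 * pi * t_frac + phase)
      build_polyala(n_res, phi + wob, psi + wob)
    }
    frames <- lapply(seq_len(n_frames), function(f) {
      t_frac <- if (n_frames == 1L) 0 else (f - 1) / n_frames
      md_frame(build(t_frac)$xyz, unit_cell(), time = f - 1)
    })
    proto <- build(0)
    top <- topology(atom_labels = proto$labels,
                    elements = proto$elements,
                    residue_ids = proto$resid,
                    residue_names = rep("ALA", length(proto$labels)),
                    chain_ids = rep("A", length(proto$labels)))
    top$bonds <- infer_bonds(top, frames[[1L]])
    trajectory(top, frames)
  })
}

# Backbone + side-chain construction at given per-residue phi/psi vectors.
build_polyala <- function(n_res, phi, psi) {
  phi <- rep(phi, length.out = n_res)
  psi <- rep(psi, length.out = n_res)
  p <- .pep
  # backbone trace: N, CA, C per residue
  N <- CA <- CC <- matrix(0, n_res, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(p$b_n_ca, 0, 0)
  ang <- p$a_n_ca_c * pi / 180
  CC[1L, ] <- CA[1L, ] + p$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      # phi(i): C(i-1)-N(i)-CA(i)-C(i)
      CC[i, ] <- place_atom(CC[i - 1L, ], N[i, ], CA[i, ],
                            p$b_ca_c, p$a_n_ca_c, phi[i])
    }
    if (i < n_res) {
      # psi(i): N(i)-CA(i)-C(i)-N(i+1)
      N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], CC[i, ],
                                p$b_c_n, p$a_ca_c_n, psi[i])
      # omega: CA(i)-C(i)-N(i+1)-CA(i+1) = 180 (trans)
      CA[i + 1L, ] <- place_atom(CA[i, ], CC[i, ], N[i + 1L, ],
                                 p$b_n_ca, p$a_c_n_ca, p$omega)
    }
  }
  labels <- character(0); elements <- character(0); resid <- integer(0)
  xyz <- NULL
  push <- function(lab, el, i, pos) {
    labels <<- c(labels, lab); elements <<- c(elements, el)
    resid <<- c(resid, i); xyz <<- rbind(xyz, pos)
  }
  for (i in seq_len(n_res)) {
    o <- place_atom(N[i, ], CA[i, ], CC[i, ], p$b_c_o, p$a_ca_c_o,
                    if (i < n_res) psi[i] + 180 else 180)
    h <- place_atom(CC[i, ], CA[i, ], N[i, ], p$b_n_h, 118,
                    if (i > 1L) phi[i] + 180 else 180)
    ha <- place_atom(CC[i, ], N[i, ], CA[i, ], p$b_ca_ha, 108, -118)
    cb <- place_atom(CC[i, ], N[i, ], CA[i, ], p$b_ca_cb, 110.5, 122)
    push("N", "N", i, N[i, ])
    push("H", "H", i, h)
    push("CA", "C", i, CA[i, ])
    push("HA", "H", i, ha)
    push("CB", "C", i, cb)
    for (k in 1:3) {
      hb <- place_atom(N[i, ], CA[i, ], cb, p$b_cb_hb, 109.5, -60 + 120 * k)
      push(sprintf("HB%d", k), "H", i, hb)
    }
    push("C", "C", i, CC[i, ])
    push("O", "O", i, o)
  }
  rownames(xyz) <- NULL
  list(labels = labels, elements = elements, resid = resid, xyz = xyz)
}

#' Build an ideal-gas-like box of rigid waters
#'
#' Rigid 3-site waters (labels OW/HW1/HW2, residue name SOL) at uniform
#' random positions with a small oxygen-oxygen exclusion distance,
#' re-randomized every frame so consecutive frames are independent samples
#' (ideal-gas-like, which makes the radial distribution function flat).
#' Waters near the box boundary are stored wrapped, so raw frames exercise
#' deperiodization.
#'
#' @param n_waters Number of water molecules.
#' @param box Cubic box edge (Angstrom).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param min_sep Minimum O-O separation (Angstrom).
#' @return An [md_trajectory()] with bonds and masses set.
#' @export
make_water_box <- function(n_waters = 100L, box = 30, n_frames = 50L,
                           seed = 1L, min_sep = 1.8) {
  stopifnot(n_waters >= 1L)
  cell <- unit_cell(rep(box, 3L))
  with_fixture_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      centers <- place_nonoverlapping(n_waters, box, min_sep)
      xyz <- matrix(0, 3L * n_waters, 3L)
      for (w in seq_len(n_waters)) {
        mol <- random_water(centers[w, ])
        xyz[(3L * w - 2L):(3L * w), ] <- mol
      }
      md_frame(wrap_position(xyz, cell), cell, time = f - 1)
    })
    n <- 3L * n_waters
    top <- topology(
      atom_labels = rep(c("OW", "HW1", "HW2"), n_waters),
      elements = rep(c("O", "H", "H"), n_waters),
      residue_ids = rep(seq_len(n_waters), each = 3L),
      residue_names = rep("SOL", n),
      chain_ids = rep("W", n),
      bonds = do.call(rbind, lapply(seq_len(n_waters), function(w) {
        o <- 3L * (w - 1L)
        rbind(c(o, o + 1L), c(o, o + 2L))
      }))
    )
    trajectory(top, frames)
  })
}

place_nonoverlapping <- function(n, box, min_sep, max_tries = 200L) {
  centers <- matrix(NA_real_, n, 3L)
  cell <- unit_cell(rep(box, 3L))
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- stats::runif(3L, 0, box)
    ok <- TRUE
    if (placed > 0L) {
      d <- minimum_image_distance(
        matrix(cand, placed, 3L, byrow = TRUE),
        centers[seq_len(placed), , drop = FALSE], cell)
      ok <- all(d >= min_sep)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries) stop("packing failure: box too small for n_waters")
    }
  }
  centers
}

random_water <- function(center) {
  # rigid geometry: O-H 0.9572, H-O-H 104.52 degrees, random orientation
  b <- 0.9572
  half <- 104.52 / 2 * pi / 180
  local <- rbind(c(0, 0, 0),
                 c(b * sin(half), b * cos(half), 0),
                 c(-b * sin(half), b * cos(half), 0))
  R <- random_rotation()
  sweep(local %*% t(R), 2L, center, `+`)
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9L), 3L)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Build a ligand/pocket system with constructed distances
#'
#' One rigid five-atom ligand residue named AIN plus `n_pocket_res` rigid
#' host residues (name PCK) whose centers of mass sit at controlled,
#' monotonically drifting distances from the ligand center of mass, so
#' contextual ligand-to-residue distance properties have known values.
#'
#' @param n_pocket_res Number of pocket residues.
#' @param n_frames Number of frames.
#' @param seed RNG seed (placement directions).
#' @param d0 Base ligand-to-pocket distance (Angstrom); residue `k` starts at
#'   `d0 + k`.
#' @param drift Distance increase per frame (Angstrom).
#' @return An [md_trajectory()].  The construction guarantees the center-of-
#'   mass distance of pocket residue `k` at frame `f` equals
#'   `d0 + k + drift * (f - 1)`.
#' @export
make_ligand_pocket <- function(n_pocket_res = 6L, n_frames = 10L, seed = 1L,
                               d0 = 5, drift = 0.1) {
  stopifnot(n_pocket_res >= 1L)
  with_fixture_seed(seed, {
    dirs <- matrix(stats::rnorm(3L * n_pocket_res), n_pocket_res, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    # symmetric rigid bodies so the center of mass equals the body center
    lig_local <- rbind(c(0, 0, 0),
                       c(1.4, 0, 0), c(-1.4, 0, 0),
                       c(0, 1.4, 0), c(0, -1.4, 0))
    pck_local <- rbind(c(0.9, 0, 0), c(-0.45, 0.779, 0), c(-0.45, -0.779, 0))
    n_atoms_tot <- 5L + 3L * n_pocket_res
    frames <- lapply(seq_len(n_frames), function(f) {
      xyz <- lig_local
      for (k in seq_len(n_pocket_res)) {
        d <- d0 + k + drift * (f - 1)
        xyz <- rbind(xyz, sweep(pck_local, 2L, d * dirs[k, ], `+`))
      }
      md_frame(xyz, unit_cell(), time = f - 1)
    })
    top <- topology(
      atom_labels = c(c("C1", "C2", "C3", "O1", "O2"),
                      rep(c("P1", "P2", "P3"), n_pocket_res)),
      elements = c(c("C", "C", "C", "O", "O"),
                   rep(c("C", "C", "C"), n_pocket_res)),
      residue_ids = c(rep(1L, 5L), rep(seq_len(n_pocket_res) + 1L, each = 3L)),
      residue_names = c(rep("AIN", 5L),
                        rep("PCK", 3L * n_pocket_res)),
      chain_ids = rep("A", n_atoms_tot),
      bonds = rbind(
        cbind(0L, 1:4),
        do.call(rbind, lapply(seq_len(n_pocket_res), function(k) {
          o <- 5L + 3L * (k - 1L)
          rbind(c(o, o + 1L), c(o, o + 2L))
        }))
      )
    )
    trajectory(top, frames)
  })
}

#' Build a molecule deliberately split across periodic boundaries
#'
#' A single bonded carbon chain positioned across a box corner and stored
#' wrapped, so consecutive bonded atoms sit in different periods until
#' [deperiodize_frame()] makes the structure whole.
#'
#' @param box Cubic box edge (Angstrom).
#' @param n_atoms Chain length.
#' @param seed RNG seed (chain direction jitter).
#' @param n_frames Number of frames.
#' @return An [md_trajectory()] with one frame per requested frame.
#' @export
make_split_molecule <- function(box = 10, n_atoms = 8L, seed = 1L,
                                n_frames = 1L) {
  cell <- unit_cell(rep(box, 3L))
  with_fixture_seed(seed, {
    start <- c(box - 2, box / 2, box / 2)
    step0 <- c(1.5, 0, 0)
    frames <- lapply(seq_len(n_frames), function(f) {
      xyz <- matrix(0, n_atoms, 3L)
      xyz[1L, ] <- start
      for (k in 2L:n_atoms) {
        jitter <- stats::runif(3L, -0.05, 0.05) * c(0, 1, 1)
        xyz[k, ] <- xyz[k - 1L, ] + step0 + jitter
      }
      md_frame(wrap_position(xyz, cell), cell, time = f - 1)
    })
    top <- topology(
      atom_labels = sprintf("C%d", seq_len(n_atoms)),
      elements = rep("C", n_atoms),
      residue_ids = rep(1L, n_atoms),
      residue_names = rep("UNK", n_atoms),
      chain_ids = rep("A", n_atoms),
      bonds = cbind(0L:(n_atoms - 2L), 1L:(n_atoms - 1L))
    )
    trajectory(top, frames)
  })
}

# ---- fixture serialisation (PDB / GRO / XYZ emission for end-to-end tests)

#' Write a trajectory to PDB, GRO or XYZ
#'
#' Fixture serialisers used for command-line and round-trip tests.  PDB
#' output carries CRYST1, MODEL/ENDMDL blocks, the element column and CONECT
#' records; GRO output is in nm with a box line; XYZ is the plain
#' count/comment/atoms dialect in Angstrom.
#'
#' @param traj An [md_trajectory()].
#' @param path Output path; the extension picks the format.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pdb = write_pdb(traj, path),
    gro = write_gro(traj, path),
    xyz = write_xyz(traj, path),
    stop(sprintf("unsupported output extension '.%s'", ext))
  )
}

write_pdb <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  cell <- traj$frames[[1L]]$cell
  if (any(cell$periodic)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       cell$lengths[1L], cell$lengths[2L], cell$lengths[3L],
                       90, 90, 90), con)
  }
  n <- n_atoms(top)
  for (m in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- traj$frames[[m]]$coordinates
    for (k in seq_len(n)) {
      el <- top$elements[k]
      writeLines(sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                         k, top$atom_labels[k], top$residue_names[k],
                         substr(top$chain_ids[k], 1, 1), top$residue_ids[k],
                         xyz[k, 1L], xyz[k, 2L], xyz[k, 3L], 1, 0,
                         if (is.na(el)) "" else el), con)
    }
    writeLines("ENDMDL", con)
  }
  if (nrow(top$bonds)) {
    for (k in seq_len(nrow(top$bonds))) {
      writeLines(sprintf("CONECT%5d%5d", top$bonds[k, 1L] + 1L,
                         top$bonds[k, 2L] + 1L), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

write_gro <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  n <- n_atoms(top)
  for (m in seq_along(traj$frames)) {
    fr <- traj$frames[[m]]
    writeLines(sprintf("fixture frame t= %g", fr$time), con)
    writeLines(sprintf("%5d", n), con)
    for (k in seq_len(n)) {
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         top$residue_ids[k] %% 100000L,
                         substr(top$residue_names[k], 1, 5),
                         substr(top$atom_labels[k], 1, 5),
                         k %% 100000L,
                         fr$coordinates[k, 1L] / 10,
                         fr$coordinates[k, 2L] / 10,
                         fr$coordinates[k, 3L] / 10), con)
    }
    L <- ifelse(fr$cell$periodic, fr$cell$lengths / 10, 0)
    writeLines(sprintf("%10.5f%10.5f%10.5f", L[1L], L[2L], L[3L]), con)
  }
  invisible(path)
}

write_xyz <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  n <- n_atoms(top)
  el <- ifelse(is.na(top$elements), "X", top$elements)
  for (m in seq_along(traj$frames)) {
    fr <- traj$frames[[m]]
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d t= %g", m - 1L, fr$time), con)
    writeLines(sprintf("%-3s %12.6f %12.6f %12.6f", el,
                       fr$coordinates[, 1L], fr$coordinates[, 2L],
                       fr$coordinates[, 3L]), con)
  }
  invisible(path)
}
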