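# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately naive (brute force, direct convolution, plain BFS) and stay
# independent of the implementation paths they check.

# Minimum-image distance by brute force over all 27 periodic images.
oracle_min_image_distance <- function(a, b, lengths) {
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- Inf
  for (k in seq_len(nrow(shifts))) {
    d <- b + shifts[k, ] * lengths - a
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# Radial growth by all-pairs brute force.
oracle_grow_radial <- function(atoms0, coords, lengths, radius) {
  n <- nrow(coords)
  keep <- logical(n)
  keep[atoms0 + 1L] <- TRUE
  for (i in seq_len(n)) {
    if (keep[i]) next
    for (j in atoms0 + 1L) {
      if (oracle_min_image_distance(coords[i, ], coords[j, ], lengths) <= radius) {
        keep[i] <- TRUE
        break
      }
    }
  }
  which(keep) - 1L
}

# Flood fill by iterated neighbour expansion over an edge list.
oracle_grow_covalent <- function(atoms0, bonds, steps) {
  cur <- sort(unique(atoms0))
  for (s in seq_len(steps)) {
    nb <- integer(0)
    for (k in seq_len(nrow(bonds))) {
      if (bonds[k, 1L] %in% cur) nb <- c(nb, bonds[k, 2L])
      if (bonds[k, 2L] %in% cur) nb <- c(nb, bonds[k, 1L])
    }
    nxt <- sort(unique(c(cur, nb)))
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

# Direct (non-separable) periodic 2D Gaussian convolution of a histogram.
oracle_smooth_2d <- function(h, sigma_degrees) {
  n <- nrow(h)
  w <- 360 / n
  sigma <- sigma_degrees / w
  wrap <- function(d) ((d + n %/% 2) %% n) - n %/% 2
  k1 <- exp(-wrap(seq_len(n) - 1L)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (a in seq_len(n)) for (b in seq_len(n)) {
      acc <- acc + h[a, b] * k1[(wrap(i - a) %% n) + 1L] * k1[(wrap(j - b) %% n) + 1L]
    }
    out[i, j] <- acc
  }
  out / sum(out)
}

# Minimal independent Gaussian cube reader (Bohr convention).
oracle_read_cube <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(trimws(lines[3L]), "\\s+")[[1L]])
  natoms <- abs(as.integer(hdr[1L]))
  dims <- integer(3L)
  steps <- matrix(0, 3L, 3L)
  for (k in 1:3) {
    v <- as.numeric(strsplit(trimws(lines[3L + k]), "\\s+")[[1L]])
    dims[k] <- as.integer(v[1L])
    steps[k, ] <- v[2:4]
  }
  data_lines <- lines[(6L + natoms + 1L):length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(data_lines), "\\s+")))
  # cube order is x-outer / z-inner
  arr <- aperm(array(vals, dim = rev(dims)), c(3L, 2L, 1L))
  list(natoms = natoms, origin = hdr[2:4], dims = dims, steps = steps,
       densities = arr)
}

# Two protein chains (A and B) of alanine in one topology, chain B rigidly
# offset, for multi-context selection semantics.
make_two_chain_protein <- function(n_res = 4L, n_frames = 2L, seed = 7L) {
  one <- make_alanine_chain(n_res = n_res, n_frames = n_frames, seed = seed,
                            amplitude = 2)
  top1 <- one$topology
  n1 <- n_atoms(top1)
  top <- topology(
    atom_labels = rep(top1$atom_labels, 2L),
    elements = rep(top1$elements, 2L),
    residue_ids = c(top1$residue_ids, top1$residue_ids),
    residue_names = rep(top1$residue_names, 2L),
    chain_ids = c(rep("A", n1), rep("B", n1)),
    bonds = rbind(top1$bonds, top1$bonds + n1)
  )
  frames <- lapply(one$frames, function(fr) {
    md_frame(rbind(fr$coordinates,
                   sweep(fr$coordinates, 2L, c(50, 0, 0), `+`)),
             fr$cell, fr$time)
  })
  trajectory(top, frames)
}

# Drop source spans and checker annotations so parse trees can be compared
# structurally.
strip_tree <- function(x) {
  if (!is.list(x)) return(x)
  x$span <- NULL
  x$vtype <- NULL
  lapply(x, strip_tree)
}
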