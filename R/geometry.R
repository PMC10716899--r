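# Geometry kernels: periodic minimum image, deperiodization, recentering,
# internal coordinates, Kabsch superposition, gyration-tensor shape measures
# and selection growth.

#' Minimum-image convention for a displacement
#'
#' Maps each periodic component of a displacement to the image of smallest
#' magnitude: `d - L * round(d / L)` with round-half-to-even ties (so a
#' displacement of exactly `L/2` is left unchanged).
#'
#' @param delta Numeric vector of length 3 or an N x 3 matrix of
#'   displacements (Angstrom).
#' @param cell A [unit_cell()]; non-periodic axes pass through unchanged.
#' @return Displacement(s) of the same shape as `delta`.
#' @examples
#' minimum_image(c(6, 0, 0), unit_cell(c(10, 10, 10)))
#' @export
minimum_image <- function(delta, cell) {
  vec <- is.null(dim(delta))
  m <- if (vec) matrix(delta, ncol = 3L) else delta
  for (ax in 1:3) {
    if (cell$periodic[ax]) {
      L <- cell$lengths[ax]
      m[, ax] <- m[, ax] - L * round(m[, ax] / L)
    }
  }
  if (vec) drop(m) else m
}

minimum_image_distance <- function(a, b, cell) {
  d <- minimum_image(b - a, cell)
  if (is.null(dim(d))) sqrt(sum(d * d)) else sqrt(rowSums(d * d))
}

# Wrap absolute positions into the primary cell [0, L).
wrap_position <- function(pos, cell) {
  vec <- is.null(dim(pos))
  m <- if (vec) matrix(pos, ncol = 3L) else pos
  for (ax in 1:3) {
    if (cell$periodic[ax]) {
      m[, ax] <- m[, ax] %% cell$lengths[ax]
    }
  }
  if (vec) drop(m) else m
}

#' Mass-weighted center of mass of an atom set
#'
#' Coordinates are used as stored; for structures split across a periodic
#' boundary, deperiodize first ([deperiodize_frame()]) so the center of mass
#' falls inside the structure rather than mid-box.
#'
#' @param frame An [md_frame()].
#' @param atoms Integer vector of 0-based atom indices (non-empty).
#' @param masses Numeric masses for *all* atoms of the frame (subset is taken
#'   internally); equal weighting when `NULL`.
#' @return Length-3 numeric position (Angstrom).
#' @export
center_of_mass <- function(frame, atoms, masses = NULL) {
  if (length(atoms) == 0L) stop("center of mass of an empty set")
  xyz <- frame$coordinates[atoms + 1L, , drop = FALSE]
  w <- if (is.null(masses)) rep(1, length(atoms)) else masses[atoms + 1L]
  if (any(!is.finite(w)) || any(w <= 0)) w <- rep(1, length(atoms))
  colSums(xyz * w) / sum(w)
}

#' Make covalent structures whole across periodic boundaries
#'
#' For every connected covalent structure: atoms are unwrapped by walking the
#' bond graph with minimum-image steps from the lowest-index atom, the
#' structure's center of mass is computed, wrapped into the primary cell, and
#' the whole structure is translated so its center of mass sits in the viewed
#' period.  The operation is idempotent.
#'
#' @param frame An [md_frame()].
#' @param topology The [topology()] supplying bonds and masses.
#' @return A new [md_frame()] with whole structures.
#' @export
deperiodize_frame <- function(frame, topology) {
  cell <- frame$cell
  if (!any(cell$periodic)) return(frame)
  n <- n_atoms(topology)
  coords <- frame$coordinates
  adj <- bond_adjacency(topology$bonds, n)
  comp <- connected_structures(topology)
  out <- coords
  for (ctx in comp$contexts) {
    ix <- ctx + 1L                           # 1-based
    un <- unwrap_structure(coords, adj, ix, cell)
    w <- topology$masses[ix]
    if (any(!is.finite(w)) || any(w <= 0)) w <- rep(1, length(ix))
    com <- colSums(un[ix, , drop = FALSE] * w) / sum(w)
    shift <- wrap_position(com, cell) - com
    out[ix, ] <- sweep(un[ix, , drop = FALSE], 2L, shift, `+`)
  }
  md_frame(out, cell = cell, time = frame$time)
}

# BFS unwrap of one component: each atom is placed next to its parent using
# the minimum-image displacement of the raw coordinates.
unwrap_structure <- function(coords, adj, ix, cell) {
  un <- coords
  root <- min(ix)
  visited <- logical(nrow(coords))
  visited[root] <- TRUE
  queue <- root
  while (length(queue)) {
    a <- queue[[1L]]
    queue <- queue[-1L]
    for (b in adj[[a]]) {
      if (!visited[b]) {
        visited[b] <- TRUE
        step <- minimum_image(coords[b, ] - coords[a, ], cell)
        un[b, ] <- un[a, ] + step
        queue <- c(queue, b)
      }
    }
  }
  un
}

#' Recenter a trajectory on the center of mass of an atom set
#'
#' Each frame is translated so the supplied set's center of mass lies at the
#' cell center, after which all covalent structures are re-wrapped whole into
#' the primary cell.  Idempotent, and intra-structure minimum-image pairwise
#' distances are preserved.
#'
#' @param traj An [md_trajectory()].
#' @param atoms Integer vector of 0-based atom indices (non-empty).
#' @return A recentered [md_trajectory()].
#' @export
recenter_trajectory <- function(traj, atoms) {
  if (length(atoms) == 0L) stop("recenter requires a non-empty atom set")
  top <- traj$topology
  frames <- lapply(traj$frames, function(fr) {
    fr <- deperiodize_frame(fr, top)
    com <- center_of_mass(fr, atoms, top$masses)
    target <- ifelse(fr$cell$periodic, fr$cell$lengths / 2, com)
    shifted <- sweep(fr$coordinates, 2L, target - com, `+`)
    deperiodize_frame(md_frame(shifted, fr$cell, fr$time), top)
  })
  trajectory(top, frames)
}

#' Internal coordinates: distance, angle, dihedral
#'
#' Distances respect the minimum-image convention.  Angles are reported in
#' degrees on `[0, 180]`; dihedrals in degrees on `(-180, 180]` with the
#' IUPAC sign convention (cis = 0, trans = 180, and
#' `dihedral(a,b,c,d) == -dihedral(d,c,b,a)`).
#'
#' @param a,b,c,d Length-3 numeric positions (Angstrom).
#' @param cell Optional [unit_cell()] for minimum-image displacements;
#'   omitted (or `NULL`) means no wrapping.
#' @return A numeric scalar.
#' @export
calc_distance <- function(a, b, cell = NULL) {
  d <- b - a
  if (!is.null(cell)) d <- minimum_image(d, cell)
  sqrt(sum(d * d))
}

#' @rdname calc_distance
#' @export
calc_angle <- function(a, b, c, cell = NULL) {
  v1 <- a - b
  v2 <- c - b
  if (!is.null(cell)) {
    v1 <- minimum_image(v1, cell)
    v2 <- minimum_image(v2, cell)
  }
  n1 <- sqrt(sum(v1 * v1)); n2 <- sqrt(sum(v2 * v2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("degenerate geometry: zero-length vector in angle")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' @rdname calc_distance
#' @export
calc_dihedral <- function(a, b, c, d, cell = NULL) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  if (!is.null(cell)) {
    b1 <- minimum_image(b1, cell)
    b2 <- minimum_image(b2, cell)
    b3 <- minimum_image(b3, cell)
  }
  if (sqrt(sum(b2 * b2)) < 1e-12) stop("degenerate geometry: zero-length axis in dihedral")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1 * n1) < 1e-18 || sum(n2 * n2) < 1e-18) {
    stop("degenerate geometry: collinear atoms in dihedral")
  }
  m1 <- cross3(n1, b2 / sqrt(sum(b2 * b2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  # convention anchor: trans-planar = 180 (not -180)
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Kabsch superposition of two point sets
#'
#' Computes the mass-weighted least-squares rigid transform (proper rotation
#' plus translation; reflections are excluded by a determinant correction)
#' aligning `mobile` onto `reference`, and the minimized RMSD.
#'
#' @param mobile,reference N x 3 matrices of matching point counts.
#' @param masses Optional length-N weights; equal weighting when `NULL`.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), `rmsd` (Angstrom) and
#'   `transform(points)`, a function applying the rigid motion.
#' @export
kabsch_superpose <- function(mobile, reference, masses = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("point-count mismatch in superposition")
  n <- nrow(mobile)
  w <- if (is.null(masses)) rep(1, n) else as.numeric(masses)
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- cr - drop(R %*% cm)
  aligned <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - Q)^2)))
  transform <- function(points) {
    sweep(as.matrix(points) %*% t(R), 2L, translation, `+`)
  }
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = transform)
}

#' Gyration-tensor shape anisotropy weights
#'
#' The mass-weighted gyration tensor of the set is diagonalised
#' (eigenvalues `l1 >= l2 >= l3 >= 0`) and mapped to the barycentric
#' anisotropy weights `c_lin = (l1 - l2)/T`, `c_plan = 2 (l2 - l3)/T`,
#' `c_iso = 3 l3 / T` with `T = l1 + l2 + l3`.  The weights sum to one and
#' place the configuration in the shape triangle with corners linear
#' (bottom-left, `(0,0)`), planar (bottom-right, `(1,0)`) and isotropic
#' (top, `(0.5, 1)`).
#'
#' @param frame An [md_frame()].
#' @param atoms 0-based atom indices (at least two).
#' @param masses Optional full-length mass vector.
#' @return List with `c_lin`, `c_plan`, `c_iso`, `point2d` (length-2), and
#'   `eigenvalues`.
#' @export
shape_weights <- function(frame, atoms, masses = NULL) {
  if (length(atoms) < 2L) stop("shape weights require at least two atoms")
  xyz <- frame$coordinates[atoms + 1L, , drop = FALSE]
  w <- if (is.null(masses)) rep(1, length(atoms)) else masses[atoms + 1L]
  if (any(!is.finite(w)) || any(w <= 0)) w <- rep(1, length(atoms))
  w <- w / sum(w)
  com <- colSums(xyz * w)
  X <- sweep(xyz, 2L, com)
  S <- t(X * w) %*% X
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  total <- sum(ev)
  if (total < 1e-12) stop("all atoms coincident: shape weights undefined")
  c_lin <- (ev[1L] - ev[2L]) / total
  c_plan <- 2 * (ev[2L] - ev[3L]) / total
  c_iso <- 3 * ev[3L] / total
  point2d <- c_lin * c(0, 0) + c_plan * c(1, 0) + c_iso * c(0.5, 1)
  list(c_lin = c_lin, c_plan = c_plan, c_iso = c_iso,
       point2d = point2d, eigenvalues = ev)
}

#' Grow a selection across covalent bonds
#'
#' Breadth-first flood fill over the bond graph, expanding the flattened
#' input set by at most `steps` bond hops.  Always a superset of the input.
#'
#' @param selection An `md_selection`.
#' @param topology The [topology()] supplying bonds.
#' @param steps Non-negative number of bond hops.
#' @return A one-context `md_selection` containing the grown set.
#' @export
grow_covalent <- function(selection, topology, steps) {
  if (steps < 0) stop("steps must be >= 0")
  n <- n_atoms(topology)
  adj <- bond_adjacency(topology$bonds, n)
  current <- selection_atoms(selection) + 1L
  visited <- logical(n)
  visited[current] <- TRUE
  frontier <- current
  k <- 0L
  while (k < steps && length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
    k <- k + 1L
  }
  context_selection(list(which(visited) - 1L),
                    source = selection$source, n_atoms = n)
}

#' Grow a selection radially
#'
#' Adds every atom whose minimum-image distance to any atom of the flattened
#' input set is at most `radius`.  A periodic cell-list grid keeps the
#' expected cost linear; results equal the brute-force all-pairs rule.
#'
#' @param selection An `md_selection`.
#' @param frame The [md_frame()] supplying coordinates and cell.
#' @param radius Growth radius in Angstrom (`>= 0`).
#' @return A one-context `md_selection` containing the grown set.
#' @export
grow_radial <- function(selection, frame, radius) {
  if (radius < 0) stop("radius must be >= 0")
  n <- nrow(frame$coordinates)
  sel <- selection_atoms(selection)
  if (radius == 0 || length(sel) == 0L) {
    return(context_selection(list(sel), source = selection$source, n_atoms = n))
  }
  coords <- frame$coordinates
  inset <- logical(n)
  inset[sel + 1L] <- TRUE
  pairs <- candidate_pairs(coords, frame$cell, radius)
  keep <- logical(n)
  keep[sel + 1L] <- TRUE
  if (nrow(pairs)) {
    i <- pairs[, 1L] + 1L; j <- pairs[, 2L] + 1L
    touch <- xor(inset[i], inset[j]) | (inset[i] & inset[j])
    cand <- which(inset[i] | inset[j])
    if (length(cand)) {
      d <- minimum_image_distance(coords[i[cand], , drop = FALSE],
                                  coords[j[cand], , drop = FALSE], frame$cell)
      hit <- cand[d <= radius]
      keep[i[hit]] <- keep[i[hit]] | inset[j[hit]]
      keep[j[hit]] <- keep[j[hit]] | inset[i[hit]]
    }
  }
  context_selection(list(which(keep) - 1L), source = selection$source,
                    n_atoms = n)
}
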