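# Shared data model: topology, unit cell, frames, trajectories, contextual
# selections and the typed values produced by script evaluation.  All atom
# indices are 0-based internally; the scripting language exposes 1-based
# indices and converts at its boundary.

# Pinned numerical constants for bond inference so tests can assert them.
.mdscript_config <- list(
  bond_scale = 1.3,     # bond if d <= scale * (r_cov(a) + r_cov(b))
  hydrogen_cap = 1.2    # any bond involving H additionally requires d <= cap (Angstrom)
)

#' Bond-inference configuration
#'
#' Returns the fixed parameters of the distance-based covalent bond
#' heuristic: the covalent-radius scale factor and the hydrogen distance cap.
#' @return Named list with elements `bond_scale` and `hydrogen_cap`.
#' @export
bond_config <- function() .mdscript_config

#' Construct a molecular topology
#'
#' A topology holds the static per-atom records of a system: labels, element
#' symbols, residue numbering and names, chain identifiers, masses, and the
#' covalent bond list.  Atoms of one residue must be contiguous in index
#' order.
#'
#' @param atom_labels Character vector of atom labels (e.g. `"CA"`, `"OW"`).
#' @param elements Character vector of element symbols; `NA` where unknown
#'   (e.g. before [infer_elements()] has run).
#' @param residue_ids Integer vector of residue numbers per atom.
#' @param residue_names Character vector of residue names per atom.
#' @param chain_ids Character vector of chain identifiers per atom.
#' @param masses Numeric vector of atomic masses (u); if `NULL`, filled from
#'   the standard element-mass table (NA elements get mass `NA`).
#' @param bonds Two-column integer matrix of 0-based atom index pairs, or
#'   `NULL` for no recorded bonds.
#' @return An object of class `"md_topology"`.
#' @examples
#' top <- topology(atom_labels = c("O", "H1", "H2"),
#'                 elements = c("O", "H", "H"),
#'                 residue_ids = c(1L, 1L, 1L),
#'                 residue_names = rep("HOH", 3),
#'                 chain_ids = rep("A", 3),
#'                 bonds = rbind(c(0L, 1L), c(0L, 2L)))
#' n_atoms(top)
#' @export
topology <- function(atom_labels, elements, residue_ids, residue_names,
                     chain_ids, masses = NULL, bonds = NULL) {
  n <- length(atom_labels)
  if (n < 1L) stop("topology must contain at least one atom")
  elements <- as.character(elements)
  stopifnot(length(elements) == n, length(residue_ids) == n,
            length(residue_names) == n, length(chain_ids) == n)
  if (is.null(masses)) {
    masses <- element_mass(elements)
  }
  stopifnot(length(masses) == n)
  bonds <- normalize_bonds(bonds, n)
  # residues must be contiguous runs of (chain, resid)
  res_key <- paste(chain_ids, residue_ids, sep = "\r")
  runs <- rle(res_key)
  if (anyDuplicated(runs$values)) {
    stop("atoms of one residue must be contiguous in index order")
  }
  structure(
    list(atom_labels = as.character(atom_labels),
         elements = elements,
         residue_ids = as.integer(residue_ids),
         residue_names = as.character(residue_names),
         chain_ids = as.character(chain_ids),
         masses = as.numeric(masses),
         bonds = bonds),
    class = "md_topology"
  )
}

normalize_bonds <- function(bonds, n) {
  if (is.null(bonds) || NROW(bonds) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (any(bonds < 0L) || any(bonds >= n)) stop("bond index out of range")
  if (any(bonds[, 1L] == bonds[, 2L])) stop("self-bonds are not allowed")
  ij <- cbind(pmin(bonds[, 1L], bonds[, 2L]), pmax(bonds[, 1L], bonds[, 2L]))
  ij <- unique(ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE])
  dimnames(ij) <- list(NULL, c("i", "j"))
  ij
}

#' @rdname topology
#' @param x A topology.
#' @export
n_atoms <- function(x) UseMethod("n_atoms")

#' @export
n_atoms.md_topology <- function(x) length(x$atom_labels)

#' @export
print.md_topology <- function(x, ...) {
  cat(sprintf("<md_topology> %d atoms, %d residues, %d chains, %d bonds\n",
              n_atoms(x), length(unique(paste(x$chain_ids, x$residue_ids))),
              length(unique(x$chain_ids)), nrow(x$bonds)))
  invisible(x)
}

# Per-atom residue index (1..n_res, in order of appearance).
residue_index <- function(top) {
  key <- paste(top$chain_ids, top$residue_ids, sep = "\r")
  match(key, unique(key))
}

# Data frame with one row per residue: index, id, name, chain, atom range.
residue_table <- function(top) {
  ridx <- residue_index(top)
  first <- !duplicated(ridx)
  data.frame(index = ridx[first],
             resid = top$residue_ids[first],
             resname = top$residue_names[first],
             chain = top$chain_ids[first],
             start = which(first) - 1L,              # 0-based first atom
             count = as.integer(table(ridx)),
             stringsAsFactors = FALSE)
}

#' Construct an orthorhombic unit cell
#'
#' @param lengths Numeric length-3 vector of box edge lengths (Angstrom).
#' @param periodic Logical length-3 vector; `FALSE` axes are never wrapped.
#' @return An object of class `"md_cell"`.
#' @export
unit_cell <- function(lengths = c(0, 0, 0),
                      periodic = lengths > 0) {
  lengths <- as.numeric(lengths)
  periodic <- as.logical(periodic)
  stopifnot(length(lengths) == 3L, length(periodic) == 3L)
  if (any(periodic & lengths <= 0)) {
    stop("periodic axes require positive box lengths")
  }
  structure(list(lengths = lengths, periodic = periodic), class = "md_cell")
}

#' Construct a trajectory frame
#'
#' @param coordinates N x 3 numeric matrix of positions (Angstrom).
#' @param cell A [unit_cell()].
#' @param time Frame time in picoseconds.
#' @return An object of class `"md_frame"`.
#' @export
md_frame <- function(coordinates, cell = unit_cell(), time = 0) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  dimnames(coordinates) <- NULL
  if (ncol(coordinates) != 3L) stop("coordinates must be N x 3")
  if (any(!is.finite(coordinates))) stop("non-finite coordinates in frame")
  structure(list(coordinates = coordinates, cell = cell,
                 time = as.numeric(time)),
            class = "md_frame")
}

#' Construct a trajectory
#'
#' @param topology A [topology()].
#' @param frames List of [md_frame()] objects with matching atom counts and
#'   non-decreasing times.
#' @return An object of class `"md_trajectory"`.
#' @export
trajectory <- function(topology, frames) {
  if (length(frames) < 1L) stop("trajectory requires at least one frame")
  n <- n_atoms(topology)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$coordinates) != n) {
      stop(sprintf("frame %d: expected %d atoms, got %d",
                   k, n, nrow(frames[[k]]$coordinates)))
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  structure(list(topology = topology, frames = frames),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d atoms x %d frames\n",
              n_atoms(x$topology), length(x$frames)))
  invisible(x)
}

#' @rdname trajectory
#' @param x A trajectory.
#' @export
n_frames <- function(x) length(x$frames)

frame_times <- function(traj) vapply(traj$frames, `[[`, numeric(1), "time")

#' Construct a contextual selection
#'
#' A selection is an ordered list of pairwise-disjoint 0-based atom-index
#' sets; each set is one *context*.  Contextual evaluation (`expr in ctx`)
#' runs an operation once per context.
#'
#' @param contexts List of integer vectors (0-based atom indices); each is
#'   sorted and de-duplicated on construction.
#' @param source Text of the originating expression (for diagnostics).
#' @param n_atoms Optional atom count to validate indices against.
#' @return An object of class `"md_selection"`.
#' @examples
#' sel <- context_selection(list(c(0L, 1L), c(2L, 3L)))
#' flatten_contexts(sel)
#' @export
context_selection <- function(contexts, source = "", n_atoms = NULL) {
  contexts <- lapply(unname(contexts), function(ix) {
    unname(sort(unique(as.integer(ix))))
  })
  all_ix <- unlist(contexts, use.names = FALSE)
  if (length(all_ix)) {
    if (any(all_ix < 0L)) stop("negative atom index in selection")
    if (!is.null(n_atoms) && any(all_ix >= n_atoms)) {
      stop("atom index out of range for topology")
    }
    if (anyDuplicated(all_ix)) stop("selection contexts must be disjoint")
  }
  structure(list(contexts = contexts, source = source),
            class = "md_selection")
}

#' @export
print.md_selection <- function(x, ...) {
  cat(sprintf("<md_selection> %d context(s), %d atom(s)%s\n",
              length(x$contexts), length(unlist(x$contexts)),
              if (nzchar(x$source)) paste0("  [", x$source, "]") else ""))
  invisible(x)
}

n_contexts <- function(sel) length(sel$contexts)

selection_atoms <- function(sel) sort(unique(unlist(sel$contexts, use.names = FALSE)))

#' Flatten a contextual selection into a single set
#'
#' The `and` operator of the scripting language implicitly flattens its
#' operands; this is the corresponding model operation.  The result always
#' has exactly one context: the union of the input contexts (the empty union
#' for a selection with no contexts).
#'
#' @param selection A [context_selection()].
#' @return A one-context `md_selection`.
#' @export
flatten_contexts <- function(selection) {
  context_selection(list(selection_atoms(selection)),
                    source = selection$source)
}

#' Construct a typed evaluation value
#'
#' Script evaluation produces typed values: per-frame scalars (`series`),
#' per-frame-per-context populations (`population_series`), 1D distributions,
#' 3D volume grids, or selections.  Series payloads are frames x length
#' matrices.
#'
#' @param kind One of `"scalar"`, `"series"`, `"population_series"`,
#'   `"distribution"`, `"volume"`, `"selection"`.
#' @param payload Numeric content (matrix for series kinds; [histogram()] for
#'   distributions; [volume_grid()] for volumes; `md_selection` for
#'   selections).
#' @param unit Unit annotation (`"angstrom"`, `"degrees"`, `""`, ...).
#' @param times Frame times for series kinds.
#' @return An object of class `"md_value"`.
#' @export
md_value <- function(kind, payload, unit = "", times = NULL) {
  kind <- match.arg(kind, c("scalar", "series", "population_series",
                            "distribution", "volume", "selection"))
  len <- switch(kind,
    scalar = 1L,
    series = 1L,
    population_series = ncol(payload),
    distribution = 1L,
    volume = 1L,
    selection = n_contexts(payload)
  )
  structure(list(kind = kind, payload = payload, unit = unit,
                 length = len, times = times),
            class = "md_value")
}

#' @export
print.md_value <- function(x, ...) {
  extra <- if (x$kind %in% c("series", "population_series")) {
    sprintf(" [%d frame(s) x %d]", nrow(x$payload), x$length)
  } else ""
  cat(sprintf("<md_value> %s%s %s\n", x$kind, extra,
              if (nzchar(x$unit)) paste0("(", x$unit, ")") else ""))
  invisible(x)
}

is_promotable <- function(value) {
  value$kind %in% c("series", "population_series", "distribution", "volume")
}

#' Aggregate a population series across its members
#'
#' Population properties can be displayed as per-frame aggregates: min, max,
#' mean, or variance across the population axis.
#'
#' @param value A `population_series` [md_value()].
#' @param mode One of `"min"`, `"max"`, `"mean"`, `"variance"`.
#' @return A `series` [md_value()] with one value per frame.  The variance is
#'   the population variance (denominator `n`), zero for a single member.
#' @export
aggregate_population <- function(value, mode = c("mean", "min", "max", "variance")) {
  mode <- match.arg(mode)
  if (!inherits(value, "md_value") || value$kind != "population_series") {
    stop("aggregate_population() requires a population_series value")
  }
  m <- value$payload
  if (ncol(m) == 0L) stop("cannot aggregate an empty population")
  agg <- switch(mode,
    mean = rowMeans(m),
    min = apply(m, 1L, min),
    max = apply(m, 1L, max),
    variance = rowMeans(m * m) - rowMeans(m)^2
  )
  md_value("series", matrix(agg, ncol = 1L), unit = value$unit,
           times = value$times)
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their minimum-image distance does not exceed
#' `bond_scale * (r_cov(a) + r_cov(b))` using standard covalent radii; bonds
#' involving hydrogen must additionally be shorter than the hydrogen cap
#' (see [bond_config()]).
#'
#' @param topology A [topology()] with all elements assigned.
#' @param frame The [md_frame()] supplying coordinates and cell.
#' @return Two-column integer matrix of 0-based bonded pairs.
#' @export
infer_bonds <- function(topology, frame) {
  el <- topology$elements
  unknown <- which(is.na(el) | !is_known_element(el))
  if (length(unknown)) {
    stop(sprintf("cannot infer bonds: atom %d (label '%s') has unknown element",
                 unknown[1L], topology$atom_labels[unknown[1L]]))
  }
  n <- n_atoms(topology)
  rc <- covalent_radius(el)
  cfg <- bond_config()
  coords <- frame$coordinates
  max_reach <- cfg$bond_scale * 2 * max(rc)
  pairs <- candidate_pairs(coords, frame$cell, max_reach)
  if (nrow(pairs) == 0L) return(normalize_bonds(NULL, n))
  i <- pairs[, 1L]; j <- pairs[, 2L]
  d <- minimum_image_distance(coords[i + 1L, , drop = FALSE],
                              coords[j + 1L, , drop = FALSE], frame$cell)
  cut <- cfg$bond_scale * (rc[i + 1L] + rc[j + 1L])
  has_h <- el[i + 1L] == "H" | el[j + 1L] == "H"
  cut[has_h] <- pmin(cut[has_h], cfg$hydrogen_cap)
  keep <- d <= cut & d > 1e-6
  normalize_bonds(pairs[keep, , drop = FALSE], n)
}

# Candidate pairs within `cutoff` via a periodic cell-list grid; falls back
# to all pairs for small systems where the grid buys nothing.
candidate_pairs <- function(coords, cell, cutoff) {
  n <- nrow(coords)
  if (n <= 400L) {
    if (n < 2L) return(matrix(integer(0), ncol = 2L))
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(cbind(idx[, "row"] - 1L, idx[, "col"] - 1L))
  }
  cell_list_pairs(coords, cell, cutoff)
}

cell_list_pairs <- function(coords, cell, cutoff) {
  n <- nrow(coords)
  L <- cell$lengths
  per <- cell$periodic
  # non-periodic axes: span the bounding box
  lo <- ifelse(per, 0, apply(coords, 2L, min) - 1e-9)
  span <- ifelse(per, L, apply(coords, 2L, max) - lo + 1e-6)
  nb <- pmax(1L, floor(span / cutoff))
  wrapped <- sweep(coords, 2L, lo)
  for (ax in 1:3) if (per[ax]) wrapped[, ax] <- wrapped[, ax] %% L[ax]
  bin <- sapply(1:3, function(ax) {
    pmin(nb[ax] - 1L, pmax(0L, as.integer(floor(wrapped[, ax] / span[ax] * nb[ax]))))
  })
  key <- bin[, 1L] + nb[1L] * (bin[, 2L] + nb[2L] * bin[, 3L])
  buckets <- split(seq_len(n) - 1L, key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0)
  bin_of <- function(k) c(k %% nb[1L], (k %/% nb[1L]) %% nb[2L], k %/% (nb[1L] * nb[2L]))
  keys <- as.numeric(names(buckets))
  keymap <- new.env(hash = TRUE)
  for (nm in names(buckets)) assign(nm, buckets[[nm]], envir = keymap)
  for (bi in seq_along(buckets)) {
    b <- bin_of(keys[bi])
    mine <- buckets[[bi]]
    for (o in seq_len(nrow(offsets))) {
      nbin <- b + offsets[o, ]
      for (ax in 1:3) {
        if (per[ax]) nbin[ax] <- nbin[ax] %% nb[ax]
      }
      if (any(nbin < 0) || any(nbin >= nb)) next
      nkey <- as.character(nbin[1L] + nb[1L] * (nbin[2L] + nb[2L] * nbin[3L]))
      other <- if (exists(nkey, envir = keymap, inherits = FALSE)) {
        get(nkey, envir = keymap)
      } else next
      g <- expand.grid(i = mine, j = other)
      g <- g[g$i < g$j, , drop = FALSE]
      out_i <- c(out_i, g$i); out_j <- c(out_j, g$j)
    }
  }
  unique(cbind(out_i, out_j))
}

#' Connected covalent structures of a topology
#'
#' Atoms connected by covalent bonds belong to the same structure; the
#' connected components of the bond graph define the structures used by
#' deperiodization.  Contexts are ordered by their lowest atom index.
#'
#' @param topology A [topology()] with bonds present (file-derived or from
#'   [infer_bonds()]).
#' @return An `md_selection` whose contexts partition all atoms.
#' @export
connected_structures <- function(topology) {
  n <- n_atoms(topology)
  comp <- bond_components(topology$bonds, n)
  groups <- split(seq_len(n) - 1L, comp)
  ord <- order(vapply(groups, min, integer(1)))
  context_selection(groups[ord], source = "connected_structures",
                    n_atoms = n)
}

# Union-find over the bond list; returns a component id per atom (1-based in).
bond_components <- function(bonds, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- find(bonds[k, 1L] + 1L)
      b <- find(bonds[k, 2L] + 1L)
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Adjacency list (1-based) from the bond matrix.
bond_adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    i <- bonds[, 1L] + 1L
    j <- bonds[, 2L] + 1L
    for (k in seq_along(i)) {
      adj[[i[k]]] <- c(adj[[i[k]]], j[k])
      adj[[j[k]]] <- c(adj[[j[k]]], i[k])
    }
  }
  adj
}

#' Property table of an evaluated script
#'
#' @param entries Named list of promoted [md_value()]s, in declaration order.
#' @return An object of class `"md_property_table"`.
#' @export
property_table <- function(entries = list()) {
  if (length(entries) && anyDuplicated(names(entries))) {
    stop("property names must be unique")
  }
  structure(list(entries = entries), class = "md_property_table")
}

#' @export
print.md_property_table <- function(x, ...) {
  cat(sprintf("<md_property_table> %d propert%s\n", length(x$entries),
              if (length(x$entries) == 1L) "y" else "ies"))
  for (nm in names(x$entries)) {
    v <- x$entries[[nm]]
    cat(sprintf("  %-12s %s (length %d)\n", nm, v$kind, v$length))
  }
  invisible(x)
}
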