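# Frame-loop evaluators for distribution and volume properties: histograms
# with conservative power-of-two down-sampling, radial distribution
# functions, and spatial distribution functions.

#' Construct a histogram
#'
#' Histograms back the 1D distribution properties: high-resolution uniform
#' bins accumulated in memory, down-sampled only for display.
#'
#' @param counts Numeric vector of accumulated (non-negative) weights.
#' @param range Length-2 numeric `[min, max]` of the binned variable.
#' @param members Optional matrix (bins x members) of per-member counts for
#'   population distributions.
#' @return An object of class `"md_histogram"` with `edges`, `counts`,
#'   `resolution`, `range`.
#' @export
histogram <- function(counts, range, members = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < -1e-12)) stop("histogram counts must be non-negative")
  if (range[2L] < range[1L]) stop("invalid histogram range")
  structure(list(edges = seq(range[1L], range[2L], length.out = length(counts) + 1L),
                 counts = counts,
                 resolution = length(counts),
                 range = as.numeric(range),
                 members = members),
            class = "md_histogram")
}

#' @export
print.md_histogram <- function(x, ...) {
  cat(sprintf("<md_histogram> %d bins on [%g, %g], total mass %g\n",
              x$resolution, x$range[1L], x$range[2L], sum(x$counts)))
  invisible(x)
}

#' Build a high-resolution histogram from a series value
#'
#' Population series pool all members into the main counts; per-member
#' histograms are retained so populations can be shown individually or as an
#' aggregate.
#'
#' @param value A series or population-series [md_value()], or a bare
#'   numeric vector.
#' @param resolution Bin count; a power of two (default 1024).
#' @param range Optional fixed `[min, max]`; defaults to the observed range
#'   (widened infinitesimally for constant data).
#' @return An `md_histogram`.
#' @export
histogram_build <- function(value, resolution = 1024L, range = NULL) {
  if (inherits(value, "md_value")) {
    m <- value$payload
  } else {
    m <- matrix(as.numeric(value), ncol = 1L)
  }
  if (!is_power_of_two(resolution)) stop("resolution must be a power of 2")
  if (!length(m) || !nrow(m)) stop("cannot histogram an empty series")
  if (is.null(range)) {
    range <- base::range(m)
    if (range[1L] == range[2L]) range <- range + c(-0.5, 0.5)
  }
  nb <- as.integer(resolution)
  members <- vapply(seq_len(ncol(m)), function(k) {
    bin_counts(m[, k], nb, range)
  }, numeric(nb))
  members <- matrix(members, nrow = nb)
  histogram(rowSums(members), range,
            members = if (ncol(m) > 1L) members else NULL)
}

bin_counts <- function(x, nb, range) {
  span <- range[2L] - range[1L]
  idx <- floor((x - range[1L]) / span * nb) + 1L
  idx[x == range[2L]] <- nb           # right edge closed
  idx <- idx[idx >= 1L & idx <= nb]
  tabulate(idx, nbins = nb)
}

is_power_of_two <- function(k) {
  k <- as.integer(k)
  k >= 1L && bitwAnd(k, k - 1L) == 0L
}

#' Conservatively down-sample a histogram
#'
#' Adjacent bins are summed, so total mass is preserved exactly and the
#' range is unchanged; composing two factor-2 down-samplings equals one
#' factor-4 down-sampling.
#'
#' @param hist An `md_histogram`.
#' @param factor Power-of-two reduction factor dividing the resolution.
#' @return An `md_histogram` with `resolution / factor` bins.
#' @export
histogram_downsample <- function(hist, factor) {
  if (!is_power_of_two(factor)) stop("down-sampling factor must be a power of 2")
  factor <- as.integer(factor)
  if (factor == 1L) return(hist)
  if (hist$resolution %% factor != 0L) stop("factor must divide the resolution")
  grp <- rep(seq_len(hist$resolution %/% factor), each = factor)
  counts <- as.numeric(rowsum(hist$counts, grp))
  members <- if (!is.null(hist$members)) {
    rowsum(hist$members, grp)
  } else NULL
  histogram(counts, hist$range, members = members)
}

#' Radial distribution function between two selections
#'
#' Pair distances use the minimum-image convention; self-pairs (the same
#' atom appearing in both selections) are excluded.  Per frame, shell counts
#' are normalized by `N_a * rho_b * V_shell` with `rho_b = N_b / V` and the
#' exact spherical-shell volume, then averaged over frames, so an ideal gas
#' yields `g(r) = 1`.
#'
#' @param traj An [md_trajectory()].
#' @param sel_a,sel_b `md_selection`s (flattened internally).
#' @param cutoff Maximum distance (Angstrom); at most half the shortest
#'   periodic box edge.
#' @param bins Number of bins (power of two, default 128).
#' @param frame_range Optional integer vector of 1-based frame indices to
#'   accumulate over (temporal filtering); default all frames.
#' @param workers Number of workers to partition the frame loop across.
#'   Per-frame contributions are folded in ascending frame order, so the
#'   result is bitwise identical for any worker count.
#' @return An `md_histogram` whose counts hold g(r).
#' @export
rdf <- function(traj, sel_a, sel_b, cutoff, bins = 128L, frame_range = NULL,
                workers = 1L) {
  a <- selection_atoms(sel_a)
  b <- selection_atoms(sel_b)
  if (!length(a) || !length(b)) stop("rdf requires non-empty selections")
  frames <- resolve_frame_range(traj, frame_range)
  cell0 <- traj$frames[[frames[1L]]]$cell
  if (any(cell0$periodic)) {
    lim <- min(cell0$lengths[cell0$periodic]) / 2
    if (cutoff > lim + 1e-9) {
      stop(sprintf("cutoff %.3f exceeds half the shortest box edge (%.3f)",
                   cutoff, lim))
    }
  }
  nb <- as.integer(bins)
  edges <- seq(0, cutoff, length.out = nb + 1L)
  shell_vol <- 4 / 3 * pi * (edges[-1L]^3 - edges[-(nb + 1L)]^3)
  contribs <- frame_map(frames, workers, function(fi) {
    rdf_frame_contribution(traj$frames[[fi]], a, b, nb, cutoff, shell_vol)
  })
  acc <- numeric(nb)
  for (v in contribs) acc <- acc + v     # fixed fold order: frame index
  histogram(acc / length(frames), c(0, cutoff))
}

rdf_frame_contribution <- function(fr, a, b, nb, cutoff, shell_vol) {
  V <- if (all(fr$cell$periodic)) {
    prod(fr$cell$lengths)
  } else {
    # aperiodic axes carry no well-defined density; use the bounding box
    ext <- apply(fr$coordinates, 2L, function(v) diff(range(v)))
    prod(ifelse(fr$cell$periodic, fr$cell$lengths, pmax(ext, 1e-6)))
  }
  rho_b <- length(b) / V
  pa <- fr$coordinates[a + 1L, , drop = FALSE]
  pb <- fr$coordinates[b + 1L, , drop = FALSE]
  cnt <- numeric(nb)
  for (k in seq_along(a)) {
    d <- minimum_image_distance(
      matrix(pa[k, ], nrow = length(b), ncol = 3L, byrow = TRUE),
      pb, fr$cell)
    same <- b == a[k]
    if (any(same)) d <- d[!same]
    d <- d[d <= cutoff & d > 1e-9]
    if (length(d)) {
      idx <- pmin(nb, floor(d / cutoff * nb) + 1L)
      cnt <- cnt + tabulate(idx, nbins = nb)
    }
  }
  cnt / (length(a) * rho_b * shell_vol)
}

# Apply `fn` to every frame index, optionally partitioned into contiguous
# chunks across forked workers; results are returned in frame order
# regardless of the partition.
frame_map <- function(frames, workers, fn) {
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || length(frames) < 2L ||
      .Platform$OS.type == "windows") {
    return(lapply(frames, fn))
  }
  chunks <- split(frames, ceiling(seq_along(frames) / ceiling(length(frames) / workers)))
  parts <- parallel::mclapply(chunks, function(ch) lapply(ch, fn),
                              mc.cores = workers)
  do.call(c, unname(parts))
}

resolve_frame_range <- function(traj, frame_range) {
  if (is.null(frame_range)) return(seq_len(n_frames(traj)))
  frame_range <- as.integer(frame_range)
  if (!length(frame_range)) stop("empty frame range")
  if (any(frame_range < 1L) || any(frame_range > n_frames(traj))) {
    stop("frame range outside trajectory")
  }
  sort(unique(frame_range))
}

#' Construct a volume grid
#'
#' @param dims Integer length-3 voxel counts.
#' @param origin Length-3 grid origin (Angstrom; corner of voxel `[1,1,1]`).
#' @param axes 3 x 3 matrix of voxel step vectors (rows; Angstrom).
#' @param densities Optional `dims` array of accumulated weights (zeros when
#'   omitted).
#' @param metadata Optional reference-structure metadata (see [sdf()]).
#' @return An object of class `"md_volume"`.
#' @export
volume_grid <- function(dims, origin, axes, densities = NULL, metadata = NULL) {
  dims <- as.integer(dims)
  if (any(dims < 1L)) stop("volume dims must be >= 1")
  if (is.null(densities)) densities <- array(0, dim = dims)
  if (any(densities < -1e-12)) stop("volume densities must be non-negative")
  structure(list(dims = dims, origin = as.numeric(origin),
                 axes = as.matrix(axes), densities = densities,
                 metadata = metadata),
            class = "md_volume")
}

#' @export
print.md_volume <- function(x, ...) {
  cat(sprintf("<md_volume> %dx%dx%d, total mass %g\n",
              x$dims[1L], x$dims[2L], x$dims[3L], sum(x$densities)))
  invisible(x)
}

#' Spatial distribution function
#'
#' Accumulates the spatial occurrence of target atoms in a local frame
#' defined by the reference contexts.  The canonical reference is the first
#' context's geometry in the first evaluated frame, centered on its center
#' of mass.  For every frame and reference context, the context is
#' Kabsch-superposed onto the canonical reference and the same rigid
#' transform is applied to the target positions (taken minimum-image
#' relative to the context's center of mass); positions within the cubic
#' extent are deposited into the nearest voxel, so total deposited mass
#' equals the number of in-range (frame, context, target-atom) triples.
#'
#' @param traj An [md_trajectory()].
#' @param reference An `md_selection`; every context needs at least three
#'   non-collinear atoms.
#' @param target An `md_selection` (flattened).
#' @param extent Half-width of the cubic grid (Angstrom).
#' @param dims Voxels per axis (default 32).
#' @param frame_range Optional 1-based frame indices (temporal filtering).
#' @param workers Worker count for the frame loop; deposits are unit counts,
#'   so accumulation is exact and partition-independent.
#' @return An `md_volume`; `metadata` holds the canonical reference
#'   structure (`coordinates`, `elements`) and per-context deposit counts.
#' @export
sdf <- function(traj, reference, target, extent, dims = 32L,
                frame_range = NULL, workers = 1L) {
  if (extent <= 0) stop("sdf extent must be positive")
  frames <- resolve_frame_range(traj, frame_range)
  ctxs <- reference$contexts
  if (!length(ctxs)) stop("sdf requires at least one reference context")
  top <- traj$topology
  tgt <- selection_atoms(target)
  small <- which(lengths(ctxs) < 3L)
  if (length(small)) {
    stop(sprintf("context %d: reference needs >= 3 atoms", small[1L]))
  }
  dims <- rep(as.integer(dims), length.out = 3L)
  step <- 2 * extent / dims
  f0 <- traj$frames[[frames[1L]]]
  ref_atoms <- ctxs[[1L]]
  ref_mass <- top$masses[ref_atoms + 1L]
  if (any(!is.finite(ref_mass)) || any(ref_mass <= 0)) {
    ref_mass <- rep(1, length(ref_atoms))
  }
  canon <- f0$coordinates[ref_atoms + 1L, , drop = FALSE]
  canon <- sweep(canon, 2L, colSums(canon * ref_mass) / sum(ref_mass))
  check_reference_geometry(canon, frames[1L], 1L)
  frame_accumulate <- function(fi) {
    dens <- array(0, dim = dims)
    per_context <- numeric(length(ctxs))
    fr <- traj$frames[[fi]]
    for (ci in seq_along(ctxs)) {
      ctx <- ctxs[[ci]]
      if (length(ctx) < 3L) {
        stop(sprintf("frame %d, context %d: reference needs >= 3 atoms", fi, ci))
      }
      if (length(ctx) != length(ref_atoms)) {
        stop(sprintf("context %d: atom count differs from canonical reference", ci))
      }
      w <- top$masses[ctx + 1L]
      if (any(!is.finite(w)) || any(w <= 0)) w <- rep(1, length(ctx))
      pts <- fr$coordinates[ctx + 1L, , drop = FALSE]
      com <- colSums(pts * w) / sum(w)
      local_ref <- sweep(pts, 2L, com)
      check_reference_geometry(local_ref, fi, ci)
      fit <- kabsch_superpose(local_ref, canon, w)
      if (length(tgt)) {
        delta <- sweep(fr$coordinates[tgt + 1L, , drop = FALSE], 2L, com)
        delta <- minimum_image(delta, fr$cell)
        local <- delta %*% t(fit$rotation)
        vox <- floor((local + extent) / step) + 1L
        ok <- vox[, 1L] >= 1L & vox[, 1L] <= dims[1L] &
              vox[, 2L] >= 1L & vox[, 2L] <= dims[2L] &
              vox[, 3L] >= 1L & vox[, 3L] <= dims[3L]
        if (any(ok)) {
          v <- vox[ok, , drop = FALSE]
          for (r in seq_len(nrow(v))) {
            dens[v[r, 1L], v[r, 2L], v[r, 3L]] <-
              dens[v[r, 1L], v[r, 2L], v[r, 3L]] + 1
          }
          per_context[ci] <- per_context[ci] + sum(ok)
        }
      }
    }
    list(dens = dens, per_context = per_context)
  }
  parts <- frame_map(frames, workers, frame_accumulate)
  dens <- array(0, dim = dims)
  per_context <- numeric(length(ctxs))
  for (p in parts) {
    dens <- dens + p$dens
    per_context <- per_context + p$per_context
  }
  axes <- diag(step)
  volume_grid(dims, origin = rep(-extent, 3L), axes = axes,
              densities = dens,
              metadata = list(
                coordinates = canon,
                elements = top$elements[ref_atoms + 1L],
                per_context_mass = per_context))
}

check_reference_geometry <- function(centered, frame_i, ctx_i) {
  s <- svd(centered)$d
  if (length(s) < 2L || s[2L] < 1e-8) {
    stop(sprintf("frame %d, context %d: degenerate (collinear) reference geometry",
                 frame_i, ctx_i))
  }
}
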