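# Ramachandran analysis: backbone phi/psi extraction, the four-class residue
# partition (general, glycine, proline, pre-proline), periodic
# Gaussian-smoothed densities and percentile-matched contour levels.

#' Default Ramachandran contour percentiles per residue class
#'
#' The stricter and looser contour percentiles follow the common-practice
#' convention for reference Ramachandran distributions: 99.95% and 98% for
#' the general class, 99.5% and 98% for glycine, proline and pre-proline.
#'
#' @param class One of `"general"`, `"glycine"`, `"proline"`,
#'   `"preproline"`.
#' @return Numeric length-2 vector `c(stricter, looser)` of percentiles.
#' @export
rama_default_percentiles <- function(class = c("general", "glycine",
                                               "proline", "preproline")) {
  class <- match.arg(class)
  if (class == "general") c(99.95, 98) else c(99.5, 98)
}

#' Classify protein residues into Ramachandran classes
#'
#' GLY residues are glycine, PRO residues proline; any other residue
#' immediately preceding a proline in the same chain is pre-proline (a
#' residue's own GLY/PRO identity wins over the pre-proline rule); all
#' remaining protein residues are general.  Non-protein residues are not
#' classified.
#'
#' @param topology A [topology()].
#' @return Data frame with one row per protein residue: `index` (residue
#'   index), `resid`, `resname`, `chain`, `class`.
#' @export
classify_residues <- function(topology) {
  rt <- residue_table(topology)
  rt <- rt[is_amino_acid(rt$resname), , drop = FALSE]
  if (!nrow(rt)) {
    return(data.frame(index = integer(0), resid = integer(0),
                      resname = character(0), chain = character(0),
                      class = character(0)))
  }
  cls <- rep("general", nrow(rt))
  up <- toupper(rt$resname)
  cls[up == "GLY"] <- "glycine"
  cls[up == "PRO"] <- "proline"
  for (k in seq_len(nrow(rt) - 1L)) {
    nxt <- k + 1L
    if (up[nxt] == "PRO" && rt$chain[k] == rt$chain[nxt] &&
        rt$index[nxt] == rt$index[k] + 1L && cls[k] == "general") {
      cls[k] <- "preproline"
    }
  }
  data.frame(index = rt$index, resid = rt$resid, resname = rt$resname,
             chain = rt$chain, class = cls, stringsAsFactors = FALSE)
}

#' Backbone phi/psi dihedral angles for one frame
#'
#' `phi(i) = dihedral(C(i-1), N(i), CA(i), C(i))` and
#' `psi(i) = dihedral(N(i), CA(i), C(i), N(i+1))`, in degrees.  Chain
#' terminals lacking a neighbour are omitted; residues missing a named
#' backbone atom (N, CA, C) are skipped with a warning.
#'
#' @param traj An [md_trajectory()].
#' @param frame 1-based frame index.
#' @return Data frame with `index`, `resid`, `resname`, `chain`, `class`,
#'   `phi`, `psi` for every interior residue with a complete backbone.
#' @export
backbone_dihedrals <- function(traj, frame = 1L) {
  top <- traj$topology
  fr <- traj$frames[[frame]]
  cls <- classify_residues(top)
  if (!nrow(cls)) {
    return(cbind(cls, phi = numeric(0), psi = numeric(0)))
  }
  ridx <- residue_index(top)
  atom_of <- function(res_index, name) {
    hit <- which(ridx == res_index & toupper(top$atom_labels) == name)
    if (length(hit)) hit[1L] else NA_integer_
  }
  bb <- lapply(cls$index, function(ri) {
    c(N = atom_of(ri, "N"), CA = atom_of(ri, "CA"), C = atom_of(ri, "C"))
  })
  incomplete <- vapply(bb, function(x) any(is.na(x)), logical(1))
  if (any(incomplete)) {
    warning(sprintf("%d residue(s) skipped: missing backbone atoms",
                    sum(incomplete)))
  }
  out <- list()
  xyz <- fr$coordinates
  for (k in seq_len(nrow(cls))) {
    if (incomplete[k]) next
    prev <- if (k > 1L && cls$chain[k - 1L] == cls$chain[k] &&
                cls$index[k - 1L] == cls$index[k] - 1L && !incomplete[k - 1L]) k - 1L else NA
    nxt <- if (k < nrow(cls) && cls$chain[k + 1L] == cls$chain[k] &&
               cls$index[k + 1L] == cls$index[k] + 1L && !incomplete[k + 1L]) k + 1L else NA
    if (is.na(prev) || is.na(nxt)) next
    phi <- calc_dihedral(xyz[bb[[prev]]["C"], ], xyz[bb[[k]]["N"], ],
                         xyz[bb[[k]]["CA"], ], xyz[bb[[k]]["C"], ])
    psi <- calc_dihedral(xyz[bb[[k]]["N"], ], xyz[bb[[k]]["CA"], ],
                         xyz[bb[[k]]["C"], ], xyz[bb[[nxt]]["N"], ])
    out[[length(out) + 1L]] <- cbind(cls[k, , drop = FALSE],
                                     phi = phi, psi = psi)
  }
  if (!length(out)) {
    return(cbind(cls[0, , drop = FALSE], phi = numeric(0), psi = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Periodic Gaussian-smoothed Ramachandran density
#'
#' Builds a histogram of (phi, psi) points on a periodic grid over
#' `[-180, 180)^2` and convolves it with a separable Gaussian kernel with
#' periodic wrap on both axes.  All points are weighted equally and the
#' result is normalized to total mass one.
#'
#' @param phi,psi Numeric vectors of angles in degrees.
#' @param grid_size Cells per axis (default 180, i.e. 2 degree cells;
#'   minimum 8).
#' @param sigma Kernel standard deviation in degrees (default 6).
#' @return An object of class `"md_rama_density"` with `grid` (a
#'   `grid_size x grid_size` matrix, phi rows x psi columns), `sigma`,
#'   `grid_size`, and empty `levels`.
#' @export
rama_density <- function(phi, psi, grid_size = 180L, sigma = 6) {
  if (!length(phi) || length(phi) != length(psi)) {
    stop("rama_density requires matching non-empty phi/psi vectors")
  }
  grid_size <- as.integer(grid_size)
  if (grid_size < 8L) stop("grid size must be >= 8")
  if (sigma <= 0) stop("sigma must be positive")
  h <- rama_histogram(phi, psi, grid_size)
  kern <- wrapped_gaussian_kernel(grid_size, sigma)
  sm <- kern %*% h %*% t(kern)    # separable periodic convolution
  sm <- sm / sum(sm)
  structure(list(grid = sm, sigma = sigma, grid_size = grid_size,
                 levels = list()),
            class = "md_rama_density")
}

# Raw 2D histogram on the periodic angle grid; cell width 360/grid_size,
# first cell starts at -180.
rama_histogram <- function(phi, psi, grid_size) {
  w <- 360 / grid_size
  ip <- (floor((phi + 180) / w) %% grid_size) + 1L
  is_ <- (floor((psi + 180) / w) %% grid_size) + 1L
  h <- matrix(0, grid_size, grid_size)
  for (k in seq_along(ip)) h[ip[k], is_[k]] <- h[ip[k], is_[k]] + 1
  h
}

# Circulant convolution matrix of a periodic Gaussian on grid_size cells.
# Row i, column j holds the wrapped kernel weight for offset (i - j); the
# full wrapped kernel is used so the operation is an exact circular
# convolution, equal to direct 2D convolution by separability.
wrapped_gaussian_kernel <- function(grid_size, sigma_degrees) {
  w <- 360 / grid_size
  sigma_cells <- sigma_degrees / w
  off <- outer(seq_len(grid_size), seq_len(grid_size), `-`)
  off <- ((off + grid_size %/% 2) %% grid_size) - grid_size %/% 2
  k <- exp(-off^2 / (2 * sigma_cells^2))
  # normalize rows so smoothing conserves mass
  k / rowSums(k)[1L]
}

#' Percentile-matched contour levels of a density
#'
#' For a percentile `p`, returns the largest density threshold `t` such that
#' the total mass of cells with density `>= t` is at least `p / 100`.
#' Default percentiles per residue class come from
#' [rama_default_percentiles()].
#'
#' @param density An `md_rama_density` (or any non-negative numeric array
#'   normalized to total mass 1).
#' @param percentiles Numeric vector of percentiles in `(0, 100]`.
#' @return Named numeric vector of thresholds (names are the percentiles);
#'   thresholds decrease as percentiles increase.
#' @export
rama_contour_levels <- function(density, percentiles) {
  g <- if (inherits(density, "md_rama_density")) density$grid else density
  if (any(percentiles <= 0) || any(percentiles > 100)) {
    stop("percentiles must lie in (0, 100]")
  }
  v <- sort(as.numeric(g), decreasing = TRUE)
  cum <- cumsum(v)
  total <- cum[length(cum)]
  out <- vapply(percentiles, function(p) {
    k <- which(cum >= p / 100 * total)[1L]
    v[k]
  }, numeric(1))
  names(out) <- as.character(percentiles)
  out
}

#' Mass enclosed at or above a density threshold
#'
#' @param density An `md_rama_density` or numeric array.
#' @param threshold Density threshold.
#' @return Fraction of total mass in cells with density `>= threshold`.
#' @export
rama_enclosed_mass <- function(density, threshold) {
  g <- if (inherits(density, "md_rama_density")) density$grid else density
  sum(g[g >= threshold]) / sum(g)
}

#' Layered Ramachandran densities with comparable contours
#'
#' Combines the full-trajectory layer, an optional temporally filtered
#' layer, and an optional reference density.  When a reference is present,
#' every layer's contour thresholds are computed at the reference's
#' percentiles so iso-lines are A-to-B comparable; each layer keeps its own
#' mass normalization.
#'
#' @param full `md_rama_density` over the full trajectory.
#' @param filtered Optional `md_rama_density` over the filtered frame range.
#' @param reference Optional reference `md_rama_density`.
#' @param percentiles Percentiles for the contours (default the general
#'   class pair).
#' @return List of layers; each has `density` and `levels`.
#' @export
rama_compare_layers <- function(full, filtered = NULL, reference = NULL,
                                percentiles = rama_default_percentiles("general")) {
  layers <- list(full = full)
  if (!is.null(filtered)) layers$filtered <- filtered
  if (!is.null(reference)) layers$reference <- reference
  gs <- vapply(layers, function(l) l$grid_size, integer(1))
  if (length(unique(gs)) != 1L) stop("layer grid sizes do not match")
  lapply(layers, function(l) {
    list(density = l, levels = rama_contour_levels(l, percentiles))
  })
}

#' Read and write Ramachandran densities as csv grids
#'
#' Row-major csv with a metadata header comment carrying grid size and
#' sigma, used to exchange reference distributions.
#'
#' @param density An `md_rama_density`.
#' @param path File path.
#' @return `write_rama_density()` returns the path invisibly;
#'   `read_rama_density()` an `md_rama_density`.
#' @export
write_rama_density <- function(density, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid_size=%d sigma=%g", density$grid_size,
                     density$sigma), con)
  utils::write.table(format(density$grid, digits = 17),
                     con, row.names = FALSE, col.names = FALSE,
                     sep = ",", quote = FALSE)
  invisible(path)
}

#' @rdname write_rama_density
#' @export
read_rama_density <- function(path) {
  lines <- read_nonempty_file(path)
  hdr <- lines[1L]
  gs <- as.integer(sub(".*grid_size=([0-9]+).*", "\\1", hdr))
  sg <- as.numeric(sub(".*sigma=([-0-9.eE+]+).*", "\\1", hdr))
  m <- as.matrix(utils::read.csv(text = paste(lines[-1L], collapse = "\n"),
                                 header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != gs || ncol(m) != gs) stop("density grid does not match header")
  structure(list(grid = m / sum(m), sigma = sg, grid_size = gs,
                 levels = list()),
            class = "md_rama_density")
}
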