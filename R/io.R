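# File input/output: PDB/GRO topologies, PDB/GRO/XYZ trajectories, csv/xvg
# tabular property exchange, and Gaussian cube volume export.
#
# Conventions: coordinates are stored in Angstrom (GRO nm input converted on
# read); only orthorhombic cells are supported and triclinic input raises an
# explicit unsupported-format error; cube files are written in Bohr by
# default.

BOHR_PER_ANGSTROM <- 1 / 0.52917721092

#' Read a molecular topology from a PDB or GRO file
#'
#' PDB files populate elements from the element column when present; GRO
#' files carry no element data, so elements are left unknown and
#' [infer_elements()] should be applied downstream.
#'
#' @param path Path to a `.pdb` or `.gro` file.
#' @return An [topology()] object (bonds from PDB `CONECT` records when
#'   present, otherwise empty).
#' @export
read_topology <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- read_nonempty_file(path)
  switch(ext,
    pdb = parse_pdb_topology(lines),
    gro = parse_gro_topology(lines),
    stop(sprintf("unrecognized topology extension '.%s' (expected .pdb or .gro)", ext))
  )
}

read_nonempty_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    stop(sprintf("empty file: %s", path))
  }
  lines
}

pdb_field <- function(line, from, to) trimws(substr(line, from, to))

parse_pdb_cell <- function(line, lineno) {
  a <- as.numeric(substr(line, 7, 15))
  b <- as.numeric(substr(line, 16, 24))
  c <- as.numeric(substr(line, 25, 33))
  ang <- c(as.numeric(substr(line, 34, 40)),
           as.numeric(substr(line, 41, 47)),
           as.numeric(substr(line, 48, 54)))
  if (any(is.na(c(a, b, c, ang)))) {
    stop(sprintf("line %d: malformed CRYST1 record", lineno))
  }
  if (any(abs(ang - 90) > 1e-3)) {
    stop("triclinic unit cells are not supported (CRYST1 angles != 90)")
  }
  if (a <= 1 && b <= 1 && c <= 1) return(unit_cell())   # placeholder P1 cell
  unit_cell(c(a, b, c))
}

parse_pdb_atom_line <- function(line, lineno) {
  if (nchar(line) < 54) {
    stop(sprintf("line %d: truncated ATOM/HETATM record", lineno))
  }
  x <- suppressWarnings(as.numeric(substr(line, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(line, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(line, 47, 54)))
  if (any(is.na(c(x, y, z)))) {
    stop(sprintf("line %d: unparsable coordinates in ATOM/HETATM record", lineno))
  }
  resid <- suppressWarnings(as.integer(pdb_field(line, 23, 26)))
  if (is.na(resid)) {
    stop(sprintf("line %d: unparsable residue number", lineno))
  }
  el <- if (nchar(line) >= 77) pdb_field(line, 77, 78) else ""
  list(label = pdb_field(line, 13, 16),
       resname = pdb_field(line, 18, 20),
       chain = if (nzchar(pdb_field(line, 22, 22))) pdb_field(line, 22, 22) else "A",
       resid = resid,
       xyz = c(x, y, z),
       element = if (nzchar(el)) normalize_element_symbol(el) else NA_character_)
}

parse_pdb_topology <- function(lines) {
  cl <- which(startsWith(lines, "CRYST1"))
  if (length(cl)) parse_pdb_cell(lines[cl[1L]], cl[1L])  # rejects triclinic
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  end1 <- which(startsWith(lines, "ENDMDL"))
  last <- if (length(end1)) end1[1L] else length(lines)
  atom_ln <- which(is_atom & seq_along(lines) <= last)
  if (!length(atom_ln)) stop("no ATOM/HETATM records found (zero atoms)")
  recs <- lapply(atom_ln, function(k) parse_pdb_atom_line(lines[k], k))
  serials <- vapply(atom_ln, function(k) {
    suppressWarnings(as.integer(pdb_field(lines[k], 7, 11)))
  }, integer(1))
  bonds <- parse_pdb_conect(lines, serials)
  topology(
    atom_labels = vapply(recs, `[[`, character(1), "label"),
    elements = vapply(recs, `[[`, character(1), "element"),
    residue_ids = vapply(recs, `[[`, integer(1), "resid"),
    residue_names = vapply(recs, `[[`, character(1), "resname"),
    chain_ids = vapply(recs, `[[`, character(1), "chain"),
    bonds = bonds
  )
}

parse_pdb_conect <- function(lines, serials) {
  con_ln <- which(startsWith(lines, "CONECT"))
  if (!length(con_ln)) return(NULL)
  out <- list()
  for (k in con_ln) {
    toks <- as.integer(strsplit(trimws(substr(lines[k], 7, 80)), "\\s+")[[1L]])
    if (length(toks) < 2L) next
    a <- match(toks[1L], serials)
    for (t in toks[-1L]) {
      b <- match(t, serials)
      if (!is.na(a) && !is.na(b) && a != b) {
        out[[length(out) + 1L]] <- c(a - 1L, b - 1L)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

parse_gro_box <- function(line, lineno) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1L]]))
  if (any(is.na(vals)) || !(length(vals) %in% c(3L, 9L))) {
    stop(sprintf("line %d: malformed GRO box line", lineno))
  }
  if (length(vals) == 9L && any(abs(vals[4:9]) > 1e-9)) {
    stop("triclinic unit cells are not supported (GRO off-diagonal box terms)")
  }
  L <- vals[1:3] * 10   # nm -> Angstrom
  if (all(L <= 0)) unit_cell() else unit_cell(L, periodic = L > 0)
}

parse_gro_atom_line <- function(line, lineno) {
  if (nchar(line) < 44) {
    stop(sprintf("line %d: truncated GRO atom record", lineno))
  }
  resid <- suppressWarnings(as.integer(substr(line, 1, 5)))
  xyz <- suppressWarnings(c(as.numeric(substr(line, 21, 28)),
                            as.numeric(substr(line, 29, 36)),
                            as.numeric(substr(line, 37, 44))))
  if (is.na(resid) || any(is.na(xyz))) {
    stop(sprintf("line %d: unparsable GRO atom record", lineno))
  }
  list(resid = resid,
       resname = trimws(substr(line, 6, 10)),
       label = trimws(substr(line, 11, 15)),
       xyz = xyz * 10)   # nm -> Angstrom
}

parse_gro_topology <- function(lines) {
  if (length(lines) < 3L) stop("line 2: missing GRO atom count")
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || n < 1L) stop("line 2: invalid GRO atom count (zero atoms?)")
  if (length(lines) < 2L + n + 1L) stop("GRO file shorter than declared atom count")
  recs <- lapply(seq_len(n), function(k) parse_gro_atom_line(lines[2L + k], 2L + k))
  topology(
    atom_labels = vapply(recs, `[[`, character(1), "label"),
    elements = rep(NA_character_, n),
    residue_ids = vapply(recs, `[[`, integer(1), "resid"),
    residue_names = vapply(recs, `[[`, character(1), "resname"),
    chain_ids = rep("A", n)
  )
}

#' Read a trajectory matching a topology
#'
#' Supports multi-model PDB (`MODEL`/`ENDMDL` blocks), multi-frame GRO
#' (concatenated blocks) and multi-frame XYZ.  Every frame must carry the
#' topology's atom count.
#'
#' @param topology The [topology()] the frames belong to.
#' @param path Path to a `.pdb`, `.gro` or `.xyz` file.
#' @return An [trajectory()] object.  XYZ frames have no unit cell; PDB
#'   frames inherit the file's `CRYST1` cell.
#' @export
read_trajectory <- function(topology, path) {
  ext <- tolower(tools::file_ext(path))
  lines <- read_nonempty_file(path)
  frames <- switch(ext,
    pdb = parse_pdb_frames(lines),
    gro = parse_gro_frames(lines),
    xyz = parse_xyz_frames(lines),
    stop(sprintf("unrecognized trajectory extension '.%s'", ext))
  )
  n <- n_atoms(topology)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$coordinates) != n) {
      stop(sprintf("frame %d: expected %d atoms, got %d",
                   k, n, nrow(frames[[k]]$coordinates)))
    }
  }
  trajectory(topology, frames)
}

parse_pdb_frames <- function(lines) {
  cell <- unit_cell()
  cl <- which(startsWith(lines, "CRYST1"))
  if (length(cl)) cell <- parse_pdb_cell(lines[cl[1L]], cl[1L])
  model_starts <- which(startsWith(lines, "MODEL"))
  frames <- list()
  if (!length(model_starts)) {
    xyz <- pdb_block_coords(lines, seq_along(lines))
    frames[[1L]] <- md_frame(xyz, cell, time = 0)
  } else {
    bounds <- c(model_starts, length(lines) + 1L)
    for (m in seq_along(model_starts)) {
      rng <- (bounds[m] + 1L):(bounds[m + 1L] - 1L)
      xyz <- pdb_block_coords(lines, rng)
      frames[[m]] <- md_frame(xyz, cell, time = m - 1)
    }
  }
  frames
}

pdb_block_coords <- function(lines, rng) {
  sel <- rng[startsWith(lines[rng], "ATOM") | startsWith(lines[rng], "HETATM")]
  if (!length(sel)) stop("model block contains no ATOM/HETATM records")
  t(vapply(sel, function(k) parse_pdb_atom_line(lines[k], k)$xyz, numeric(3)))
}

parse_gro_frames <- function(lines) {
  frames <- list()
  pos <- 1L
  t_index <- 0
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    if (pos + 1L > length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("line %d: invalid GRO atom count", pos + 1L))
    }
    if (pos + 1L + n + 1L > length(lines)) {
      stop(sprintf("frame %d: GRO block truncated", length(frames) + 1L))
    }
    recs <- lapply(seq_len(n), function(k) {
      parse_gro_atom_line(lines[pos + 1L + k], pos + 1L + k)
    })
    cell <- parse_gro_box(lines[pos + 1L + n + 1L], pos + 1L + n + 1L)
    xyz <- t(vapply(recs, `[[`, numeric(3), "xyz"))
    tm <- gro_title_time(lines[pos])
    frames[[length(frames) + 1L]] <- md_frame(xyz, cell,
                                              time = if (is.na(tm)) t_index else tm)
    t_index <- t_index + 1
    pos <- pos + 1L + n + 2L
  }
  if (!length(frames)) stop("no GRO frames found")
  frames
}

gro_title_time <- function(title) {
  m <- regmatches(title, regexpr("t=\\s*([-0-9.eE+]+)", title))
  if (!length(m)) return(NA_real_)
  suppressWarnings(as.numeric(sub("t=\\s*", "", m)))
}

parse_xyz_frames <- function(lines) {
  frames <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("line %d: invalid XYZ atom count", pos))
    }
    if (pos + 1L + n > length(lines)) {
      stop(sprintf("frame %d: XYZ block truncated", length(frames) + 1L))
    }
    xyz <- matrix(0, n, 3L)
    for (k in seq_len(n)) {
      toks <- strsplit(trimws(lines[pos + 1L + k]), "\\s+")[[1L]]
      if (length(toks) < 4L) {
        stop(sprintf("line %d: malformed XYZ atom line", pos + 1L + k))
      }
      xyz[k, ] <- as.numeric(toks[2:4])
    }
    if (any(!is.finite(xyz))) {
      stop(sprintf("frame %d: non-finite XYZ coordinates", length(frames) + 1L))
    }
    frames[[length(frames) + 1L]] <- md_frame(xyz, unit_cell(),
                                              time = length(frames))
    pos <- pos + 2L + n
  }
  if (!length(frames)) stop("no XYZ frames found")
  frames
}

#' Infer element symbols from atom labels
#'
#' Deterministic heuristic used when a format (GRO, element-less PDB) omits
#' elements: strip leading digits, take the leading alphabetic run, then try
#' the case-normalized two-letter symbol followed by the one-letter symbol.
#' Inside amino-acid residues the ambiguous labels CA/CB/CD/CE/CG (and HG)
#' resolve to their carbon/hydrogen reading rather than Ca/Hg, and any label
#' starting with H after digit stripping is hydrogen.  Unresolvable labels
#' are left unknown; the operation is total and idempotent.
#'
#' @param topology A [topology()].
#' @return The topology with unknown elements filled in where possible (and
#'   masses refreshed from the element table for atoms that had none).
#' @export
infer_elements <- function(topology) {
  lab <- topology$atom_labels
  res <- topology$residue_names
  el <- topology$elements
  for (k in seq_along(lab)) {
    if (!is.na(el[k]) && is_known_element(el[k])) next
    el[k] <- infer_one_element(lab[k], res[k])
  }
  out <- topology
  out$elements <- el
  fill <- is.na(out$masses) & !is.na(el)
  out$masses[fill] <- element_mass(el[fill])
  out
}

.aa_carbon_labels <- c("CA", "CB", "CD", "CE", "CG", "CZ", "CH",
                       "CD1", "CD2", "CE1", "CE2", "CE3", "CG1", "CG2",
                       "CZ2", "CZ3", "CH2")

infer_one_element <- function(label, resname) {
  s <- sub("^[0-9]+", "", label)
  alpha <- regmatches(s, regexpr("^[A-Za-z]+", s))
  if (!length(alpha) || !nzchar(alpha)) return(NA_character_)
  alpha <- alpha[[1L]]
  if (is_amino_acid(resname)) {
    # amino-acid naming: CA is an alpha carbon, never calcium; HG a gamma
    # hydrogen, never mercury
    stripped <- toupper(s)
    if (stripped %in% .aa_carbon_labels) return("C")
    if (startsWith(stripped, "H")) return("H")
  }
  if (nchar(alpha) >= 2L) {
    two <- normalize_element_symbol(substr(alpha, 1L, 2L))
    if (!is.na(two)) return(two)
  }
  one <- normalize_element_symbol(substr(alpha, 1L, 1L))
  if (!is.na(one)) return(one)
  NA_character_
}

#' Remap assigned elements by atom label or atom index
#'
#' Overrides applied after inference: a label rule touches every atom with
#' that label, an index rule a single atom.  Later rules win; applying the
#' same remap twice is idempotent.
#'
#' @param topology A [topology()].
#' @param rules List of rules; each rule is `list(label = "CA", element =
#'   "Ca")` or `list(atom = <0-based index>, element = "Ca")`.
#' @return The remapped topology (masses refreshed for remapped atoms).
#' @export
remap_elements <- function(topology, rules) {
  out <- topology
  for (rule in rules) {
    el <- rule$element
    if (is.na(normalize_element_symbol(el))) {
      stop(sprintf("invalid element symbol '%s' in remap rule", el))
    }
    el <- normalize_element_symbol(el)
    if (!is.null(rule$label)) {
      hit <- out$atom_labels == rule$label
      if (!any(hit)) {
        warning(sprintf("remap rule for absent label '%s' matched no atoms", rule$label))
      }
      out$elements[hit] <- el
      out$masses[hit] <- element_mass(el)
    } else if (!is.null(rule$atom)) {
      k <- rule$atom + 1L
      if (k < 1L || k > n_atoms(out)) stop("remap rule atom index out of range")
      out$elements[k] <- el
      out$masses[k] <- element_mass(el)
    } else {
      stop("remap rule must carry 'label' or 'atom'")
    }
  }
  out
}

#' Import tabular temporal data (csv or xvg)
#'
#' CSV requires a header row; XVG (Grace) treats `@`/`#` lines as metadata
#' and takes column names from `@ s<k> legend "..."` entries when present,
#' else `col0..colK`.  Relative paths resolve against `base_dir`.
#'
#' @param path Path to the table.
#' @param filter Optional character vector of column names to retain.
#' @param base_dir Base directory for relative paths (defaults to the
#'   working directory).
#' @return List with `path`, `filter`, and `values` (named list of numeric
#'   columns of equal length).
#' @export
import_table <- function(path, filter = NULL, base_dir = ".") {
  if (!file.exists(path)) {
    cand <- file.path(base_dir, path)
    if (file.exists(cand)) path <- cand
  }
  ext <- tolower(tools::file_ext(path))
  lines <- read_nonempty_file(path)
  tab <- if (ext == "xvg") parse_xvg(lines) else parse_csv_table(lines)
  if (!is.null(filter)) {
    missing <- setdiff(filter, names(tab))
    if (length(missing)) {
      stop(sprintf("column(s) %s not found; available: %s",
                   paste(sQuote(missing), collapse = ", "),
                   paste(names(tab), collapse = ", ")))
    }
    tab <- tab[filter]
  }
  list(path = path, filter = filter, values = tab)
}

parse_csv_table <- function(lines) {
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        check.names = FALSE)
  if (!nrow(df) || !ncol(df)) stop("csv table has no data rows")
  lapply(as.list(df), as.numeric)
}

parse_xvg <- function(lines) {
  meta <- startsWith(trimws(lines), "@") | startsWith(trimws(lines), "#")
  data_lines <- lines[!meta & nzchar(trimws(lines))]
  if (!length(data_lines)) stop("xvg file has no data rows")
  rows <- lapply(data_lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L) stop("xvg rows have inconsistent column counts")
  m <- do.call(rbind, rows)
  legends <- regmatches(lines, regexpr('@\\s*s[0-9]+\\s+legend\\s+".*"', lines))
  names_out <- paste0("col", seq_len(ncols) - 1L)
  for (lg in legends) {
    idx <- as.integer(sub("@\\s*s([0-9]+).*", "\\1", lg))
    nm <- sub('.*legend\\s+"(.*)".*', "\\1", lg)
    # legend s0 names the first data column after the abscissa
    if (idx + 2L <= ncols) names_out[idx + 2L] <- nm
  }
  out <- lapply(seq_len(ncols), function(k) m[, k])
  names(out) <- names_out
  out
}

#' Export temporal properties to csv or xvg
#'
#' Series and population series share a time column; population members
#' expand to one column per member plus the population mean.
#'
#' @param values Named list of series / population-series [md_value()]s.
#' @param path Output path.
#' @param format `"csv"` or `"xvg"`.
#' @return The path, invisibly.
#' @export
export_temporal <- function(values, path, format = c("csv", "xvg")) {
  format <- match.arg(format)
  if (!length(values)) stop("no values to export")
  cols <- list()
  nf <- NULL
  for (nm in names(values)) {
    v <- values[[nm]]
    if (!v$kind %in% c("series", "population_series")) {
      stop(sprintf("property '%s' is not temporal", nm))
    }
    if (is.null(nf)) {
      nf <- nrow(v$payload)
      tm <- if (is.null(v$times)) seq_len(nf) - 1 else v$times
      cols[["time"]] <- tm
    } else if (nrow(v$payload) != nf) {
      stop("temporal properties have mixed frame counts")
    }
    if (v$kind == "series") {
      cols[[nm]] <- v$payload[, 1L]
    } else {
      for (k in seq_len(ncol(v$payload))) {
        cols[[sprintf("%s[%d]", nm, k)]] <- v$payload[, k]
      }
      cols[[sprintf("%s(mean)", nm)]] <- rowMeans(v$payload)
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c('@    title "mdscript temporal export"',
                 '@    xaxis  label "time (ps)"'), con)
    nms <- names(df)[-1L]
    for (k in seq_along(nms)) {
      writeLines(sprintf('@ s%d legend "%s"', k - 1L, nms[k]), con)
    }
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Export a 1D distribution to csv or xvg
#'
#' Writes bin centers and (per-member, where applicable) counts.
#'
#' @param hist A [histogram()].
#' @param path Output path.
#' @param format `"csv"` or `"xvg"`.
#' @return The path, invisibly.
#' @export
export_distribution <- function(hist, path, format = c("csv", "xvg")) {
  format <- match.arg(format)
  centers <- (hist$edges[-1L] + hist$edges[-length(hist$edges)]) / 2
  df <- data.frame(bin_center = centers, count = hist$counts,
                   check.names = FALSE)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c('@    title "mdscript distribution export"',
                 '@ s0 legend "count"'), con)
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export a volume grid as a Gaussian cube file
#'
#' The optional reference structure is written as the molecule block
#' (atomic numbers plus coordinates); origin, axes and atom coordinates are
#' in Bohr by default, or Angstrom with the conventional negative-atom-count
#' signal when `angstrom = TRUE`.  Densities are written x-outer / z-inner.
#'
#' @param volume A [volume_grid()].
#' @param path Output path.
#' @param reference Optional list with `coordinates` (N x 3, Angstrom) and
#'   `elements` (symbols) for the molecule block.
#' @param angstrom Write lengths in Angstrom instead of Bohr.
#' @return The path, invisibly.
#' @export
export_cube <- function(volume, path, reference = NULL, angstrom = FALSE) {
  dims <- volume$dims
  if (any(dims < 1L)) stop("cube export requires a non-empty grid")
  ax <- volume$axes
  if (max(abs(ax[upper.tri(ax)]), abs(ax[lower.tri(ax)])) > 1e-9) {
    stop("cube export requires orthogonal grid axes")
  }
  scale <- if (angstrom) 1 else BOHR_PER_ANGSTROM
  natom_sig <- if (angstrom) -1 else 1
  atoms <- if (is.null(reference)) 0L else nrow(reference$coordinates)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("mdscript volume export",
               "spatial density grid"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", natom_sig * atoms,
                     volume$origin[1] * scale, volume$origin[2] * scale,
                     volume$origin[3] * scale), con)
  for (k in 1:3) {
    step <- ax[k, ] * scale
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", dims[k],
                       step[1], step[2], step[3]), con)
  }
  if (atoms > 0L) {
    z <- atomic_number(reference$elements)
    z[is.na(z)] <- 0L
    for (k in seq_len(atoms)) {
      writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z[k], 0,
                         reference$coordinates[k, 1] * scale,
                         reference$coordinates[k, 2] * scale,
                         reference$coordinates[k, 3] * scale), con)
    }
  }
  # density block: x outer, y middle, z inner, six values per line
  vals <- as.vector(aperm(volume$densities, c(3L, 2L, 1L)))  # z fastest
  chunks <- split(vals, ceiling(seq_along(vals) / 6))
  writeLines(vapply(chunks, function(v) paste(sprintf("%13.5e", v), collapse = " "),
                    character(1)), con)
  invisible(path)
}
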