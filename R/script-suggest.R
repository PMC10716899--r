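# Script suggestions from an active selection, and renderer-agnostic
# visualization payloads for expression nodes.

#' Suggest script snippets for an active selection
#'
#' Operation suggestions are keyed to the selection cardinality (2 atoms ->
#' distance, 3 -> angle, 4 -> dihedral; any size -> com and rmsd).  When all
#' selected atoms share one residue, the contextual variant with indices
#' local to the residue is additionally emitted (`... in resname("XXX")`).
#' Selection suggestions render the set as `atoms(...)`, plus exact
#' `resname(...)` / `resid(...)` forms where the set matches whole residues.
#' Every emitted snippet parses and validates against the topology.
#'
#' @param atoms Integer vector of selected 0-based atom indices.
#' @param topology The loaded [topology()].
#' @return List of suggestions, each `list(category, snippet, description)`;
#'   empty for an empty selection.
#' @export
suggest_snippets <- function(atoms, topology) {
  atoms <- sort(unique(as.integer(atoms)))
  if (!length(atoms)) return(list())
  out <- list()
  add <- function(category, snippet, description) {
    out[[length(out) + 1L]] <<- list(category = category, snippet = snippet,
                                     description = description)
  }
  g <- atoms + 1L      # script-level 1-based indices
  op_name <- switch(as.character(length(atoms)),
                    "2" = "distance", "3" = "angle", "4" = "dihedral", NULL)
  if (!is.null(op_name)) {
    add("operation",
        sprintf("%s(%s)", op_name, paste(g, collapse = ", ")),
        sprintf("%s between the selected atoms", op_name))
    ridx <- residue_index(topology)
    rsel <- unique(ridx[atoms + 1L])
    if (length(rsel) == 1L) {
      # all atoms share one residue: contextual variant with local indices
      res_atoms <- which(ridx == rsel) - 1L
      local <- match(atoms, res_atoms)
      resname <- topology$residue_names[atoms[1L] + 1L]
      add("operation",
          sprintf('%s(%s) in resname("%s")', op_name,
                  paste(local, collapse = ", "), resname),
          sprintf("%s within each %s residue", op_name, resname))
    }
  }
  if (length(atoms) >= 2L) {
    add("operation", sprintf("com(%s)", atoms_snippet(g)),
        "center of mass of the selection")
  }
  if (length(atoms) >= 3L) {
    add("operation", sprintf("rmsd(%s)", atoms_snippet(g)),
        "RMSD of the selection against the first frame")
  }
  add("selection", atoms_snippet(g), "the selected atoms")
  exact <- exact_residue_forms(atoms, topology)
  for (e in exact) add("selection", e$snippet, e$description)
  out
}

# Compact atoms(...) rendering with i..j runs.
atoms_snippet <- function(g) {
  runs <- split(g, cumsum(c(1L, diff(g) != 1L)))
  parts <- vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r) else sprintf("%d..%d", r[1L], r[length(r)])
  }, character(1))
  sprintf("atoms(%s)", paste(parts, collapse = ", "))
}

exact_residue_forms <- function(atoms, topology) {
  ridx <- residue_index(topology)
  rsel <- unique(ridx[atoms + 1L])
  covered <- which(ridx %in% rsel) - 1L
  if (!setequal(covered, atoms)) return(list())
  out <- list()
  rt <- residue_table(topology)
  names_sel <- unique(rt$resname[rt$index %in% rsel])
  if (length(names_sel) == 1L &&
      setequal(rt$index[rt$resname == names_sel], rsel)) {
    out[[length(out) + 1L]] <- list(
      snippet = sprintf('resname("%s")', names_sel),
      description = sprintf("all %s residues", names_sel))
  }
  ids <- sort(rt$resid[rt$index %in% rsel])
  if (!anyDuplicated(rt$resid)) {
    runs <- split(ids, cumsum(c(1L, diff(ids) != 1L)))
    parts <- vapply(runs, function(r) {
      if (length(r) == 1L) as.character(r) else sprintf("%d..%d", r[1L], r[length(r)])
    }, character(1))
    out[[length(out) + 1L]] <- list(
      snippet = sprintf("resid(%s)", paste(parts, collapse = ", ")),
      description = "the selected residues by id")
  }
  out
}

#' Geometry payload for visualizing an expression node
#'
#' Returns a renderer-agnostic record for a statically valid node: the
#' highlighted atom indices plus marker points, connecting lines, and (for
#' angles/dihedrals) wedge descriptors, one set per evaluation context.
#' No drawing is performed.
#'
#' @param node A checked expression node (from [check_script()]).
#' @param traj An [md_trajectory()].
#' @param frame 1-based frame index.
#' @return List with `highlight` (0-based atom indices), `points`,
#'   `lines`, `wedges`.
#' @export
visualization_payload <- function(node, traj, frame = 1L) {
  st <- new.env(parent = emptyenv())
  st$top <- traj$topology
  st$traj <- traj
  st$sel_values <- list()
  st$num_values <- list()
  empty <- list(highlight = integer(0), points = list(), lines = list(),
                wedges = list())
  if (is.null(node$vtype)) stop("node must be statically checked first")
  if (node$vtype$kind == "selection") {
    sel <- eval_selection(node, st)
    return(modifyList(empty, list(highlight = selection_atoms(sel))))
  }
  geom <- collect_geometry_nodes(node)
  if (!length(geom)) return(empty)
  fr <- traj$frames[[frame]]
  payload <- empty
  contexts <- list(NULL)
  if (node$type == "in") {
    contexts <- eval_selection(node$rhs, st)$contexts
  }
  for (gn in geom) {
    for (C in contexts) {
      pts <- lapply(gn$args, function(a) arg_positions(a, frame, st, C)[1L, ])
      base <- length(payload$points)
      payload$points <- c(payload$points, pts)
      for (k in seq_len(length(pts) - 1L)) {
        payload$lines[[length(payload$lines) + 1L]] <-
          c(base + k, base + k + 1L)
      }
      if (gn$name %in% c("angle", "dihedral")) {
        payload$wedges[[length(payload$wedges) + 1L]] <-
          seq.int(base + 1L, base + length(pts))
      }
      atom_args <- Filter(function(a) a$type == "lit_int", gn$args)
      ixs <- vapply(atom_args, function(a) {
        if (is.null(C)) a$value - 1L else C[a$value]
      }, integer(1))
      payload$highlight <- sort(unique(c(payload$highlight, ixs)))
    }
  }
  payload
}

collect_geometry_nodes <- function(nd) {
  out <- list()
  walk <- function(x) {
    if (!is.list(x) || is.null(x$type)) return()
    if (x$type == "call" && x$name %in% c("distance", "angle", "dihedral")) {
      out[[length(out) + 1L]] <<- x
      return()
    }
    for (f in c("lhs", "rhs", "operand", "value")) {
      if (!is.null(x[[f]])) walk(x[[f]])
    }
    if (!is.null(x$args)) for (a in x$args) walk(a)
  }
  walk(nd)
  out
}
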