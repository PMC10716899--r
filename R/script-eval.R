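# Evaluation engine: runs a statically checked script over a trajectory and
# produces the property table.  Selections are topology-only; numeric
# expressions are evaluated per frame; distributions and volumes accumulate
# over the (optionally filtered) frame range with per-frame contributions
# folded in frame order, so results are independent of how frames are
# partitioned across workers.

#' Evaluate an analysis script over a trajectory
#'
#' @param script Script text, a [parse_script()] result, or a
#'   [check_script()] result.
#' @param traj An [md_trajectory()].
#' @param frame_range Optional 1-based frame indices for the temporal filter;
#'   applies to distribution and volume properties only (temporal series are
#'   never truncated by the filter).
#' @param workers Worker count for the frame loops (results are identical
#'   for any value).
#' @param base_dir Base directory for `import()` paths.
#' @return An `md_property_table` of all promoted properties, with a
#'   `variables` attribute holding selection variables.
#' @examples
#' traj <- make_alanine_chain(n_res = 3, n_frames = 2, seed = 1)
#' pt <- evaluate_script('a1 = angle(1, 2, 3) in resname("ALA")', traj)
#' pt$entries$a1$length
#' @export
evaluate_script <- function(script, traj, frame_range = NULL, workers = 1L,
                            base_dir = ".") {
  checked <- resolve_checked_script(script, traj$topology, base_dir)
  st <- new.env(parent = emptyenv())
  st$top <- traj$topology
  st$traj <- traj
  st$base_dir <- base_dir
  st$sel_values <- list()
  st$num_values <- list()
  st$units <- list()
  entries <- list()
  variables <- list()
  for (nd in checked$statements) {
    is_assign <- nd$type == "assign"
    name <- if (is_assign) nd$name else NULL
    expr <- if (is_assign) nd$value else nd
    val <- eval_statement(expr, st, frame_range, workers)
    if (is_assign) {
      if (val$kind == "selection") {
        st$sel_values[[name]] <- val$payload
        variables[[name]] <- val
      } else {
        if (val$kind %in% c("series", "population_series")) {
          st$num_values[[name]] <- val$payload
          st$units[[name]] <- val$unit
        }
        if (is_promotable(val)) entries[[name]] <- val
      }
    }
  }
  pt <- property_table(entries)
  attr(pt, "variables") <- variables
  pt
}

resolve_checked_script <- function(script, topology, base_dir) {
  if (is.character(script)) script <- parse_script(script)
  if (!is.null(script$symbols)) return(assert_clean(script))  # already checked
  assert_clean(check_script(script, topology, base_dir))
}

assert_clean <- function(checked) {
  errs <- Filter(function(d) d$severity == "error", checked$diagnostics)
  if (length(errs)) {
    stop(paste(c("script errors:", format_diagnostics(errs)), collapse = "\n"))
  }
  checked
}

eval_statement <- function(nd, st, frame_range, workers) {
  kind <- nd$vtype$kind
  if (kind == "selection") {
    sel <- eval_selection(nd, st)
    return(md_value("selection", sel))
  }
  if (kind == "distribution") {
    return(eval_distribution(nd, st, frame_range, workers))
  }
  if (kind == "volume") {
    return(eval_volume(nd, st, frame_range, workers))
  }
  if (nd$type == "call" && nd$name == "import") {
    return(eval_import(nd, st))
  }
  if (kind %in% c("int", "float")) {
    return(eval_series(nd, st, workers))
  }
  stop(sprintf("cannot evaluate a value of type '%s' at statement level", kind))
}

eval_import <- function(nd, st) {
  tab <- import_table(nd$args[[1L]]$value, nd$import_filter,
                      base_dir = st$base_dir)
  m <- do.call(cbind, tab$values)
  nf <- n_frames(st$traj)
  if (nrow(m) != nf) {
    stop(sprintf("imported table has %d rows but the trajectory has %d frames",
                 nrow(m), nf))
  }
  md_value(if (ncol(m) > 1L) "population_series" else "series", m,
           times = frame_times(st$traj))
}

eval_series <- function(nd, st, workers) {
  frames <- seq_len(n_frames(st$traj))
  rows <- frame_map(frames, workers, function(fi) {
    as.numeric(eval_frame(nd, fi, st, ctx_atoms = NULL)$v)
  })
  m <- do.call(rbind, rows)
  k <- nd$vtype$length
  if (ncol(m) != k) {
    stop(sprintf("evaluated length %d does not match declared length %d",
                 ncol(m), k))
  }
  md_value(if (k > 1L) "population_series" else "series", m,
           unit = node_unit(nd), times = frame_times(st$traj))
}

node_unit <- function(nd) {
  if (nd$type == "call" && nd$name %in% c("distance", "rmsd")) return("angstrom")
  if (nd$type == "call" && nd$name %in% c("angle", "dihedral")) return("degrees")
  if (nd$type == "in") return(node_unit(nd$lhs))
  ""
}

eval_distribution <- function(nd, st, frame_range, workers) {
  sel_a <- eval_selection(nd$args[[1L]], st)
  sel_b <- eval_selection(nd$args[[2L]], st)
  cutoff <- eval_const(nd$args[[3L]], st)
  h <- rdf(st$traj, sel_a, sel_b, cutoff, frame_range = frame_range,
           workers = workers)
  md_value("distribution", h, unit = "angstrom")
}

eval_volume <- function(nd, st, frame_range, workers) {
  ref <- eval_selection(nd$args[[1L]], st)
  tgt <- eval_selection(nd$args[[2L]], st)
  extent <- eval_const(nd$args[[3L]], st)
  v <- sdf(st$traj, ref, tgt, extent, frame_range = frame_range,
           workers = workers)
  md_value("volume", v, unit = "angstrom")
}

# Constant numeric expressions (literals and arithmetic on them).
eval_const <- function(nd, st) {
  switch(nd$type,
    lit_int = as.numeric(nd$value),
    lit_float = nd$value,
    neg = -eval_const(nd$operand, st),
    binop = {
      a <- eval_const(nd$lhs, st); b <- eval_const(nd$rhs, st)
      switch(nd$op, "+" = a + b, "-" = a - b, "*" = a * b, "/" = a / b)
    },
    stop("expected a constant numeric argument")
  )
}

# ---- selections (topology-only) --------------------------------------------

eval_selection <- function(nd, st, ctx_atoms = NULL) {
  # selections are topology-only, so context-free results are memoized
  if (is.null(ctx_atoms)) {
    key <- format_node(nd)
    if (is.null(st$sel_cache)) st$sel_cache <- new.env(parent = emptyenv())
    if (exists(key, envir = st$sel_cache, inherits = FALSE)) {
      return(get(key, envir = st$sel_cache, inherits = FALSE))
    }
    res <- eval_selection_impl(nd, st, NULL)
    assign(key, res, envir = st$sel_cache)
    return(res)
  }
  eval_selection_impl(nd, st, ctx_atoms)
}

eval_selection_impl <- function(nd, st, ctx_atoms = NULL) {
  top <- st$top
  n <- n_atoms(top)
  src <- format_node(nd)
  switch(nd$type,
    ident = {
      if (nd$name %in% c("protein", "water")) {
        nd$args <- list()
        return(eval_selection_call(nd, st, ctx_atoms, src))
      }
      st$sel_values[[nd$name]]
    },
    and = {
      a <- selection_atoms(eval_selection(nd$lhs, st, ctx_atoms))
      b <- selection_atoms(eval_selection(nd$rhs, st, ctx_atoms))
      context_selection(list(intersect(a, b)), source = src, n_atoms = n)
    },
    or = {
      a <- selection_atoms(eval_selection(nd$lhs, st, ctx_atoms))
      b <- selection_atoms(eval_selection(nd$rhs, st, ctx_atoms))
      context_selection(list(union(a, b)), source = src, n_atoms = n)
    },
    not = {
      a <- selection_atoms(eval_selection(nd$operand, st, ctx_atoms))
      context_selection(list(setdiff(seq_len(n) - 1L, a)), source = src,
                        n_atoms = n)
    },
    `in` = {
      rhs <- eval_selection(nd$rhs, st)
      ctxs <- lapply(rhs$contexts, function(C) {
        s <- eval_selection(nd$lhs, st, ctx_atoms = C)
        intersect(selection_atoms(s), C)
      })
      context_selection(ctxs, source = src, n_atoms = n)
    },
    call = eval_selection_call(nd, st, ctx_atoms, src),
    stop(sprintf("node type '%s' is not a selection", nd$type))
  )
}

eval_selection_call <- function(nd, st, ctx_atoms, src) {
  top <- st$top
  n <- n_atoms(top)
  rt <- residue_table(top)
  ridx <- residue_index(top)
  per_residue <- function(hit) {
    ctxs <- lapply(rt$index[hit], function(ri) which(ridx == ri) - 1L)
    context_selection(ctxs, source = src, n_atoms = n)
  }
  switch(nd$name,
    element = {
      sym <- normalize_element_symbol(nd$args[[1L]]$value)
      context_selection(list(which(!is.na(top$elements) & top$elements == sym) - 1L),
                        source = src, n_atoms = n)
    },
    resname = per_residue(toupper(rt$resname) == toupper(nd$args[[1L]]$value)),
    resid = per_residue(rt$resid %in% unlist(lapply(nd$args, range_values))),
    residue = per_residue(rt$index %in% unlist(lapply(nd$args, range_values))),
    chain = context_selection(list(which(top$chain_ids == nd$args[[1L]]$value) - 1L),
                              source = src, n_atoms = n),
    protein = context_selection(protein_chain_contexts(top), source = src,
                                n_atoms = n),
    water = per_residue(is_water_resname(rt$resname)),
    atoms = {
      vals <- unlist(lapply(nd$args, range_values))
      ix <- if (is.null(ctx_atoms)) vals - 1L else ctx_atoms[vals]
      context_selection(list(ix), source = src, n_atoms = n)
    },
    stop(sprintf("function '%s' does not build a selection", nd$name))
  )
}

# ---- per-frame numeric evaluation ------------------------------------------

eval_frame <- function(nd, fi, st, ctx_atoms = NULL) {
  switch(nd$type,
    lit_int = list(kind = "num", v = as.numeric(nd$value)),
    lit_float = list(kind = "num", v = nd$value),
    neg = {
      a <- eval_frame(nd$operand, fi, st, ctx_atoms)
      list(kind = "num", v = -a$v)
    },
    binop = {
      a <- eval_frame(nd$lhs, fi, st, ctx_atoms)
      b <- eval_frame(nd$rhs, fi, st, ctx_atoms)
      v <- switch(nd$op, "+" = a$v + b$v, "-" = a$v - b$v,
                  "*" = a$v * b$v, "/" = a$v / b$v)
      list(kind = "num", v = v)
    },
    ident = {
      m <- st$num_values[[nd$name]]
      if (is.null(m)) stop(sprintf("identifier '%s' has no numeric value", nd$name))
      list(kind = "num", v = m[fi, ])
    },
    `in` = {
      rhs <- eval_selection(nd$rhs, st)
      v <- vapply(seq_along(rhs$contexts), function(ci) {
        C <- rhs$contexts[[ci]]
        r <- tryCatch(eval_frame(nd$lhs, fi, st, ctx_atoms = C),
                      error = function(e) {
                        stop(sprintf("frame %d, context %d: %s", fi, ci,
                                     conditionMessage(e)), call. = FALSE)
                      })
        as.numeric(r$v[1L])
      }, numeric(1))
      list(kind = "num", v = v)
    },
    call = eval_frame_call(nd, fi, st, ctx_atoms),
    stop(sprintf("cannot evaluate node type '%s' per frame", nd$type))
  )
}

eval_frame_call <- function(nd, fi, st, ctx_atoms) {
  fr <- st$traj$frames[[fi]]
  top <- st$top
  switch(nd$name,
    distance = ,
    angle = ,
    dihedral = {
      pts <- lapply(nd$args, function(a) arg_positions(a, fi, st, ctx_atoms))
      k <- max(vapply(pts, nrow, integer(1)))
      pts <- lapply(pts, function(m) {
        if (nrow(m) == k) m else m[rep(1L, k), , drop = FALSE]
      })
      v <- vapply(seq_len(k), function(r) {
        ps <- lapply(pts, function(m) m[r, ])
        switch(nd$name,
          distance = calc_distance(ps[[1L]], ps[[2L]], fr$cell),
          angle = calc_angle(ps[[1L]], ps[[2L]], ps[[3L]], fr$cell),
          dihedral = calc_dihedral(ps[[1L]], ps[[2L]], ps[[3L]], ps[[4L]], fr$cell))
      }, numeric(1))
      list(kind = "num", v = v)
    },
    com = {
      sel <- eval_selection(nd$args[[1L]], st, ctx_atoms)
      m <- t(vapply(sel$contexts, function(C) {
        center_of_mass(fr, C, top$masses)
      }, numeric(3)))
      list(kind = "pos", m = m)
    },
    rmsd = {
      sel <- eval_selection(nd$args[[1L]], st, ctx_atoms)
      f1 <- st$traj$frames[[1L]]
      v <- vapply(sel$contexts, function(C) {
        if (length(C) < 3L) stop("rmsd() requires at least 3 atoms per context")
        kabsch_superpose(fr$coordinates[C + 1L, , drop = FALSE],
                         f1$coordinates[C + 1L, , drop = FALSE],
                         top$masses[C + 1L])$rmsd
      }, numeric(1))
      list(kind = "num", v = v)
    },
    planarity = {
      sel <- eval_selection(nd$args[[1L]], st, ctx_atoms)
      v <- vapply(sel$contexts, function(C) {
        shape_weights(fr, C, top$masses)$c_plan
      }, numeric(1))
      list(kind = "num", v = v)
    },
    stop(sprintf("function '%s' is not a per-frame numeric operation", nd$name))
  )
}

# Positions of a geometry-call argument: an atom index (local inside `in`),
# a com() position, or a bare selection (meaning its per-context center of
# mass).  Returns a K x 3 matrix.
arg_positions <- function(a, fi, st, ctx_atoms) {
  fr <- st$traj$frames[[fi]]
  if (a$type == "lit_int") {
    ix <- if (is.null(ctx_atoms)) a$value - 1L else {
      if (a$value > length(ctx_atoms)) {
        stop(sprintf("local index %d exceeds context size %d",
                     a$value, length(ctx_atoms)))
      }
      ctx_atoms[a$value]
    }
    return(matrix(fr$coordinates[ix + 1L, ], ncol = 3L))
  }
  if (!is.null(a$vtype) && a$vtype$kind == "selection") {
    sel <- eval_selection(a, st, ctx_atoms)
    return(t(vapply(sel$contexts, function(C) {
      center_of_mass(fr, C, st$top$masses)
    }, numeric(3))))
  }
  r <- eval_frame(a, fi, st, ctx_atoms)
  if (r$kind == "pos") return(r$m)
  stop("geometry arguments must be atom indices, positions, or selections")
}

#' Evaluate with a temporal filter
#'
#' Runs the script once over the full trajectory and once restricted to the
#' frames whose times fall in `[t0, t1]`.  Distribution and volume
#' properties are recomputed over the filtered range and stored alongside
#' the full-range results (in each entry's `filtered` field); temporal
#' series are untouched by the filter.
#'
#' @param script Script text or parsed/checked script.
#' @param traj An [md_trajectory()].
#' @param t0,t1 Time range (ps), `t0 <= t1`, within the trajectory span.
#' @param workers Worker count.
#' @param base_dir Base directory for `import()` paths.
#' @return An `md_property_table`; filtered distribution/volume results sit
#'   in `entry$filtered`.
#' @export
apply_temporal_filter <- function(script, traj, t0, t1, workers = 1L,
                                  base_dir = ".") {
  if (t0 > t1) stop("temporal filter requires t0 <= t1")
  times <- frame_times(traj)
  frames <- which(times >= t0 & times <= t1)
  if (!length(frames)) stop("temporal filter selects no frames")
  full <- evaluate_script(script, traj, frame_range = NULL,
                          workers = workers, base_dir = base_dir)
  filt <- evaluate_script(script, traj, frame_range = frames,
                          workers = workers, base_dir = base_dir)
  for (nm in names(full$entries)) {
    if (full$entries[[nm]]$kind %in% c("distribution", "volume")) {
      full$entries[[nm]]$filtered <- filt$entries[[nm]]$payload
    }
  }
  full
}
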