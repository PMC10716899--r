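# Static validation of parsed scripts against a loaded topology.  Every
# expression node is annotated with a value type and length before
# evaluation; unknown residue names, absent elements, out-of-range (local)
# atom indices and type mismatches are reported as diagnostics.
#
# Value types: int, float[K], string, position[K] (K points), selection
# (K contexts), distribution, volume.  `expr in ctx` gives the left side one
# evaluation per context; a numeric left side of length 1 over K contexts
# types as float[K], a selection left side as a selection of K contexts.
# Atom indices on the left side of `in` are local to each context.

vtype <- function(kind, length = 1L, contexts = NULL) {
  list(kind = kind, length = as.integer(length), contexts = contexts)
}

type_str <- function(t) {
  if (t$kind %in% c("float", "position", "selection") && t$length != 1L) {
    sprintf("%s[%d]", t$kind, t$length)
  } else t$kind
}

new_checker <- function(topology, base_dir = ".") {
  env <- new.env(parent = emptyenv())
  env$top <- topology
  env$base_dir <- base_dir
  env$symbols <- list()
  env$diags <- list()
  env
}

c_error <- function(st, nd, message) {
  st$diags[[length(st$diags) + 1L]] <-
    make_diag("error", message, nd$span$line, nd$span$col)
  NULL
}

#' Statically check a parsed script against a topology
#'
#' @param program Result of [parse_script()].
#' @param topology The loaded [topology()] (elements should be inferred
#'   first for element validation to be meaningful).
#' @param base_dir Base directory for `import()` path resolution.
#' @return List with `statements` (nodes annotated with `$vtype`),
#'   `symbols` (identifier -> type), and `diagnostics`.
#' @export
check_script <- function(program, topology, base_dir = ".") {
  st <- new_checker(topology, base_dir)
  out <- list()
  if (length(program$diagnostics)) {
    errs <- vapply(program$diagnostics, function(d) d$severity == "error",
                   logical(1))
    if (any(errs)) {
      return(list(statements = list(), symbols = list(),
                  diagnostics = program$diagnostics))
    }
  }
  for (nd in program$statements) {
    if (nd$type == "assign") {
      if (!is.null(st$symbols[[nd$name]])) {
        c_error(st, nd, sprintf("identifier '%s' is already declared", nd$name))
        next
      }
      val <- check_node(nd$value, st, ctx = NULL)
      if (is.null(val)) next
      nd$value <- val
      nd$vtype <- val$vtype
      st$symbols[[nd$name]] <- val$vtype
    } else {
      chk <- check_node(nd, st, ctx = NULL)
      if (is.null(chk)) next
      nd <- chk
    }
    out[[length(out) + 1L]] <- nd
  }
  list(statements = out, symbols = st$symbols, diagnostics = st$diags)
}

check_node <- function(nd, st, ctx) {
  res <- switch(nd$type,
    lit_int = { nd$vtype <- vtype("int"); nd },
    lit_float = { nd$vtype <- vtype("float"); nd },
    lit_string = { nd$vtype <- vtype("string"); nd },
    lit_range = check_range(nd, st),
    ident = check_ident(nd, st),
    call = check_call(nd, st, ctx),
    and = check_setop(nd, st, ctx),
    or = check_setop(nd, st, ctx),
    not = check_not(nd, st, ctx),
    `in` = check_in(nd, st, ctx),
    binop = check_binop(nd, st, ctx),
    neg = check_neg(nd, st, ctx),
    c_error(st, nd, sprintf("unsupported node type '%s'", nd$type))
  )
  res
}

check_range <- function(nd, st) {
  if (nd$hi < nd$lo) {
    return(c_error(st, nd, sprintf("empty range %d..%d", nd$lo, nd$hi)))
  }
  nd$vtype <- vtype("int_range")
  nd
}

check_ident <- function(nd, st) {
  if (nd$name %in% c("protein", "water")) {
    return(check_call(c(nd, list(name = nd$name, args = list())), st, NULL))
  }
  t <- st$symbols[[nd$name]]
  if (is.null(t)) {
    return(c_error(st, nd, sprintf("unknown identifier '%s'", nd$name)))
  }
  nd$vtype <- t
  nd
}

is_numeric_type <- function(t) t$kind %in% c("int", "float")

check_setop <- function(nd, st, ctx) {
  lhs <- check_node(nd$lhs, st, ctx)
  rhs <- check_node(nd$rhs, st, ctx)
  if (is.null(lhs) || is.null(rhs)) return(NULL)
  if (lhs$vtype$kind != "selection" || rhs$vtype$kind != "selection") {
    return(c_error(st, nd, sprintf(
      "'%s' requires selection operands, got %s and %s", nd$type,
      type_str(lhs$vtype), type_str(rhs$vtype))))
  }
  nd$lhs <- lhs; nd$rhs <- rhs
  nd$vtype <- vtype("selection", 1L)    # and/or implicitly flatten
  nd
}

check_not <- function(nd, st, ctx) {
  op <- check_node(nd$operand, st, ctx)
  if (is.null(op)) return(NULL)
  if (op$vtype$kind != "selection") {
    return(c_error(st, nd, sprintf("'not' requires a selection operand, got %s",
                                   type_str(op$vtype))))
  }
  nd$operand <- op
  nd$vtype <- vtype("selection", 1L)
  nd
}

check_in <- function(nd, st, ctx) {
  if (!is.null(ctx)) {
    return(c_error(st, nd, "nested 'in' contexts are not supported"))
  }
  rhs <- check_node(nd$rhs, st, NULL)
  if (is.null(rhs)) return(NULL)
  if (rhs$vtype$kind != "selection") {
    return(c_error(st, nd, sprintf(
      "right side of 'in' must be a selection, got %s", type_str(rhs$vtype))))
  }
  k <- rhs$vtype$length
  sizes <- rhs$vtype$contexts
  lhs <- check_node(nd$lhs, st, ctx = list(n = k, sizes = sizes))
  if (is.null(lhs)) return(NULL)
  nd$lhs <- lhs; nd$rhs <- rhs
  if (lhs$vtype$kind == "selection") {
    nd$vtype <- vtype("selection", k)
  } else if (is_numeric_type(lhs$vtype) && lhs$vtype$length == 1L) {
    nd$vtype <- vtype("float", k)
  } else {
    return(c_error(st, nd, sprintf(
      "left side of 'in' must be a selection or scalar expression, got %s",
      type_str(lhs$vtype))))
  }
  nd
}

check_binop <- function(nd, st, ctx) {
  lhs <- check_node(nd$lhs, st, ctx)
  rhs <- check_node(nd$rhs, st, ctx)
  if (is.null(lhs) || is.null(rhs)) return(NULL)
  if (!is_numeric_type(lhs$vtype) || !is_numeric_type(rhs$vtype)) {
    return(c_error(st, nd, sprintf(
      "arithmetic requires numeric operands, got %s and %s",
      type_str(lhs$vtype), type_str(rhs$vtype))))
  }
  l1 <- lhs$vtype$length; l2 <- rhs$vtype$length
  if (l1 != l2 && l1 != 1L && l2 != 1L) {
    return(c_error(st, nd, sprintf(
      "length mismatch in arithmetic: %d vs %d", l1, l2)))
  }
  nd$lhs <- lhs; nd$rhs <- rhs
  nd$vtype <- vtype("float", max(l1, l2))
  nd
}

check_neg <- function(nd, st, ctx) {
  op <- check_node(nd$operand, st, ctx)
  if (is.null(op)) return(NULL)
  if (!is_numeric_type(op$vtype)) {
    return(c_error(st, nd, sprintf("unary '-' requires a numeric operand, got %s",
                                   type_str(op$vtype))))
  }
  nd$operand <- op
  nd$vtype <- vtype("float", op$vtype$length)
  nd
}

# ---- selection builders and numeric builtins -------------------------------

expect_args <- function(st, nd, n_min, n_max = n_min) {
  n <- length(nd$args)
  if (n < n_min || n > n_max) {
    c_error(st, nd, sprintf("'%s' expects %s argument(s), got %d", nd$name,
                            if (n_min == n_max) n_min
                            else sprintf("%d..%d", n_min, n_max), n))
    return(FALSE)
  }
  TRUE
}

range_values <- function(nd) {
  if (nd$type == "lit_int") return(nd$value)
  if (nd$type == "lit_range") return(seq.int(nd$lo, nd$hi))
  NULL
}

check_call <- function(nd, st, ctx) {
  top <- st$top
  name <- nd$name
  checker <- switch(name,
    element = function() {
      if (!expect_args(st, nd, 1L)) return(NULL)
      a <- nd$args[[1L]]
      if (a$type != "lit_string") {
        return(c_error(st, nd, "element() expects an element symbol string"))
      }
      sym <- normalize_element_symbol(a$value)
      if (is.na(sym)) {
        return(c_error(st, nd, sprintf("unknown element symbol '%s'", a$value)))
      }
      present <- !is.na(top$elements) & top$elements == sym
      if (!any(present)) {
        return(c_error(st, nd, sprintf(
          "element '%s' is not present in the topology", sym)))
      }
      nd$vtype <- vtype("selection", 1L, contexts = sum(present))
      nd
    },
    resname = function() {
      if (!expect_args(st, nd, 1L)) return(NULL)
      a <- nd$args[[1L]]
      if (a$type != "lit_string") {
        return(c_error(st, nd, "resname() expects a residue name string"))
      }
      rt <- residue_table(top)
      hit <- toupper(rt$resname) == toupper(a$value)
      if (!any(hit)) {
        return(c_error(st, nd, sprintf(
          "residue name '%s' is not present in the topology", a$value)))
      }
      nd$vtype <- vtype("selection", sum(hit), contexts = rt$count[hit])
      nd
    },
    resid = ,
    residue = function() {
      if (!expect_args(st, nd, 1L, 64L)) return(NULL)
      vals <- unlist(lapply(nd$args, range_values))
      if (is.null(vals) || length(vals) < length(nd$args)) {
        return(c_error(st, nd, sprintf(
          "%s() expects integer or range arguments", name)))
      }
      rt <- residue_table(top)
      hit <- if (name == "resid") rt$resid %in% vals else rt$index %in% vals
      if (!any(hit)) {
        return(c_error(st, nd, sprintf(
          "%s() matches no residues in the topology", name)))
      }
      nd$vtype <- vtype("selection", sum(hit), contexts = rt$count[hit])
      nd
    },
    chain = function() {
      if (!expect_args(st, nd, 1L)) return(NULL)
      a <- nd$args[[1L]]
      if (a$type != "lit_string") {
        return(c_error(st, nd, "chain() expects a chain identifier string"))
      }
      chains <- unique(top$chain_ids)
      if (!a$value %in% chains) {
        return(c_error(st, nd, sprintf(
          "chain '%s' is not present in the topology", a$value)))
      }
      sizes <- sum(top$chain_ids == a$value)
      nd$vtype <- vtype("selection", 1L, contexts = sizes)
      nd
    },
    protein = function() {
      if (!expect_args(st, nd, 0L)) return(NULL)
      k <- length(protein_chain_contexts(top))
      if (k == 0L) {
        return(c_error(st, nd, "no protein residues in the topology"))
      }
      nd$vtype <- vtype("selection", k,
                        contexts = lengths(protein_chain_contexts(top)))
      nd
    },
    water = function() {
      if (!expect_args(st, nd, 0L)) return(NULL)
      rt <- residue_table(top)
      hit <- is_water_resname(rt$resname)
      if (!any(hit)) {
        return(c_error(st, nd, "no water residues in the topology"))
      }
      nd$vtype <- vtype("selection", sum(hit), contexts = rt$count[hit])
      nd
    },
    atoms = function() {
      if (!expect_args(st, nd, 1L, 64L)) return(NULL)
      vals <- unlist(lapply(nd$args, range_values))
      if (is.null(vals) || length(vals) < length(nd$args)) {
        return(c_error(st, nd, "atoms() expects integer or range arguments"))
      }
      bad <- check_atom_indices(st, nd, vals, ctx)
      if (bad) return(NULL)
      nd$vtype <- vtype("selection", 1L, contexts = length(vals))
      nd
    },
    distance = function() check_geometry_call(nd, st, ctx, 2L),
    angle = function() check_geometry_call(nd, st, ctx, 3L),
    dihedral = function() check_geometry_call(nd, st, ctx, 4L),
    com = function() {
      if (!expect_args(st, nd, 1L)) return(NULL)
      a <- check_node(nd$args[[1L]], st, ctx)
      if (is.null(a)) return(NULL)
      if (a$vtype$kind != "selection") {
        return(c_error(st, nd, sprintf("com() expects a selection, got %s",
                                       type_str(a$vtype))))
      }
      nd$args[[1L]] <- a
      nd$vtype <- vtype("position", a$vtype$length)
      nd
    },
    rmsd = ,
    planarity = function() {
      if (!expect_args(st, nd, 1L)) return(NULL)
      a <- check_node(nd$args[[1L]], st, ctx)
      if (is.null(a)) return(NULL)
      if (a$vtype$kind != "selection") {
        return(c_error(st, nd, sprintf("%s() expects a selection, got %s",
                                       name, type_str(a$vtype))))
      }
      nd$args[[1L]] <- a
      nd$vtype <- vtype("float", a$vtype$length)
      nd
    },
    rdf = function() {
      if (!expect_args(st, nd, 3L)) return(NULL)
      a <- check_node(nd$args[[1L]], st, ctx)
      b <- check_node(nd$args[[2L]], st, ctx)
      cutv <- check_node(nd$args[[3L]], st, ctx)
      if (is.null(a) || is.null(b) || is.null(cutv)) return(NULL)
      if (a$vtype$kind != "selection" || b$vtype$kind != "selection" ||
          !is_numeric_type(cutv$vtype)) {
        return(c_error(st, nd, "rdf() expects (selection, selection, cutoff)"))
      }
      nd$args <- list(a, b, cutv)
      nd$vtype <- vtype("distribution")
      nd
    },
    sdf = function() {
      if (!expect_args(st, nd, 3L)) return(NULL)
      a <- check_node(nd$args[[1L]], st, ctx)
      b <- check_node(nd$args[[2L]], st, ctx)
      extv <- check_node(nd$args[[3L]], st, ctx)
      if (is.null(a) || is.null(b) || is.null(extv)) return(NULL)
      if (a$vtype$kind != "selection" || b$vtype$kind != "selection" ||
          !is_numeric_type(extv$vtype)) {
        return(c_error(st, nd, "sdf() expects (reference, target, extent)"))
      }
      nd$args <- list(a, b, extv)
      nd$vtype <- vtype("volume")
      nd
    },
    import = function() {
      if (!expect_args(st, nd, 1L, 2L)) return(NULL)
      a <- nd$args[[1L]]
      if (a$type != "lit_string") {
        return(c_error(st, nd, "import() expects a path string"))
      }
      filter <- NULL
      if (length(nd$args) == 2L) {
        f <- nd$args[[2L]]
        if (f$type != "lit_string") {
          return(c_error(st, nd, "import() filter must be a string of column names"))
        }
        filter <- strsplit(f$value, "[,;]\\s*")[[1L]]
      }
      tab <- tryCatch(import_table(a$value, filter, base_dir = st$base_dir),
                      error = function(e) e)
      if (inherits(tab, "error")) {
        return(c_error(st, nd, conditionMessage(tab)))
      }
      nd$import_filter <- filter
      nd$vtype <- vtype("float", length(tab$values))
      nd
    },
    NULL
  )
  if (is.null(checker)) {
    return(c_error(st, nd, sprintf("unknown function '%s'", name)))
  }
  checker()
}

# atom indices are 1-based in scripts; local to the context inside `in`
check_atom_indices <- function(st, nd, vals, ctx) {
  if (any(vals < 1L)) {
    c_error(st, nd, "atom indices are 1-based")
    return(TRUE)
  }
  if (is.null(ctx)) {
    n <- n_atoms(st$top)
    if (any(vals > n)) {
      c_error(st, nd, sprintf("atom index %d exceeds atom count %d",
                              max(vals), n))
      return(TRUE)
    }
  } else {
    sizes <- ctx$sizes
    if (!is.null(sizes) && any(vals > min(sizes))) {
      c_error(st, nd, sprintf("local index %d exceeds context size %d",
                              max(vals), min(sizes)))
      return(TRUE)
    }
  }
  FALSE
}

check_geometry_call <- function(nd, st, ctx, n_points) {
  if (!expect_args(st, nd, n_points)) return(NULL)
  lens <- integer(0)
  for (k in seq_along(nd$args)) {
    a <- nd$args[[k]]
    if (a$type == "lit_int") {
      if (check_atom_indices(st, nd, a$value, ctx)) return(NULL)
      a$vtype <- vtype("int")
      nd$args[[k]] <- a
      lens <- c(lens, 1L)
    } else {
      a <- check_node(a, st, ctx)
      if (is.null(a)) return(NULL)
      if (a$vtype$kind == "position") {
        lens <- c(lens, a$vtype$length)
      } else if (a$vtype$kind == "selection") {
        # a bare selection argument means its center of mass
        lens <- c(lens, a$vtype$length)
      } else {
        return(c_error(st, nd, sprintf(
          "'%s' arguments must be atom indices, positions, or selections; got %s",
          nd$name, type_str(a$vtype))))
      }
      nd$args[[k]] <- a
    }
  }
  u <- unique(lens[lens != 1L])
  if (length(u) > 1L) {
    return(c_error(st, nd, sprintf("'%s': mismatched argument lengths (%s)",
                                   nd$name, paste(lens, collapse = ", "))))
  }
  nd$vtype <- vtype("float", if (length(u)) u else 1L)
  nd
}

# Contexts of the `protein` builtin: contiguous runs of amino-acid residues
# grouped per chain, ordered by lowest atom index.
protein_chain_contexts <- function(top) {
  aa <- is_amino_acid(top$residue_names)
  if (!any(aa)) return(list())
  keys <- paste(top$chain_ids, sep = "")
  grp <- split(which(aa) - 1L, top$chain_ids[aa])
  grp <- grp[order(vapply(grp, min, integer(1)))]
  unname(grp)
}
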