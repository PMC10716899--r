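# Lexer and recursive-descent parser for the analysis scripting language.
#
# Grammar:
#   program   := statement*
#   statement := ident "=" expr | expr
#   expr      := or_expr ("in" or_expr)?          # `in` binds loosest
#   or_expr   := and_expr ("or" and_expr)*
#   and_expr  := not_expr ("and" not_expr)*
#   not_expr  := "not" not_expr | add_expr
#   add_expr  := mul_expr (("+" | "-") mul_expr)*
#   mul_expr  := unary (("*" | "/") unary)*
#   unary     := "-" unary | primary
#   primary   := number | int ".." int | string | call | ident | "(" expr ")"
#   call      := ident "(" (expr ("," expr)*)? ")"
#
# Comments run from "#" to end of line.  String literals accept single or
# double quotes.  Integer ranges are written i..j (inclusive).  Atom and
# residue indices at the script level are 1-based.

KEYWORDS <- c("and", "or", "not", "in")

make_diag <- function(severity, message, line, col) {
  list(severity = severity, message = message, line = line, col = col)
}

#' Format diagnostics as text
#'
#' @param diagnostics List of diagnostics from [parse_script()] or
#'   [check_script()].
#' @return Character vector, one `"line:col: severity: message"` per entry.
#' @export
format_diagnostics <- function(diagnostics) {
  vapply(diagnostics, function(d) {
    sprintf("%d:%d: %s: %s", d$line, d$col, d$severity, d$message)
  }, character(1))
}

tokenize_script <- function(text) {
  tokens <- list()
  diags <- list()
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (!length(lines)) lines <- ""
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
      if (ch == "#") break
      start <- i
      if (grepl("^[A-Za-z_]", ch)) {
        while (i <= n && grepl("^[A-Za-z0-9_]", substr(s, i, i))) i <- i + 1L
        word <- substr(s, start, i - 1L)
        type <- if (word %in% KEYWORDS) "kw" else "ident"
        tokens[[length(tokens) + 1L]] <- list(type = type, value = word,
                                              line = ln, col = start)
        next
      }
      if (grepl("^[0-9]", ch) ||
          (ch == "." && i < n && grepl("^[0-9]", substr(s, i + 1L, i + 1L)))) {
        j <- i
        seen_dot <- FALSE
        while (j <= n) {
          cj <- substr(s, j, j)
          if (grepl("^[0-9]", cj)) { j <- j + 1L; next }
          if (cj == "." && !seen_dot) {
            # ".." is the range operator, not a decimal point
            if (j < n && substr(s, j + 1L, j + 1L) == ".") break
            seen_dot <- TRUE
            j <- j + 1L
            next
          }
          if (cj %in% c("e", "E") && seen_dot) {
            if (j < n && grepl("^[-+0-9]", substr(s, j + 1L, j + 1L))) {
              j <- j + 2L
              while (j <= n && grepl("^[0-9]", substr(s, j, j))) j <- j + 1L
            }
          }
          break
        }
        num <- substr(s, i, j - 1L)
        tokens[[length(tokens) + 1L]] <- list(
          type = if (seen_dot || grepl("[eE]", num)) "float" else "int",
          value = num, line = ln, col = start)
        i <- j
        next
      }
      if (ch %in% c('"', "'")) {
        j <- i + 1L
        while (j <= n && substr(s, j, j) != ch) j <- j + 1L
        if (j > n) {
          diags[[length(diags) + 1L]] <-
            make_diag("error", "unterminated string literal", ln, start)
          i <- n + 1L
          next
        }
        tokens[[length(tokens) + 1L]] <- list(type = "string",
                                              value = substr(s, i + 1L, j - 1L),
                                              line = ln, col = start)
        i <- j + 1L
        next
      }
      if (i < n && substr(s, i, i + 1L) == "..") {
        tokens[[length(tokens) + 1L]] <- list(type = "op", value = "..",
                                              line = ln, col = start)
        i <- i + 2L
        next
      }
      if (ch %in% c("=", "(", ")", ",", "+", "-", "*", "/")) {
        tokens[[length(tokens) + 1L]] <- list(type = "op", value = ch,
                                              line = ln, col = start)
        i <- i + 1L
        next
      }
      diags[[length(diags) + 1L]] <-
        make_diag("error", sprintf("unexpected character '%s'", ch), ln, start)
      i <- i + 1L
    }
    tokens[[length(tokens) + 1L]] <- list(type = "newline", value = "\n",
                                          line = ln, col = nchar(s) + 1L)
  }
  tokens[[length(tokens) + 1L]] <- list(type = "eof", value = "",
                                        line = length(lines),
                                        col = nchar(lines[length(lines)]) + 1L)
  list(tokens = tokens, diagnostics = diags)
}

# Parser state is a mutable environment over the token stream.
new_parser <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  env$diags <- list()
  env
}

peek <- function(p, skip_newlines = FALSE) {
  k <- p$pos
  if (skip_newlines) {
    while (p$tokens[[k]]$type == "newline") k <- k + 1L
  }
  p$tokens[[k]]
}

advance <- function(p) {
  t <- p$tokens[[p$pos]]
  if (t$type != "eof") p$pos <- p$pos + 1L
  t
}

skip_newlines <- function(p) {
  while (p$tokens[[p$pos]]$type == "newline") p$pos <- p$pos + 1L
}

p_error <- function(p, message, tok = NULL) {
  tok <- if (is.null(tok)) peek(p) else tok
  p$diags[[length(p$diags) + 1L]] <- make_diag("error", message, tok$line, tok$col)
  NULL
}

node <- function(type, tok, ...) {
  c(list(type = type, span = list(line = tok$line, col = tok$col)), list(...))
}

#' Parse an analysis script
#'
#' @param text Script source (UTF-8; `#` starts a comment).
#' @return List with `statements` (syntax-tree nodes; assignments have
#'   `name` and `value`) and `diagnostics`.  Syntax errors never throw; they
#'   are reported through the diagnostics channel.
#' @examples
#' parse_script("s1 = element('H') and protein")
#' @export
parse_script <- function(text) {
  lex <- tokenize_script(text)
  p <- new_parser(lex$tokens)
  p$diags <- lex$diagnostics
  statements <- list()
  repeat {
    skip_newlines(p)
    if (peek(p)$type == "eof") break
    st <- parse_statement(p)
    if (is.null(st)) {
      # error recovery: skip to next line
      while (!peek(p)$type %in% c("newline", "eof")) advance(p)
      next
    }
    statements[[length(statements) + 1L]] <- st
    nxt <- peek(p)
    if (!nxt$type %in% c("newline", "eof")) {
      p_error(p, sprintf("unexpected token '%s' after statement", nxt$value))
      while (!peek(p)$type %in% c("newline", "eof")) advance(p)
    }
  }
  list(statements = statements, diagnostics = p$diags)
}

parse_statement <- function(p) {
  t1 <- peek(p)
  if (t1$type == "ident" && p$tokens[[p$pos + 1L]]$type == "op" &&
      p$tokens[[p$pos + 1L]]$value == "=") {
    advance(p); advance(p)
    value <- parse_expr(p)
    if (is.null(value)) return(NULL)
    return(node("assign", t1, name = t1$value, value = value))
  }
  parse_expr(p)
}

parse_expr <- function(p) {
  lhs <- parse_or(p)
  if (is.null(lhs)) return(NULL)
  t <- peek(p)
  if (t$type == "kw" && t$value == "in") {
    advance(p)
    rhs <- parse_or(p)
    if (is.null(rhs)) return(NULL)
    return(node("in", t, lhs = lhs, rhs = rhs))
  }
  lhs
}

parse_or <- function(p) {
  lhs <- parse_and(p)
  if (is.null(lhs)) return(NULL)
  repeat {
    t <- peek(p)
    if (t$type == "kw" && t$value == "or") {
      advance(p)
      rhs <- parse_and(p)
      if (is.null(rhs)) return(NULL)
      lhs <- node("or", t, lhs = lhs, rhs = rhs)
    } else return(lhs)
  }
}

parse_and <- function(p) {
  lhs <- parse_not(p)
  if (is.null(lhs)) return(NULL)
  repeat {
    t <- peek(p)
    if (t$type == "kw" && t$value == "and") {
      advance(p)
      rhs <- parse_not(p)
      if (is.null(rhs)) return(NULL)
      lhs <- node("and", t, lhs = lhs, rhs = rhs)
    } else return(lhs)
  }
}

parse_not <- function(p) {
  t <- peek(p)
  if (t$type == "kw" && t$value == "not") {
    advance(p)
    operand <- parse_not(p)
    if (is.null(operand)) return(NULL)
    return(node("not", t, operand = operand))
  }
  parse_add(p)
}

parse_add <- function(p) {
  lhs <- parse_mul(p)
  if (is.null(lhs)) return(NULL)
  repeat {
    t <- peek(p)
    if (t$type == "op" && t$value %in% c("+", "-")) {
      advance(p)
      rhs <- parse_mul(p)
      if (is.null(rhs)) return(NULL)
      lhs <- node("binop", t, op = t$value, lhs = lhs, rhs = rhs)
    } else return(lhs)
  }
}

parse_mul <- function(p) {
  lhs <- parse_unary(p)
  if (is.null(lhs)) return(NULL)
  repeat {
    t <- peek(p)
    if (t$type == "op" && t$value %in% c("*", "/")) {
      advance(p)
      rhs <- parse_unary(p)
      if (is.null(rhs)) return(NULL)
      lhs <- node("binop", t, op = t$value, lhs = lhs, rhs = rhs)
    } else return(lhs)
  }
}

parse_unary <- function(p) {
  t <- peek(p)
  if (t$type == "op" && t$value == "-") {
    advance(p)
    operand <- parse_unary(p)
    if (is.null(operand)) return(NULL)
    return(node("neg", t, operand = operand))
  }
  parse_primary(p)
}

parse_primary <- function(p) {
  t <- peek(p)
  if (t$type == "int") {
    advance(p)
    nxt <- peek(p)
    if (nxt$type == "op" && nxt$value == "..") {
      advance(p)
      hi <- peek(p)
      if (hi$type != "int") return(p_error(p, "expected integer after '..'", hi))
      advance(p)
      return(node("lit_range", t, lo = as.integer(t$value),
                  hi = as.integer(hi$value)))
    }
    return(node("lit_int", t, value = as.integer(t$value)))
  }
  if (t$type == "float") {
    advance(p)
    return(node("lit_float", t, value = as.numeric(t$value)))
  }
  if (t$type == "string") {
    advance(p)
    return(node("lit_string", t, value = t$value))
  }
  if (t$type == "op" && t$value == "(") {
    advance(p)
    inner <- parse_expr(p)
    if (is.null(inner)) return(NULL)
    cl <- peek(p)
    if (!(cl$type == "op" && cl$value == ")")) {
      return(p_error(p, "expected ')'", cl))
    }
    advance(p)
    return(inner)
  }
  if (t$type == "ident") {
    advance(p)
    nxt <- peek(p)
    if (nxt$type == "op" && nxt$value == "(") {
      advance(p)
      args <- list()
      if (!(peek(p)$type == "op" && peek(p)$value == ")")) {
        repeat {
          if (peek(p)$type %in% c("eof", "newline")) {
            return(p_error(p, sprintf("unterminated call to '%s'", t$value)))
          }
          arg <- parse_expr(p)
          if (is.null(arg)) return(NULL)
          args[[length(args) + 1L]] <- arg
          sep <- peek(p)
          if (sep$type == "op" && sep$value == ",") { advance(p); next }
          break
        }
      }
      cl <- peek(p)
      if (!(cl$type == "op" && cl$value == ")")) {
        return(p_error(p, sprintf("expected ')' to close call to '%s'", t$value), cl))
      }
      advance(p)
      return(node("call", t, name = t$value, args = args))
    }
    return(node("ident", t, name = t$value))
  }
  p_error(p, sprintf("unexpected token '%s'",
                     if (nzchar(t$value)) t$value else "end of input"), t)
}

#' Pretty-print a syntax tree back to script text
#'
#' The printed form re-parses to a structurally equal tree.
#'
#' @param x A node or statement list from [parse_script()].
#' @return A character scalar of script text.
#' @export
format_script <- function(x) {
  if (!is.null(x$statements)) {
    return(paste(vapply(x$statements, format_node, character(1)),
                 collapse = "\n"))
  }
  format_node(x)
}

format_node <- function(nd) {
  switch(nd$type,
    assign = sprintf("%s = %s", nd$name, format_node(nd$value)),
    lit_int = as.character(nd$value),
    lit_float = format(nd$value, digits = 15),
    lit_string = sprintf('"%s"', nd$value),
    lit_range = sprintf("%d..%d", nd$lo, nd$hi),
    ident = nd$name,
    call = sprintf("%s(%s)", nd$name,
                   paste(vapply(nd$args, format_node, character(1)),
                         collapse = ", ")),
    and = sprintf("(%s and %s)", format_node(nd$lhs), format_node(nd$rhs)),
    or = sprintf("(%s or %s)", format_node(nd$lhs), format_node(nd$rhs)),
    not = sprintf("(not %s)", format_node(nd$operand)),
    `in` = sprintf("(%s in %s)", format_node(nd$lhs), format_node(nd$rhs)),
    binop = sprintf("(%s %s %s)", format_node(nd$lhs), nd$op,
                    format_node(nd$rhs)),
    neg = sprintf("(-%s)", format_node(nd$operand)),
    stop(sprintf("unknown node type '%s'", nd$type))
  )
}
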