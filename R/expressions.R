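# Infix math expression engine used for observable formulas, noise formulas
# and kinetic laws.  Expressions are stored as nested lists ("petab_expr"):
#   list(kind = "num",  value = <double>)
#   list(kind = "sym",  name  = <identifier>)
#   list(kind = "call", fn = <operator or function name>, args = list(...))
# Supported functions: exp, log, log10, log2, sqrt, abs, sin, cos, tanh,
# min, max, piecewise(value, condition, otherwise).  Conditions use the
# comparison operators <, <=, >, >=, ==, != and evaluate to 1/0.

.expr_functions <- c("exp", "log", "log10", "log2", "sqrt", "abs",
                     "sin", "cos", "tanh", "min", "max", "piecewise")

.id_regex <- "^[A-Za-z_][A-Za-z0-9_]*$"

is_identifier <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(.id_regex, x)
}

expr_num <- function(value) {
  structure(list(kind = "num", value = as.numeric(value)),
            class = "petab_expr")
}

expr_sym <- function(name) {
  structure(list(kind = "sym", name = name), class = "petab_expr")
}

expr_call <- function(fn, args) {
  structure(list(kind = "call", fn = fn, args = args), class = "petab_expr")
}

petab_error <- function(code, message, ...) {
  stop(structure(class = c(paste0("petab_", code), "petab_error",
                           "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

# ---- tokenizer -------------------------------------------------------------

.tokenize_expression <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) {
      i <- i + 1L
      next
    }
    if (grepl("^[0-9.]$", ch)) {
      tail_text <- substr(text, i, n)
      m <- regmatches(tail_text,
                      regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                              tail_text))
      if (length(m) == 0L || !nzchar(m)) {
        petab_error("expression_syntax",
                    sprintf("invalid number at position %d in '%s'", i, text),
                    position = i)
      }
      push("num", as.numeric(m), i)
      i <- i + nchar(m)
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      tail_text <- substr(text, i, n)
      m <- regmatches(tail_text, regexpr("^[A-Za-z_][A-Za-z0-9_]*",
                                         tail_text))
      push("name", m, i)
      i <- i + nchar(m)
      next
    }
    two <- substr(text, i, min(i + 1L, n))
    if (two %in% c("<=", ">=", "==", "!=")) {
      push("op", two, i)
      i <- i + 2L
      next
    }
    if (ch %in% c("+", "-", "*", "/", "^", "(", ")", ",", "<", ">")) {
      push("op", ch, i)
      i <- i + 1L
      next
    }
    petab_error("expression_syntax",
                sprintf("unexpected character '%s' at position %d in '%s'",
                        ch, i, text),
                position = i)
  }
  tokens
}

# ---- Pratt parser ----------------------------------------------------------
# Precedence (loosest to tightest): comparisons < +,- < *,/ < unary- < ^
# with ^ right-associative and binding tighter than unary minus on its left
# operand (-x^2 == -(x^2)).

#' Parse a math expression
#'
#' Parses the infix expression grammar used in observable formulas, noise
#' formulas and kinetic laws into an expression tree.
#'
#' @param text A single character string, e.g. `"scaling_p * B + offset_p"`.
#' @return An object of class `petab_expr`.
#' @examples
#' e <- parse_expression("k1 * A")
#' free_symbols(e)
#' evaluate_expression(e, c(k1 = 0.8, A = 1))
#' @export
parse_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    petab_error("expression_syntax", "expression text must be non-empty")
  }
  tokens <- .tokenize_expression(text)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$i <- 1L
  state$text <- text
  expr <- .parse_comparison(state)
  if (state$i <= length(state$tokens)) {
    tok <- state$tokens[[state$i]]
    petab_error("expression_syntax",
                sprintf("unexpected token '%s' at position %d in '%s'",
                        tok$value, tok$pos, text),
                position = tok$pos)
  }
  expr
}

.peek <- function(state) {
  if (state$i > length(state$tokens)) NULL else state$tokens[[state$i]]
}

.advance <- function(state) {
  tok <- .peek(state)
  if (is.null(tok)) {
    petab_error("expression_syntax",
                sprintf("unexpected end of expression in '%s'", state$text))
  }
  state$i <- state$i + 1L
  tok
}

.expect_op <- function(state, op) {
  tok <- .advance(state)
  if (tok$type != "op" || tok$value != op) {
    petab_error("expression_syntax",
                sprintf("expected '%s' at position %d in '%s'",
                        op, tok$pos, state$text),
                position = tok$pos)
  }
  tok
}

.parse_comparison <- function(state) {
  left <- .parse_additive(state)
  tok <- .peek(state)
  if (!is.null(tok) && tok$type == "op" &&
      tok$value %in% c("<", "<=", ">", ">=", "==", "!=")) {
    state$i <- state$i + 1L
    right <- .parse_additive(state)
    return(expr_call(tok$value, list(left, right)))
  }
  left
}

.parse_additive <- function(state) {
  left <- .parse_multiplicative(state)
  repeat {
    tok <- .peek(state)
    if (is.null(tok) || tok$type != "op" || !tok$value %in% c("+", "-")) {
      return(left)
    }
    state$i <- state$i + 1L
    right <- .parse_multiplicative(state)
    left <- expr_call(tok$value, list(left, right))
  }
}

.parse_multiplicative <- function(state) {
  left <- .parse_unary(state)
  repeat {
    tok <- .peek(state)
    if (is.null(tok) || tok$type != "op" || !tok$value %in% c("*", "/")) {
      return(left)
    }
    state$i <- state$i + 1L
    right <- .parse_unary(state)
    left <- expr_call(tok$value, list(left, right))
  }
}

.parse_unary <- function(state) {
  tok <- .peek(state)
  if (!is.null(tok) && tok$type == "op" && tok$value %in% c("-", "+")) {
    state$i <- state$i + 1L
    operand <- .parse_unary(state)
    if (tok$value == "+") return(operand)
    return(expr_call("neg", list(operand)))
  }
  .parse_power(state)
}

.parse_power <- function(state) {
  base <- .parse_atom(state)
  tok <- .peek(state)
  if (!is.null(tok) && tok$type == "op" && tok$value == "^") {
    state$i <- state$i + 1L
    # right-associative; exponent may carry a unary minus
    exponent <- .parse_unary(state)
    return(expr_call("^", list(base, exponent)))
  }
  base
}

.parse_atom <- function(state) {
  tok <- .advance(state)
  if (tok$type == "num") {
    return(expr_num(tok$value))
  }
  if (tok$type == "name") {
    nxt <- .peek(state)
    if (!is.null(nxt) && nxt$type == "op" && nxt$value == "(") {
      if (!tok$value %in% .expr_functions) {
        petab_error("expression_syntax",
                    sprintf("unknown function '%s' at position %d",
                            tok$value, tok$pos),
                    position = tok$pos)
      }
      state$i <- state$i + 1L
      args <- list()
      nxt <- .peek(state)
      if (!is.null(nxt) && !(nxt$type == "op" && nxt$value == ")")) {
        repeat {
          args[[length(args) + 1L]] <- .parse_comparison(state)
          nxt <- .peek(state)
          if (!is.null(nxt) && nxt$type == "op" && nxt$value == ",") {
            state$i <- state$i + 1L
          } else {
            break
          }
        }
      }
      .expect_op(state, ")")
      .check_arity(tok$value, length(args), tok$pos)
      return(expr_call(tok$value, args))
    }
    return(expr_sym(tok$value))
  }
  if (tok$type == "op" && tok$value == "(") {
    inner <- .parse_comparison(state)
    .expect_op(state, ")")
    return(inner)
  }
  petab_error("expression_syntax",
              sprintf("unexpected token '%s' at position %d in '%s'",
                      tok$value, tok$pos, state$text),
              position = tok$pos)
}

.check_arity <- function(fn, n, pos) {
  expected <- switch(fn,
    exp = 1L, log = 1L, log10 = 1L, log2 = 1L, sqrt = 1L, abs = 1L,
    sin = 1L, cos = 1L, tanh = 1L, piecewise = 3L, min = 2L, max = 2L)
  if (!is.null(expected) && n != expected) {
    petab_error("expression_syntax",
                sprintf("function '%s' expects %d argument(s), got %d",
                        fn, expected, n),
                position = pos)
  }
}

# ---- evaluation ------------------------------------------------------------

#' Evaluate an expression tree
#'
#' @param expr A `petab_expr` (or a string, parsed on the fly).
#' @param env A named numeric vector or list supplying every free symbol.
#' @return A numeric scalar. Comparison operators yield 1 or 0.
#' @export
evaluate_expression <- function(expr, env = list()) {
  if (is.character(expr)) expr <- parse_expression(expr)
  env <- as.list(env)
  .eval_node(expr, env)
}

.eval_node <- function(node, env) {
  switch(node$kind,
    num = node$value,
    sym = {
      val <- env[[node$name]]
      if (is.null(val)) {
        if (node$name == "time") {
          petab_error("missing_symbol",
                      "symbol 'time' not provided in environment",
                      symbol = "time")
        }
        petab_error("missing_symbol",
                    sprintf("symbol '%s' not provided in environment",
                            node$name),
                    symbol = node$name)
      }
      as.numeric(val)
    },
    call = .eval_call(node, env),
    petab_error("internal", "corrupt expression node"))
}

.eval_call <- function(node, env) {
  fn <- node$fn
  if (fn == "piecewise") {
    cond <- .eval_node(node$args[[2]], env)
    if (cond != 0) .eval_node(node$args[[1]], env)
    else .eval_node(node$args[[3]], env)
  } else if (fn == "neg") {
    -.eval_node(node$args[[1]], env)
  } else {
    a <- vapply(node$args, .eval_node, numeric(1), env = env)
    switch(fn,
      "+" = a[1] + a[2],
      "-" = a[1] - a[2],
      "*" = a[1] * a[2],
      "/" = a[1] / a[2],
      "^" = a[1]^a[2],
      "<" = as.numeric(a[1] < a[2]),
      "<=" = as.numeric(a[1] <= a[2]),
      ">" = as.numeric(a[1] > a[2]),
      ">=" = as.numeric(a[1] >= a[2]),
      "==" = as.numeric(a[1] == a[2]),
      "!=" = as.numeric(a[1] != a[2]),
      exp = exp(a[1]),
      log = .checked_log(a[1], base = exp(1)),
      log10 = .checked_log(a[1], base = 10),
      log2 = .checked_log(a[1], base = 2),
      sqrt = {
        if (a[1] < 0) petab_error("domain", "sqrt of negative value",
                                  op = "sqrt", value = a[1])
        sqrt(a[1])
      },
      abs = abs(a[1]),
      sin = sin(a[1]),
      cos = cos(a[1]),
      tanh = tanh(a[1]),
      min = min(a),
      max = max(a),
      petab_error("internal", sprintf("unknown function '%s'", fn)))
  }
}

.checked_log <- function(x, base) {
  if (is.na(x) || x <= 0) {
    petab_error("domain", sprintf("log of non-positive value %g", x),
                op = "log", value = x)
  }
  log(x, base = base)
}

#' Free symbols of an expression
#'
#' @param expr A `petab_expr` or a string.
#' @return Character vector of symbol names, in first-appearance order.
#' @export
free_symbols <- function(expr) {
  if (is.character(expr)) expr <- parse_expression(expr)
  out <- character(0)
  walk <- function(node) {
    if (node$kind == "sym") {
      out[[length(out) + 1L]] <<- node$name
    } else if (node$kind == "call") {
      for (a in node$args) walk(a)
    }
  }
  walk(expr)
  unique(out)
}

#' Print an expression tree back to its infix form
#'
#' `parse_expression(expression_to_string(e))` reproduces `e` structurally.
#'
#' @param expr A `petab_expr`.
#' @return A character string.
#' @export
expression_to_string <- function(expr) {
  if (is.character(expr)) return(expr)
  .print_node(expr, parent_prec = 0L)
}

.op_prec <- c("<" = 1L, "<=" = 1L, ">" = 1L, ">=" = 1L, "==" = 1L,
              "!=" = 1L, "+" = 2L, "-" = 2L, "*" = 3L, "/" = 3L,
              "neg" = 4L, "^" = 5L)

.print_node <- function(node, parent_prec) {
  if (node$kind == "num") {
    return(format_petab_number(node$value))
  }
  if (node$kind == "sym") {
    return(node$name)
  }
  fn <- node$fn
  if (fn %in% names(.op_prec)) {
    prec <- .op_prec[[fn]]
    if (fn == "neg") {
      s <- paste0("-", .print_node(node$args[[1]], prec))
    } else {
      # left operand at own precedence, right one tighter (left-assoc ops);
      # '^' is right-assoc so flip
      lp <- if (fn == "^") prec + 1L else prec
      rp <- if (fn == "^") prec else prec + 1L
      s <- paste0(.print_node(node$args[[1]], lp), " ", fn, " ",
                  .print_node(node$args[[2]], rp))
    }
    if (prec < parent_prec) s <- paste0("(", s, ")")
    return(s)
  }
  paste0(fn, "(",
         paste(vapply(node$args, .print_node, character(1), parent_prec = 0L),
               collapse = ", "),
         ")")
}

# Convert to an R language object; used by the simulator so kinetic laws can
# be evaluated with eval() in a tight loop instead of tree-walking.
expr_to_lang <- function(expr) {
  if (is.character(expr)) expr <- parse_expression(expr)
  .node_to_lang <- function(node) {
    switch(node$kind,
      num = node$value,
      sym = as.name(node$name),
      call = {
        fn <- node$fn
        if (fn == "neg") {
          call("-", .node_to_lang(node$args[[1]]))
        } else if (fn == "piecewise") {
          call("if", call("!=", .node_to_lang(node$args[[2]]), 0),
               .node_to_lang(node$args[[1]]),
               .node_to_lang(node$args[[3]]))
        } else if (fn %in% c("<", "<=", ">", ">=", "==", "!=")) {
          call("as.numeric", as.call(c(as.name(fn),
                                       lapply(node$args, .node_to_lang))))
        } else {
          as.call(c(as.name(fn), lapply(node$args, .node_to_lang)))
        }
      })
  }
  .node_to_lang(expr)
}

# Substitute symbols by other expression trees (used to inline SBML
# assignment rules into kinetic laws).
expr_substitute <- function(expr, substitutions) {
  if (is.character(expr)) expr <- parse_expression(expr)
  walk <- function(node) {
    if (node$kind == "sym" && node$name %in% names(substitutions)) {
      return(substitutions[[node$name]])
    }
    if (node$kind == "call") {
      node$args <- lapply(node$args, walk)
    }
    node
  }
  walk(expr)
}

#' Format a number the way the package writes it to TSV cells
#'
#' Up to 15 significant digits, no trailing zeros, locale-independent.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_petab_number <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (is.infinite(v)) return(if (v > 0) "inf" else "-inf")
    if (v == trunc(v) && abs(v) < 1e15) {
      return(sprintf("%.0f", v))
    }
    sprintf("%.15g", v)
  }, character(1))
}
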