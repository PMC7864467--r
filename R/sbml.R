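# Minimal SBML interface: entity inventory for any SBML level/version plus
# ODE extraction for the restricted subset the reference simulator handles
# (reactions with kinetic laws, assignment rules, constant compartments; no
# events, no algebraic/rate rules, no delays, no function definitions).

#' Load an SBML model
#'
#' Reads any SBML Level 2/3 file well enough to enumerate its entities.
#' Models using constructs outside the simulatable subset are still loaded
#' (for mapping and validation), with `simulation_supported = FALSE` and the
#' offending constructs listed in `support_reasons`.
#'
#' Species are handled as concentrations: an `initialAmount` is divided by
#' the compartment size on load.  Initial assignments are evaluated once at
#' load time; assignment rules are kept symbolically and substituted into
#' kinetic laws when the ODE right-hand side is built.
#'
#' @param path Path to an SBML XML file.
#' @return An object of class `petab_sbml_model` with elements
#'   `parameters` (named numeric), `species` (data.frame with `id`,
#'   `initial`, `compartment`, `constant`), `compartments` (named numeric),
#'   `reactions`, `assignment_rules`, `simulation_supported`,
#'   `support_reasons` and `xml_text`.
#' @export
load_sbml_model <- function(path) {
  if (!file.exists(path)) {
    petab_error("missing_file", sprintf("file not found: %s", path),
                path = path)
  }
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    petab_error("sbml_read",
                                sprintf("cannot parse %s: %s", path,
                                        conditionMessage(e)))
                  })
  if (xml2::xml_name(doc) != "sbml") {
    petab_error("not_sbml", sprintf("%s is not an SBML document", path))
  }
  xml_text <- readChar(path, file.size(path), useBytes = TRUE)
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, "./model")
  if (length(model_node) == 0L) {
    petab_error("not_sbml", "SBML document has no <model> element")
  }

  num_attr <- function(node, attr, default = NA_real_) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else as.numeric(v)
  }

  comp_nodes <- xml2::xml_find_all(model_node,
                                   "./listOfCompartments/compartment")
  compartments <- stats::setNames(
    vapply(comp_nodes, num_attr, numeric(1), attr = "size", default = 1),
    vapply(comp_nodes, xml2::xml_attr, character(1), attr = "id"))

  par_nodes <- xml2::xml_find_all(model_node, "./listOfParameters/parameter")
  parameters <- stats::setNames(
    vapply(par_nodes, num_attr, numeric(1), attr = "value", default = NA_real_),
    vapply(par_nodes, xml2::xml_attr, character(1), attr = "id"))

  sp_nodes <- xml2::xml_find_all(model_node, "./listOfSpecies/species")
  species <- data.frame(
    id = vapply(sp_nodes, xml2::xml_attr, character(1), attr = "id"),
    compartment = vapply(sp_nodes, xml2::xml_attr, character(1),
                         attr = "compartment"),
    constant = vapply(sp_nodes, function(n) {
      isTRUE(xml2::xml_attr(n, "constant") == "true") ||
        isTRUE(xml2::xml_attr(n, "boundaryCondition") == "true")
    }, logical(1)),
    stringsAsFactors = FALSE)
  species$initial <- vapply(seq_along(sp_nodes), function(i) {
    n <- sp_nodes[[i]]
    conc <- num_attr(n, "initialConcentration")
    if (!is.na(conc)) return(conc)
    amt <- num_attr(n, "initialAmount")
    if (!is.na(amt)) {
      vol <- compartments[[species$compartment[i]]]
      if (is.null(vol) || is.na(vol)) vol <- 1
      return(amt / vol)
    }
    NA_real_
  }, numeric(1))

  reasons <- character(0)
  if (length(xml2::xml_find_all(model_node, "./listOfEvents/event")) > 0L) {
    reasons <- c(reasons, "events")
  }
  if (length(xml2::xml_find_all(model_node,
                                "./listOfRules/algebraicRule")) > 0L) {
    reasons <- c(reasons, "algebraic rules")
  }
  if (length(xml2::xml_find_all(model_node, "./listOfRules/rateRule")) > 0L) {
    reasons <- c(reasons, "rate rules")
  }
  if (length(xml2::xml_find_all(
        model_node, "./listOfFunctionDefinitions/functionDefinition")) > 0L) {
    reasons <- c(reasons, "function definitions")
  }

  rule_nodes <- xml2::xml_find_all(model_node, "./listOfRules/assignmentRule")
  assignment_rules <- list()
  for (n in rule_nodes) {
    target <- xml2::xml_attr(n, "variable")
    math <- xml2::xml_find_first(n, "./math")
    assignment_rules[[target]] <- mathml_to_expr(math)
  }

  ia_nodes <- xml2::xml_find_all(model_node,
                                 "./listOfInitialAssignments/initialAssignment")
  if (length(ia_nodes) > 0L) {
    env <- c(as.list(parameters), as.list(compartments),
             stats::setNames(as.list(species$initial), species$id),
             list(time = 0))
    for (n in ia_nodes) {
      target <- xml2::xml_attr(n, "symbol")
      value <- evaluate_expression(
        mathml_to_expr(xml2::xml_find_first(n, "./math")), env)
      if (target %in% names(parameters)) parameters[[target]] <- value
      else if (target %in% names(compartments)) compartments[[target]] <- value
      else if (target %in% species$id) {
        species$initial[species$id == target] <- value
      }
    }
  }

  rx_nodes <- xml2::xml_find_all(model_node, "./listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(n) {
    stoich <- numeric(0)
    add <- function(refs, sign) {
      for (r in refs) {
        sp <- xml2::xml_attr(r, "species")
        s <- xml2::xml_attr(r, "stoichiometry")
        s <- if (is.na(s)) 1 else as.numeric(s)
        stoich[sp] <<- (if (sp %in% names(stoich)) stoich[[sp]] else 0) +
          sign * s
      }
    }
    add(xml2::xml_find_all(n, "./listOfReactants/speciesReference"), -1)
    add(xml2::xml_find_all(n, "./listOfProducts/speciesReference"), +1)
    kl <- xml2::xml_find_first(n, "./kineticLaw")
    law <- NULL
    local_parameters <- numeric(0)
    if (length(kl) > 0L) {
      lp_nodes <- c(xml2::xml_find_all(kl, "./listOfParameters/parameter"),
                    xml2::xml_find_all(kl,
                                       "./listOfLocalParameters/localParameter"))
      if (length(lp_nodes) > 0L) {
        local_parameters <- stats::setNames(
          vapply(lp_nodes, function(p) as.numeric(xml2::xml_attr(p, "value")),
                 numeric(1)),
          vapply(lp_nodes, xml2::xml_attr, character(1), attr = "id"))
      }
      math <- xml2::xml_find_first(kl, "./math")
      if (length(math) > 0L) law <- mathml_to_expr(math)
    }
    list(id = xml2::xml_attr(n, "id"), stoichiometry = stoich, law = law,
         local_parameters = local_parameters)
  })
  if (any(vapply(reactions, function(r) is.null(r$law), logical(1))) &&
      length(reactions) > 0L) {
    reasons <- c(reasons, "reaction without kinetic law")
  }

  model <- structure(list(parameters = parameters,
                          species = species,
                          compartments = compartments,
                          reactions = reactions,
                          assignment_rules = assignment_rules,
                          simulation_supported = length(reasons) == 0L,
                          support_reasons = reasons,
                          xml_text = xml_text,
                          path = normalizePath(path)),
                     class = "petab_sbml_model")
  model
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' @export
print.petab_sbml_model <- function(x, ...) {
  cat(sprintf("SBML model: %d species, %d parameters, %d compartments, %d reactions\n",
              nrow(x$species), length(x$parameters), length(x$compartments),
              length(x$reactions)))
  if (!x$simulation_supported) {
    cat("  not simulatable:", paste(x$support_reasons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify an identifier against the model's entity inventory
#'
#' @param model A `petab_sbml_model`.
#' @param id Identifier to look up.
#' @return One of `"parameter"`, `"species"`, `"compartment"`,
#'   `"rule-target"`, `"absent"`.  The reserved symbol `time` is `"absent"`
#'   (it is not an overridable entity).
#' @export
has_entity <- function(model, id) {
  if (is.null(model)) return("absent")
  if (id %in% names(model$assignment_rules)) return("rule-target")
  if (id %in% names(model$parameters)) return("parameter")
  if (id %in% model$species$id) return("species")
  if (id %in% names(model$compartments)) return("compartment")
  "absent"
}

# ---- MathML ----------------------------------------------------------------

mathml_to_expr <- function(math_node) {
  kids <- xml2::xml_children(math_node)
  if (length(kids) != 1L) {
    petab_error("sbml_read", "expected exactly one MathML root expression")
  }
  .mathml_node(kids[[1]])
}

.mathml_node <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    txt <- xml2::xml_text(node)
    if (!is.na(type) && type == "e-notation") {
      parts <- strsplit(trimws(txt), "[ \t\r\n]+")[[1]]
      parts <- parts[nzchar(parts)]
      return(expr_num(as.numeric(parts[1]) * 10^as.numeric(parts[2])))
    }
    if (!is.na(type) && type == "rational") {
      parts <- strsplit(trimws(txt), "[ \t\r\n]+")[[1]]
      parts <- parts[nzchar(parts)]
      return(expr_num(as.numeric(parts[1]) / as.numeric(parts[2])))
    }
    return(expr_num(as.numeric(trimws(txt))))
  }
  if (name == "ci") {
    return(expr_sym(trimws(xml2::xml_text(node))))
  }
  if (name == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (!is.na(url) && grepl("time", url)) return(expr_sym("time"))
    petab_error("sbml_read", sprintf("unsupported csymbol '%s'", url))
  }
  if (name == "true") return(expr_num(1))
  if (name == "false") return(expr_num(0))
  if (name == "pi") return(expr_num(pi))
  if (name == "exponentiale") return(expr_num(exp(1)))
  if (name == "piecewise") {
    pieces <- xml2::xml_find_all(node, "./piece")
    otherwise <- xml2::xml_find_first(node, "./otherwise")
    if (length(otherwise) == 0L) {
      petab_error("sbml_read", "piecewise without otherwise is unsupported")
    }
    out <- .mathml_node(xml2::xml_children(otherwise)[[1]])
    for (p in rev(pieces)) {
      pk <- xml2::xml_children(p)
      out <- expr_call("piecewise",
                       list(.mathml_node(pk[[1]]), .mathml_node(pk[[2]]), out))
    }
    return(out)
  }
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    rest <- kids[-1]
    if (op %in% c("log", "root")) {
      qual <- if (op == "log") "logbase" else "degree"
      nm <- vapply(rest, xml2::xml_name, character(1))
      x <- .mathml_node(rest[[which(nm != qual)[1]]])
      if (qual %in% nm) {
        q <- .mathml_node(xml2::xml_children(rest[[which(nm == qual)[1]]])[[1]])
        if (op == "log") {
          return(expr_call("/", list(expr_call("log", list(x)),
                                     expr_call("log", list(q)))))
        }
        if (q$kind != "num" || q$value != 2) {
          petab_error("sbml_read", "only square roots are supported")
        }
        return(expr_call("sqrt", list(x)))
      }
      return(if (op == "log") expr_call("log10", list(x))
             else expr_call("sqrt", list(x)))
    }
    args <- lapply(rest, .mathml_node)
    fold <- function(fn, args) {
      out <- args[[1]]
      for (a in args[-1]) out <- expr_call(fn, list(out, a))
      out
    }
    return(switch(op,
      plus = if (length(args) == 0L) expr_num(0) else fold("+", args),
      times = if (length(args) == 0L) expr_num(1) else fold("*", args),
      minus = if (length(args) == 1L) expr_call("neg", args)
              else fold("-", args),
      divide = fold("/", args),
      power = fold("^", args),
      exp = expr_call("exp", args),
      ln = expr_call("log", args),
      abs = expr_call("abs", args),
      sin = expr_call("sin", args),
      cos = expr_call("cos", args),
      tanh = expr_call("tanh", args),
      lt = expr_call("<", args),
      leq = expr_call("<=", args),
      gt = expr_call(">", args),
      geq = expr_call(">=", args),
      eq = expr_call("==", args),
      neq = expr_call("!=", args),
      petab_error("sbml_read",
                  sprintf("unsupported MathML operator '%s'", op))))
  }
  if (name == "logbase") {
    # handled inside log; reaching here means a malformed tree
    petab_error("sbml_read", "unexpected <logbase> element")
  }
  petab_error("sbml_read", sprintf("unsupported MathML element '%s'", name))
}

# ---- ODE extraction --------------------------------------------------------

# Build the symbolic ODE right-hand side: for each non-constant species s,
#   d[s]/dt = (1/V_s) * sum_r stoich(s, r) * rate_r
# with assignment rules substituted into kinetic laws and local reaction
# parameters inlined as numbers.
model_ode_system <- function(model) {
  if (!model$simulation_supported) {
    petab_error("unsupported_model",
                paste("model not simulatable:",
                      paste(model$support_reasons, collapse = ", ")),
                reasons = model$support_reasons)
  }
  dynamic <- model$species$id[!model$species$constant]
  subs <- model$assignment_rules
  # substitute rules into each other once (rules referencing rules)
  if (length(subs) > 0L) {
    for (pass in seq_len(length(subs))) {
      subs <- lapply(subs, expr_substitute, substitutions = subs)
    }
  }
  terms <- stats::setNames(vector("list", length(dynamic)), dynamic)
  for (r in model$reactions) {
    law <- r$law
    if (length(r$local_parameters) > 0L) {
      law <- expr_substitute(law, lapply(r$local_parameters, expr_num))
    }
    if (length(subs) > 0L) law <- expr_substitute(law, subs)
    for (sp in names(r$stoichiometry)) {
      if (!sp %in% dynamic) next
      coef <- r$stoichiometry[[sp]]
      if (coef == 0) next
      term <- if (coef == 1) law
              else if (coef == -1) expr_call("neg", list(law))
              else expr_call("*", list(expr_num(coef), law))
      terms[[sp]] <- c(terms[[sp]], list(term))
    }
  }
  rhs <- lapply(dynamic, function(sp) {
    tl <- terms[[sp]]
    if (length(tl) == 0L) return(expr_num(0))
    out <- tl[[1]]
    for (t in tl[-1]) {
      if (t$kind == "call" && t$fn == "neg") {
        out <- expr_call("-", list(out, t$args[[1]]))
      } else {
        out <- expr_call("+", list(out, t))
      }
    }
    vol_id <- model$species$compartment[model$species$id == sp]
    vol <- model$compartments[[vol_id]]
    if (is.null(vol)) vol <- 1
    out <- expr_call("/", list(out, expr_sym(vol_id)))
    out
  })
  names(rhs) <- dynamic
  list(species = dynamic, rhs = rhs,
       rhs_lang = lapply(rhs, expr_to_lang),
       rules = subs)
}

# Human-readable right-hand side, e.g. for inspection/tests:
#   dA/dt = (-(k1 * A) + k2 * B) / compartment
ode_rhs_strings <- function(model) {
  sys <- model_ode_system(model)
  stats::setNames(vapply(sys$rhs, expression_to_string, character(1)),
                  sys$species)
}
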