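# The linter: a closed registry of machine-checkable rules over an
# assembled problem.  Issues are data (a data.frame), never exceptions;
# assert_petab_valid() turns error-severity issues into one aggregated
# condition.  Linting never mutates the problem and does not require a
# simulatable model: simulator-subset violations are simulation errors, not
# format errors.

.lint_registry <- data.frame(
  code = c("INVALID_ID", "DUPLICATE_ID", "REF_CONDITION", "REF_OBSERVABLE",
           "CONDITION_TARGET", "FORMULA_SYNTAX", "PLACEHOLDER_ARITY",
           "PARAMETER_COVERAGE", "UNUSED_PARAMETER", "BOUNDS_ORDER",
           "BOUNDS_LOG_POSITIVE", "ESTIMATE_FLAG", "BAD_SCALE",
           "BAD_TRANSFORMATION", "BAD_DISTRIBUTION", "NEGATIVE_TIME",
           "MEASUREMENT_NOT_FINITE", "LOG_MEASUREMENT_POSITIVE",
           "PRIOR_PARAMETERS", "NOMINAL_MISSING", "NOMINAL_OUT_OF_BOUNDS",
           "REF_VISUALIZATION", "VIS_PLOT_TYPE"),
  severity = c("error", "error", "error", "error",
               "error", "error", "error",
               "error", "warning", "error",
               "error", "error", "error",
               "error", "error", "error",
               "error", "error",
               "error", "error", "warning",
               "error", "warning"),
  description = c(
    "identifier violates the grammar [A-Za-z_][A-Za-z0-9_]*",
    "duplicate identifier within a table",
    "measurement references an unknown condition id",
    "measurement references an unknown observable id",
    "condition column targets neither a model entity nor a parameter row",
    "observable or noise formula does not parse",
    "override cell entry count does not match the formula's placeholders",
    "formula or override symbol resolves through no table and no model entity",
    "estimated parameter is never referenced by the problem",
    "lowerBound exceeds upperBound for an estimated parameter",
    "non-positive lower bound under a log estimation scale",
    "estimate flag is neither 0 nor 1",
    "parameterScale outside {lin, log, log10}",
    "observableTransformation outside {lin, log, log10}",
    "noiseDistribution outside {normal, laplace}",
    "measurement time is negative",
    "measurement value is not finite",
    "non-positive measurement under a log observable transformation",
    "prior parameters missing or of wrong arity for the prior type",
    "fixed parameter (estimate = 0) lacks a nominal value",
    "nominal value of an estimated parameter lies outside its bounds",
    "visualization references an unknown observable or dataset id",
    "unknown plot type (plot is skipped)"),
  stringsAsFactors = FALSE)

#' The lint rule registry
#'
#' @return A data.frame with columns `code`, `severity`, `description`.
#' @export
lint_rules <- function() .lint_registry

.issue <- function(code, message, role, location) {
  sev <- .lint_registry$severity[.lint_registry$code == code]
  petab_issue(sev, code, message, role, location)
}

#' Lint an assembled PEtab problem
#'
#' Runs every registered rule (see [lint_rules()]) and returns the issues
#' found, in stable rule-then-row order.  An empty result means the problem
#' is valid.
#'
#' @param problem A `petab_problem` (possibly invalid).
#' @return A data.frame of issues (zero rows when valid).
#' @export
lint_problem <- function(problem) {
  issues <- list()
  add <- function(code, message, role, location) {
    issues[[length(issues) + 1L]] <<- .issue(code, message, role, location)
  }
  model <- problem$model
  cond <- problem$conditions
  meas <- problem$measurements
  obs <- problem$observables
  par <- problem$parameters

  # INVALID_ID / DUPLICATE_ID over the three id-bearing tables
  for (spec in list(list(cond$conditionId, "condition"),
                    list(obs$observableId, "observable"),
                    list(par$parameterId, "parameter"))) {
    ids <- spec[[1]]
    role <- spec[[2]]
    for (id in ids[!is.na(ids) & !grepl(.id_regex, ids)]) {
      add("INVALID_ID", sprintf("invalid identifier '%s'", id), role, id)
    }
    for (id in unique(ids[duplicated(ids)])) {
      add("DUPLICATE_ID", sprintf("duplicate id '%s'", id), role, id)
    }
  }

  # measurement references
  for (i in seq_len(nrow(meas))) {
    if (!meas$simulationConditionId[i] %in% cond$conditionId) {
      add("REF_CONDITION",
          sprintf("row %d: unknown simulation condition '%s'", i,
                  meas$simulationConditionId[i]), "measurement", i)
    }
    preeq <- if ("preequilibrationConditionId" %in% names(meas)) {
      meas$preequilibrationConditionId[i]
    } else NA_character_
    if (!is.na(preeq) && !preeq %in% cond$conditionId) {
      add("REF_CONDITION",
          sprintf("row %d: unknown pre-equilibration condition '%s'", i,
                  preeq), "measurement", i)
    }
    if (!meas$observableId[i] %in% obs$observableId) {
      add("REF_OBSERVABLE",
          sprintf("row %d: unknown observable '%s'", i, meas$observableId[i]),
          "measurement", i)
    }
  }

  # condition targets and identifier cells
  for (target in condition_targets(cond)) {
    kind <- has_entity(model, target)
    if (kind == "absent" && !target %in% par$parameterId) {
      add("CONDITION_TARGET",
          sprintf("column '%s' is neither a model entity nor a parameter",
                  target), "condition", target)
    }
    for (i in seq_len(nrow(cond))) {
      cell <- cond[[target]][i]
      if (is.na(cell)) next
      if (is.na(suppressWarnings(as.numeric(cell))) &&
          !cell %in% par$parameterId) {
        add("PARAMETER_COVERAGE",
            sprintf("condition '%s', column '%s': '%s' is not numeric and not a parameter",
                    cond$conditionId[i], target, cell), "condition",
            cond$conditionId[i])
      }
    }
  }

  # observable formulas: syntax, placeholder naming, symbol coverage
  parsed <- list()
  for (i in seq_len(nrow(obs))) {
    oid <- obs$observableId[i]
    for (field in c("observableFormula", "noiseFormula")) {
      txt <- obs[[field]][i]
      tree <- tryCatch(parse_expression(txt), petab_error = function(e) e)
      if (inherits(tree, "petab_error")) {
        add("FORMULA_SYNTAX",
            sprintf("observable '%s', %s: %s", oid, field,
                    conditionMessage(tree)), "observable", oid)
        next
      }
      parsed[[paste(oid, field)]] <- tree
      for (sym in free_symbols(tree)) {
        if (sym == "time") next
        if (grepl("^(observable|noise)Parameter[0-9]+_", sym)) {
          if (sym != sub("^((observable|noise)Parameter[0-9]+_).*$",
                         paste0("\\1", oid), sym)) {
            add("PARAMETER_COVERAGE",
                sprintf("observable '%s': placeholder '%s' names a different observable",
                        oid, sym), "observable", oid)
          }
          next
        }
        if (has_entity(model, sym) != "absent") next
        if (sym %in% par$parameterId) next
        if (sym %in% obs$observableId) next
        add("PARAMETER_COVERAGE",
            sprintf("observable '%s', %s: symbol '%s' resolves through nothing",
                    oid, field, sym), "observable", oid)
      }
    }
    if (!obs$observableTransformation[i] %in% .observable_transformations) {
      add("BAD_TRANSFORMATION",
          sprintf("observable '%s': transformation '%s'", oid,
                  obs$observableTransformation[i]), "observable", oid)
    }
    if (!obs$noiseDistribution[i] %in% .noise_distributions) {
      add("BAD_DISTRIBUTION",
          sprintf("observable '%s': distribution '%s'", oid,
                  obs$noiseDistribution[i]), "observable", oid)
    }
  }

  # measurements: placeholder arity, time, value domain, override symbols
  for (i in seq_len(nrow(meas))) {
    oid <- meas$observableId[i]
    orow <- obs[obs$observableId == oid, , drop = FALSE]
    if (nrow(orow) == 1L) {
      for (kind in c("observable", "noise")) {
        key <- paste(oid, paste0(kind, "Formula"))
        if (is.null(parsed[[key]])) next
        k <- placeholder_count(orow[1, ], kind)
        col <- paste0(kind, "Parameters")
        cell <- if (col %in% names(meas)) meas[[col]][i] else NA_character_
        entries <- parse_override_list(cell)
        if (length(entries) != k && !(k == 0L && length(entries) == 0L)) {
          add("PLACEHOLDER_ARITY",
              sprintf("row %d: %s has %d entries, observable '%s' uses %d placeholder(s)",
                      i, col, length(entries), oid, k), "measurement", i)
        }
        for (e in entries) {
          if (is.character(e) && !e %in% par$parameterId &&
              has_entity(model, e) == "absent") {
            add("PARAMETER_COVERAGE",
                sprintf("row %d: override '%s' is not a parameter", i, e),
                "measurement", i)
          }
        }
      }
      tr <- orow$observableTransformation[1]
      if (tr %in% c("log", "log10") && !is.na(meas$measurement[i]) &&
          is.finite(meas$measurement[i]) && meas$measurement[i] <= 0) {
        add("LOG_MEASUREMENT_POSITIVE",
            sprintf("row %d: measurement %g under %s transformation", i,
                    meas$measurement[i], tr), "measurement", i)
      }
    }
    if (is.na(meas$time[i]) || (!is.infinite(meas$time[i]) &&
                                meas$time[i] < 0)) {
      add("NEGATIVE_TIME", sprintf("row %d: time %s", i,
                                   format(meas$time[i])), "measurement", i)
    }
    if (is.na(meas$measurement[i]) || !is.finite(meas$measurement[i])) {
      add("MEASUREMENT_NOT_FINITE",
          sprintf("row %d: measurement is %s", i,
                  format(meas$measurement[i])), "measurement", i)
    }
  }

  # parameter table
  referenced <- .referenced_parameter_ids(problem, parsed)
  for (i in seq_len(nrow(par))) {
    pid <- par$parameterId[i]
    est <- par$estimate[i]
    if (is.na(est) || !est %in% c(0, 1)) {
      add("ESTIMATE_FLAG", sprintf("parameter '%s': estimate '%s'", pid,
                                   format(est)), "parameter", pid)
      next
    }
    if (!par$parameterScale[i] %in% .parameter_scales) {
      add("BAD_SCALE", sprintf("parameter '%s': scale '%s'", pid,
                               par$parameterScale[i]), "parameter", pid)
    }
    if (est == 1) {
      lb <- par$lowerBound[i]
      ub <- par$upperBound[i]
      if (!is.na(lb) && !is.na(ub) && lb > ub) {
        add("BOUNDS_ORDER", sprintf("parameter '%s': bounds [%g, %g]", pid,
                                    lb, ub), "parameter", pid)
      }
      if (par$parameterScale[i] %in% c("log", "log10") && !is.na(lb) &&
          lb <= 0) {
        add("BOUNDS_LOG_POSITIVE",
            sprintf("parameter '%s': lower bound %g under %s scale", pid, lb,
                    par$parameterScale[i]), "parameter", pid)
      }
      if (!is.na(par$nominalValue[i]) && !is.na(lb) && !is.na(ub) &&
          (par$nominalValue[i] < lb || par$nominalValue[i] > ub)) {
        add("NOMINAL_OUT_OF_BOUNDS",
            sprintf("parameter '%s': nominal %g outside [%g, %g]", pid,
                    par$nominalValue[i], lb, ub), "parameter", pid)
      }
      if (!pid %in% referenced && has_entity(model, pid) == "absent") {
        add("UNUSED_PARAMETER",
            sprintf("estimated parameter '%s' is never referenced", pid),
            "parameter", pid)
      }
    } else {
      if (is.na(par$nominalValue[i])) {
        add("NOMINAL_MISSING",
            sprintf("fixed parameter '%s' lacks a nominal value", pid),
            "parameter", pid)
      }
    }
    type <- if ("initializationPriorType" %in% names(par)) {
      par$initializationPriorType[i]
    } else NA_character_
    if (!is.na(type)) {
      if (!type %in% .prior_types) {
        add("PRIOR_PARAMETERS", sprintf("parameter '%s': unknown prior '%s'",
                                        pid, type), "parameter", pid)
      } else {
        pp <- if ("initializationPriorParameters" %in% names(par)) {
          unlist(parse_override_list(par$initializationPriorParameters[i]))
        } else NULL
        need2 <- !type %in% "parameterScaleUniform"
        if ((need2 && (length(pp) != 2L || !is.numeric(pp))) ||
            (!need2 && !length(pp) %in% c(0L, 2L))) {
          add("PRIOR_PARAMETERS",
              sprintf("parameter '%s': prior '%s' needs two numeric parameters",
                      pid, type), "parameter", pid)
        }
      }
    }
  }

  # visualization
  vis <- problem$visualization
  if (!is.null(vis)) {
    for (i in seq_len(nrow(vis))) {
      for (oid in unlist(lapply(parse_override_list(vis$yObservables[i]),
                                as.character))) {
        if (!oid %in% obs$observableId) {
          add("REF_VISUALIZATION",
              sprintf("plot '%s': unknown observable '%s'", vis$plotId[i],
                      oid), "visualization", vis$plotId[i])
        }
      }
      if (vis$grouping[i] == "by_dataset_id" &&
          "datasetId" %in% names(meas)) {
        # dataset ids are free-form; nothing to resolve
      }
      if (!vis$plotType[i] %in% .plot_types) {
        add("VIS_PLOT_TYPE", sprintf("plot '%s': unknown type '%s'",
                                     vis$plotId[i], vis$plotType[i]),
            "visualization", vis$plotId[i])
      }
    }
  }

  if (length(issues) == 0L) return(.empty_issues())
  out <- do.call(rbind, issues)
  out <- out[order(match(out$code, .lint_registry$code)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Parameter ids referenced anywhere: formulas, condition cells, measurement
# override cells, prior parameters never count.
.referenced_parameter_ids <- function(problem, parsed = NULL) {
  refs <- character(0)
  if (is.null(parsed)) {
    parsed <- list()
    for (i in seq_len(nrow(problem$observables))) {
      for (field in c("observableFormula", "noiseFormula")) {
        tree <- tryCatch(parse_expression(problem$observables[[field]][i]),
                         petab_error = function(e) NULL)
        if (!is.null(tree)) {
          parsed[[paste(problem$observables$observableId[i], field)]] <- tree
        }
      }
    }
  }
  for (tree in parsed) refs <- c(refs, free_symbols(tree))
  for (target in condition_targets(problem$conditions)) {
    refs <- c(refs, target)
    cells <- problem$conditions[[target]]
    cells <- cells[!is.na(cells)]
    refs <- c(refs, cells[is.na(suppressWarnings(as.numeric(cells)))])
  }
  for (col in c("observableParameters", "noiseParameters")) {
    if (!col %in% names(problem$measurements)) next
    for (cell in problem$measurements[[col]]) {
      entries <- parse_override_list(cell)
      refs <- c(refs, unlist(Filter(is.character, entries)))
    }
  }
  unique(refs)
}

#' Stop on any error-severity lint issue
#'
#' @param problem A `petab_problem`.
#' @return The problem, invisibly, when valid (warnings do not block).
#' @export
assert_petab_valid <- function(problem) {
  issues <- lint_problem(problem)
  errors <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errors) > 0L) {
    petab_error("validation",
                paste0(sprintf("problem has %d validation error(s):\n",
                               nrow(errors)),
                       paste(sprintf("  [%s] %s", errors$code,
                                     errors$message), collapse = "\n")),
                issues = issues)
  }
  invisible(problem)
}
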