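# Resolution of the hierarchical parameter-override rules into concrete
# per-condition maps, and derivation of the simulation jobs (condition
# pairs) from the measurement table.
#
# Precedence for a model entity's value, lowest to highest:
#   1. the default in the SBML model,
#   2. the parameter table (nominal value, or the free parameter itself when
#      estimate = 1), for model parameters that appear there,
#   3. the condition table column for the condition (numeric cell = literal;
#      identifier cell = one chain step into the parameter table).
# Independently, placeholder symbols introduced by observable/noise formulas
# (observableParameter{n}_<observableId>, noiseParameter{n}_<observableId>)
# are bound per measurement row from the respective override cells.

#' Derive the unique (pre-equilibration, simulation) condition pairs
#'
#' Each pair is one simulation job.  Pairs are returned in first-appearance
#' order of the measurement table; every measurement belongs to exactly one
#' pair.
#'
#' @param measurements Canonical measurement table.
#' @return A data.frame with columns `preequilibrationConditionId`
#'   (`NA` when absent), `simulationConditionId`, and a list-column
#'   `measurement_rows` with the row indices of the pair's measurements.
#' @export
get_condition_pairs <- function(measurements) {
  preeq <- if ("preequilibrationConditionId" %in% names(measurements)) {
    measurements$preequilibrationConditionId
  } else {
    rep(NA_character_, nrow(measurements))
  }
  sim <- measurements$simulationConditionId
  key <- paste(ifelse(is.na(preeq), "", preeq), sim, sep = "\r")
  ord <- unique(key)
  out <- data.frame(
    preequilibrationConditionId = vapply(ord, function(k) {
      p <- strsplit(k, "\r", fixed = TRUE)[[1]][1]
      if (!nzchar(p)) NA_character_ else p
    }, character(1)),
    simulationConditionId = vapply(ord, function(k) {
      strsplit(k, "\r", fixed = TRUE)[[1]][2]
    }, character(1)),
    stringsAsFactors = FALSE)
  out$measurement_rows <- lapply(ord, function(k) which(key == k))
  rownames(out) <- NULL
  out
}

# Highest placeholder index of kind "observableParameter" or
# "noiseParameter" used by an observable's formulas.
placeholder_count <- function(observable_row, kind = c("observable", "noise")) {
  kind <- match.arg(kind)
  formula <- if (kind == "observable") observable_row$observableFormula
             else observable_row$noiseFormula
  syms <- free_symbols(formula)
  pat <- sprintf("^%sParameter([0-9]+)_%s$", kind, observable_row$observableId)
  idx <- as.integer(sub(pat, "\\1", syms[grepl(pat, syms)]))
  if (length(idx) == 0L) 0L else max(idx)
}

# Resolve one value cell of the condition table: numeric literal, or one
# chain step into the parameter table (free id when estimated, nominal
# value otherwise).  Identifier cells that chain to another identifier are
# rejected as cyclic.
.resolve_value_cell <- function(cell, parameters, where) {
  num <- suppressWarnings(as.numeric(cell))
  if (!is.na(num)) return(num)
  row <- which(parameters$parameterId == cell)
  if (length(row) == 0L) {
    petab_error("unresolved_symbol",
                sprintf("'%s' (%s) is neither numeric nor a parameter-table id",
                        cell, where),
                id = cell, where = where)
  }
  if (parameters$estimate[row] == 1) return(cell)
  nominal <- parameters$nominalValue[row]
  if (is.na(nominal)) {
    petab_error("unresolved_symbol",
                sprintf("parameter '%s' (%s) is fixed but has no nominal value",
                        cell, where),
                id = cell, where = where)
  }
  nominal
}

# Base map for one condition: model defaults, overlaid by the parameter
# table, overlaid by the condition row.  Species/compartment entries are
# values; parameters may resolve to a free parameter id.
.condition_map <- function(problem, condition_id, base_state_policy) {
  model <- problem$model
  map <- list()
  for (p in names(model$parameters)) map[[p]] <- model$parameters[[p]]
  for (cmp in names(model$compartments)) {
    map[[cmp]] <- model$compartments[[cmp]]
  }
  for (i in seq_len(nrow(model$species))) {
    map[[model$species$id[i]]] <- model$species$initial[i]
  }
  # parameter table overrides model parameters it names
  for (i in seq_len(nrow(problem$parameters))) {
    pid <- problem$parameters$parameterId[i]
    if (has_entity(model, pid) == "absent") next
    if (problem$parameters$estimate[i] == 1) {
      map[[pid]] <- pid
    } else if (!is.na(problem$parameters$nominalValue[i])) {
      map[[pid]] <- problem$parameters$nominalValue[i]
    }
  }
  empty_species <- character(0)
  overridden_species <- character(0)
  if (!is.na(condition_id)) {
    crow <- which(problem$conditions$conditionId == condition_id)
    if (length(crow) == 0L) {
      petab_error("unresolved_symbol",
                  sprintf("condition '%s' not found", condition_id),
                  id = condition_id, where = "condition table")
    }
    for (target in condition_targets(problem$conditions)) {
      cell <- problem$conditions[[target]][crow]
      kind <- has_entity(model, target)
      if (is.na(cell)) {
        # EMPTY: meaningful only for species columns, where it requests the
        # carry-over of the pre-equilibrated state
        if (kind == "species") empty_species <- c(empty_species, target)
        next
      }
      value <- .resolve_value_cell(cell, problem$parameters,
                                   sprintf("condition '%s', column '%s'",
                                           condition_id, target))
      map[[target]] <- value
      if (kind == "species") overridden_species <- c(overridden_species, target)
    }
  }
  list(map = map, empty_species = empty_species,
       overridden_species = overridden_species)
}

#' Resolve the parameter mapping for one condition pair
#'
#' Applies the override precedence (model default, then parameter table,
#' then condition table) separately for the pre-equilibration and the
#' simulation condition, binds observable/noise placeholder symbols per
#' measurement row, determines which species are reinitialized on the
#' switch from pre-equilibration to simulation, and collects the estimation
#' scale of every free parameter that appears in the maps.
#'
#' @param problem A valid `petab_problem` (run [assert_petab_valid()] first).
#' @param pair One row of [get_condition_pairs()] (data.frame or list with
#'   `preequilibrationConditionId`, `simulationConditionId`, and optionally
#'   `measurement_rows`).
#' @return An object of class `petab_mapping`: list with `map_preeq`
#'   (`NULL` without pre-equilibration), `map_sim`, `placeholders` (per
#'   measurement row: named list binding placeholder symbols to numbers or
#'   free parameter ids), `reinit_states`, `carryover_states` and
#'   `scale_map`.
#' @export
resolve_mapping <- function(problem, pair) {
  preeq_id <- pair$preequilibrationConditionId
  if (is.list(preeq_id)) preeq_id <- preeq_id[[1]]
  sim_id <- pair$simulationConditionId
  if (is.list(sim_id)) sim_id <- sim_id[[1]]
  rows <- pair$measurement_rows
  if (is.list(rows) && length(rows) == 1L && is.numeric(rows[[1]])) {
    rows <- rows[[1]]
  }
  if (is.null(rows)) {
    pairs <- get_condition_pairs(problem$measurements)
    hit <- which(
      pairs$simulationConditionId == sim_id &
        (is.na(pairs$preequilibrationConditionId) == is.na(preeq_id)) &
        (is.na(preeq_id) | pairs$preequilibrationConditionId %in% preeq_id))
    rows <- if (length(hit) > 0L) pairs$measurement_rows[[hit[1]]] else integer(0)
  }

  sim_res <- .condition_map(problem, sim_id, "model")
  map_preeq <- NULL
  reinit_states <- character(0)
  carryover_states <- character(0)
  if (!is.na(preeq_id)) {
    preeq_res <- .condition_map(problem, preeq_id, "model")
    map_preeq <- preeq_res$map
    reinit_states <- sim_res$overridden_species
    carryover_states <- setdiff(problem$model$species$id, reinit_states)
  }

  placeholders <- list()
  for (ri in rows) {
    m <- problem$measurements[ri, ]
    orow <- problem$observables[
      problem$observables$observableId == m$observableId, , drop = FALSE]
    if (nrow(orow) == 0L) next
    binding <- list()
    for (kind in c("observable", "noise")) {
      k <- placeholder_count(orow[1, ], kind)
      if (k == 0L) next
      col <- paste0(kind, "Parameters")
      cell <- if (col %in% names(m)) m[[col]] else NA_character_
      entries <- parse_override_list(cell)
      if (length(entries) != k) {
        petab_error("unresolved_symbol",
                    sprintf("measurement row %d: %s cell has %d entries, formula uses %d placeholder(s)",
                            ri, col, length(entries), k),
                    id = m$observableId, where = col)
      }
      for (n in seq_len(k)) {
        sym <- sprintf("%sParameter%d_%s", kind, n, m$observableId)
        e <- entries[[n]]
        binding[[sym]] <- if (is.numeric(e)) e else {
          .resolve_value_cell(e, problem$parameters,
                              sprintf("measurement row %d, %s", ri, col))
        }
      }
    }
    placeholders[[as.character(ri)]] <- binding
  }

  free_ids <- unique(unlist(c(
    Filter(is.character, sim_res$map),
    if (!is.null(map_preeq)) Filter(is.character, map_preeq),
    lapply(placeholders, function(b) unlist(Filter(is.character, b))))))
  scale_map <- character(0)
  for (fid in free_ids) {
    prow <- which(problem$parameters$parameterId == fid)
    scale_map[fid] <- problem$parameters$parameterScale[prow[1]]
  }

  structure(list(preequilibrationConditionId = preeq_id,
                 simulationConditionId = sim_id,
                 measurement_rows = rows,
                 map_preeq = map_preeq,
                 map_sim = sim_res$map,
                 placeholders = placeholders,
                 reinit_states = reinit_states,
                 carryover_states = carryover_states,
                 scale_map = scale_map),
            class = "petab_mapping")
}

#' @export
print.petab_mapping <- function(x, ...) {
  cat(sprintf("Parameter mapping for (%s -> %s)\n",
              if (is.na(x$preequilibrationConditionId)) "-"
              else x$preequilibrationConditionId,
              x$simulationConditionId))
  show_map <- function(map) {
    for (k in names(map)) {
      v <- map[[k]]
      cat(sprintf("    %s = %s\n", k,
                  if (is.character(v)) paste0("<", v, ">")
                  else format_petab_number(v)))
    }
  }
  if (!is.null(x$map_preeq)) {
    cat("  pre-equilibration map:\n"); show_map(x$map_preeq)
  }
  cat("  simulation map:\n"); show_map(x$map_sim)
  if (length(x$reinit_states) > 0L) {
    cat("  reinitialized states:", paste(x$reinit_states, collapse = ", "),
        "\n")
  }
  invisible(x)
}

# ---- parameter scales ------------------------------------------------------

#' Transform a value to / from an estimation scale
#'
#' `petab_scale` maps a linear-scale value onto the estimation scale
#' (`lin` = identity, `log` = natural log, `log10` = base-10 log);
#' `petab_unscale` is its inverse.
#'
#' @param value Numeric vector (positive for the log scales in
#'   `petab_scale`).
#' @param scale One of `"lin"`, `"log"`, `"log10"`.
#' @return Numeric vector.
#' @export
petab_scale <- function(value, scale) {
  switch(scale,
    lin = value,
    log = {
      if (any(value <= 0)) {
        petab_error("domain", "log scaling requires positive values",
                    op = "log", value = min(value))
      }
      log(value)
    },
    log10 = {
      if (any(value <= 0)) {
        petab_error("domain", "log10 scaling requires positive values",
                    op = "log10", value = min(value))
      }
      log10(value)
    },
    petab_error("bad_scale", sprintf("unknown scale '%s'", scale)))
}

#' @rdname petab_scale
#' @export
petab_unscale <- function(value, scale) {
  switch(scale,
    lin = value,
    log = exp(value),
    log10 = 10^value,
    petab_error("bad_scale", sprintf("unknown scale '%s'", scale)))
}

#' List the free (estimated) parameters on their estimation scales
#'
#' @param problem A `petab_problem`.
#' @return A data.frame with one row per `estimate = 1` parameter row, in
#'   parameter-table order: `parameterId`, `parameterScale`, scaled
#'   `lowerBound`, `upperBound` and `nominalValue`.
#' @export
get_free_parameters <- function(problem) {
  p <- problem$parameters
  est <- p[p$estimate == 1, , drop = FALSE]
  out <- data.frame(parameterId = est$parameterId,
                    parameterScale = est$parameterScale,
                    lowerBound = NA_real_, upperBound = NA_real_,
                    nominalValue = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(est))) {
    sc <- est$parameterScale[i]
    out$lowerBound[i] <- petab_scale(est$lowerBound[i], sc)
    out$upperBound[i] <- petab_scale(est$upperBound[i], sc)
    if (!is.na(est$nominalValue[i])) {
      out$nominalValue[i] <- petab_scale(est$nominalValue[i], sc)
    }
  }
  rownames(out) <- NULL
  out
}

# Concrete numeric values for one map given linear-scale values of the free
# parameters (named vector); free ids are substituted, numbers pass through.
materialize_map <- function(map, free_values) {
  out <- numeric(0)
  for (k in names(map)) {
    v <- map[[k]]
    if (is.character(v)) {
      if (!v %in% names(free_values)) {
        petab_error("unresolved_symbol",
                    sprintf("no value supplied for free parameter '%s'", v),
                    id = v, where = "materialize_map")
      }
      out[k] <- free_values[[v]]
    } else {
      out[k] <- v
    }
  }
  out
}

# Nominal linear-scale values for every parameter-table row (estimated rows
# use their nominal value; it is required for fixed rows).
nominal_free_values <- function(problem) {
  p <- problem$parameters
  stats::setNames(p$nominalValue, p$parameterId)
}
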