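# Core domain types.  Tables are stored as data.frames in a canonical typed
# form; the problem container is an S3 list.  Cheap structural invariants are
# enforced at construction; referential rules live in the linter
# (lint_problem), which must be able to inspect broken problems.

# Column registries: required columns in their documented order, then
# optional columns.  Any other column in measurement/observable/parameter/
# visualization tables is an extension column, preserved verbatim.  In the
# condition table every non-registry column is an override target, so the
# condition table has no extension columns.
.petab_columns <- list(
  condition = list(
    required = "conditionId",
    optional = "conditionName",
    open = TRUE
  ),
  measurement = list(
    required = c("observableId", "simulationConditionId", "measurement",
                 "time"),
    optional = c("preequilibrationConditionId", "observableParameters",
                 "noiseParameters", "datasetId", "replicateId"),
    open = FALSE
  ),
  observable = list(
    required = c("observableId", "observableFormula", "noiseFormula"),
    optional = c("observableName", "observableTransformation",
                 "noiseDistribution"),
    open = FALSE
  ),
  parameter = list(
    required = c("parameterId", "parameterScale", "lowerBound", "upperBound",
                 "estimate"),
    optional = c("parameterName", "nominalValue", "initializationPriorType",
                 "initializationPriorParameters"),
    open = FALSE
  ),
  visualization = list(
    required = c("plotId", "plotType", "yObservables"),
    optional = c("xVariable", "grouping", "xScale", "yScale", "xOffset",
                 "yOffset"),
    open = FALSE
  )
)

.numeric_columns <- list(
  condition = character(0),
  measurement = c("measurement", "time"),
  observable = character(0),
  parameter = c("lowerBound", "upperBound", "nominalValue", "estimate"),
  visualization = c("xOffset", "yOffset")
)

.parameter_scales <- c("lin", "log", "log10")
.observable_transformations <- c("lin", "log", "log10")
.noise_distributions <- c("normal", "laplace")
.prior_types <- c("uniform", "normal", "laplace", "logNormal",
                  "parameterScaleUniform", "parameterScaleNormal",
                  "parameterScaleLaplace")
.plot_types <- c("time_course", "dose_response")
.plot_groupings <- c("by_dataset_id", "by_simulation_condition",
                     "by_observable")

table_roles <- function() names(.petab_columns)

required_columns <- function(role) .petab_columns[[role]]$required

optional_columns <- function(role) .petab_columns[[role]]$optional

#' Split a semicolon-separated override cell into its entries
#'
#' Cells in the `observableParameters` and `noiseParameters` columns hold
#' semicolon-separated lists whose entries are numbers or parameter
#' identifiers.  An empty or missing cell yields an empty list.
#'
#' @param cell A single character value (may be `NA`).
#' @return A list whose elements are numerics or identifier strings.
#' @export
parse_override_list <- function(cell) {
  if (length(cell) != 1L) stop("parse_override_list expects a single cell")
  if (is.na(cell) || !nzchar(trimws(cell))) return(list())
  parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  lapply(parts, function(p) {
    num <- suppressWarnings(as.numeric(p))
    if (!is.na(num)) num else p
  })
}

#' @rdname parse_override_list
#' @param entries A list of numbers and identifier strings.
#' @return `format_override_list`: the cell text (empty string for none).
#' @export
format_override_list <- function(entries) {
  if (length(entries) == 0L) return("")
  paste(vapply(entries, function(e) {
    if (is.numeric(e)) format_petab_number(e) else as.character(e)
  }, character(1)), collapse = ";")
}

# Canonicalize a raw character data.frame for a role: coerce typed columns,
# normalize empty cells to NA, apply defaults for absent optional columns
# that have them.  Raises typed errors on unparseable cells.
.canonicalize_table <- function(df, role, source = "<memory>") {
  reg <- .petab_columns[[role]]
  if (is.null(reg)) petab_error("bad_role", sprintf("unknown table role '%s'", role))
  missing <- setdiff(reg$required, names(df))
  if (length(missing) > 0L) {
    petab_error("missing_required_column",
                sprintf("%s table %s lacks required column(s): %s",
                        role, source, paste(missing, collapse = ", ")),
                column = missing, role = role)
  }
  for (col in names(df)) {
    v <- as.character(df[[col]])
    v[!nzchar(trimws(v))] <- NA_character_
    v[!is.na(v) & trimws(tolower(v)) == "nan"] <- NA_character_
    df[[col]] <- v
  }
  for (col in intersect(.numeric_columns[[role]], names(df))) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    inf <- !is.na(raw) & tolower(trimws(raw)) %in% c("inf", "+inf")
    num[inf] <- Inf
    bad <- which(!is.na(raw) & is.na(num) & !inf)
    if (length(bad) > 0L) {
      petab_error("unparseable_cell",
                  sprintf("%s table %s: cannot parse '%s' in column '%s', row %d",
                          role, source, raw[bad[1]], col, bad[1]),
                  row = bad[1], column = col, raw = raw[bad[1]])
    }
    df[[col]] <- num
  }
  # defaults
  if (role == "observable") {
    if (!"observableTransformation" %in% names(df)) {
      df$observableTransformation <- rep("lin", nrow(df))
    }
    df$observableTransformation[is.na(df$observableTransformation)] <- "lin"
    if (!"noiseDistribution" %in% names(df)) {
      df$noiseDistribution <- rep("normal", nrow(df))
    }
    df$noiseDistribution[is.na(df$noiseDistribution)] <- "normal"
  }
  if (role == "visualization") {
    if (!"xVariable" %in% names(df)) df$xVariable <- rep("time", nrow(df))
    df$xVariable[is.na(df$xVariable)] <- "time"
    if (!"grouping" %in% names(df)) {
      df$grouping <- rep("by_simulation_condition", nrow(df))
    }
    df$grouping[is.na(df$grouping)] <- "by_simulation_condition"
    if (!"xScale" %in% names(df)) df$xScale <- rep("lin", nrow(df))
    if (!"yScale" %in% names(df)) df$yScale <- rep("lin", nrow(df))
    df$xScale[is.na(df$xScale)] <- "lin"
    df$yScale[is.na(df$yScale)] <- "lin"
    if (!"xOffset" %in% names(df)) df$xOffset <- rep(0, nrow(df))
    if (!"yOffset" %in% names(df)) df$yOffset <- rep(0, nrow(df))
    df$xOffset[is.na(df$xOffset)] <- 0
    df$yOffset[is.na(df$yOffset)] <- 0
  }
  id_col <- switch(role, condition = "conditionId",
                   observable = "observableId",
                   parameter = "parameterId", NULL)
  if (!is.null(id_col)) {
    ids <- df[[id_col]]
    if (anyDuplicated(ids)) {
      dup <- ids[duplicated(ids)][1]
      petab_error("duplicate_id",
                  sprintf("%s table %s: duplicate id '%s'", role, source, dup),
                  id = dup, role = role)
    }
  }
  ext <- if (reg$open) character(0) else {
    setdiff(names(df), c(reg$required, reg$optional))
  }
  attr(df, "extension_columns") <- ext
  rownames(df) <- NULL
  df
}

#' Assemble a PEtab problem container
#'
#' Bundles the model handle and the five tables into a `petab_problem`.
#' Tables may be passed as canonical data.frames (see [read_petab_table()])
#' or as raw character data.frames, which are canonicalized.  The container
#' is structural only: referential consistency is checked by
#' [lint_problem()] / [assert_petab_valid()], not here.
#'
#' @param model A `petab_sbml_model` from [load_sbml_model()], or `NULL`.
#' @param conditions,measurements,observables,parameters,visualization
#'   data.frames for the respective table roles (`visualization` may be
#'   `NULL`).
#' @param yaml_path Optional provenance path of the YAML problem file.
#' @return An object of class `petab_problem`.
#' @export
petab_problem <- function(model, conditions, measurements, observables,
                          parameters, visualization = NULL,
                          yaml_path = NULL) {
  conditions <- .canonicalize_table(conditions, "condition")
  measurements <- .canonicalize_table(measurements, "measurement")
  observables <- .canonicalize_table(observables, "observable")
  parameters <- .canonicalize_table(parameters, "parameter")
  if (!is.null(visualization) && nrow(visualization) > 0L) {
    visualization <- .canonicalize_table(visualization, "visualization")
  } else {
    visualization <- NULL
  }
  structure(list(model = model,
                 conditions = conditions,
                 measurements = measurements,
                 observables = observables,
                 parameters = parameters,
                 visualization = visualization,
                 yaml_path = yaml_path),
            class = "petab_problem")
}

#' @export
print.petab_problem <- function(x, ...) {
  cat("PEtab problem\n")
  if (!is.null(x$model)) {
    cat(sprintf("  model: %d species, %d parameters, %d reactions%s\n",
                nrow(x$model$species), length(x$model$parameters),
                length(x$model$reactions),
                if (x$model$simulation_supported) ""
                else " (not simulatable)"))
  } else {
    cat("  model: <none>\n")
  }
  cat(sprintf("  conditions:   %d\n", nrow(x$conditions)))
  cat(sprintf("  measurements: %d\n", nrow(x$measurements)))
  cat(sprintf("  observables:  %d\n", nrow(x$observables)))
  cat(sprintf("  parameters:   %d (%d estimated)\n", nrow(x$parameters),
              sum(x$parameters$estimate == 1, na.rm = TRUE)))
  if (!is.null(x$visualization)) {
    cat(sprintf("  plots:        %d\n",
                length(unique(x$visualization$plotId))))
  }
  invisible(x)
}

# Override target columns of the condition table (everything that is not
# the id/name column).
condition_targets <- function(conditions) {
  setdiff(names(conditions), c("conditionId", "conditionName"))
}

#' Construct a validation issue
#'
#' @param severity `"error"` or `"warning"`.
#' @param code Machine tag from the registry in [lint_rules()].
#' @param message Human-readable description.
#' @param role Table role (or `"problem"`).
#' @param location Row index or identifier the issue points at.
#' @return A one-row data.frame.
#' @export
petab_issue <- function(severity, code, message, role = "problem",
                        location = NA_character_) {
  stopifnot(severity %in% c("error", "warning"))
  data.frame(severity = severity, code = code, message = message,
             role = role, location = as.character(location),
             stringsAsFactors = FALSE)
}

.empty_issues <- function() {
  data.frame(severity = character(0), code = character(0),
             message = character(0), role = character(0),
             location = character(0), stringsAsFactors = FALSE)
}
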