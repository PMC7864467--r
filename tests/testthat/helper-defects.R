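# Seeded-defect harness for the lint rule registry: one surgical mutation
# per rule code, applied to a valid fixture problem.  Each mutation is
# expected to introduce exactly its own code and nothing else.

add_parameter_row <- function(problem, ...) {
  row <- data.frame(..., stringsAsFactors = FALSE)
  p <- problem$parameters
  for (col in setdiff(names(p), names(row))) row[[col]] <- NA
  for (col in setdiff(names(row), names(p))) p[[col]] <- NA
  problem$parameters <- rbind(p, row[names(p)])
  problem
}

lint_defects <- function() {
  basic <- function() generate_fixture("Basic simulation")$problem
  with_placeholders <- function() {
    generate_fixture(
      "Numeric observable parameter overrides in measurement table")$problem
  }
  log_case <- function() {
    generate_fixture("Observable transformations to log scale")$problem
  }
  list(
    INVALID_ID = function() {
      p <- basic()
      p$conditions <- rbind(p$conditions,
                            data.frame(conditionId = "1bad",
                                       stringsAsFactors = FALSE))
      p
    },
    DUPLICATE_ID = function() {
      p <- basic()
      p$parameters <- rbind(p$parameters, p$parameters[1, ])
      p
    },
    REF_CONDITION = function() {
      p <- basic()
      p$measurements$simulationConditionId[1] <- "c_missing"
      p
    },
    REF_OBSERVABLE = function() {
      p <- basic()
      p$measurements$observableId[1] <- "obs_missing"
      p
    },
    CONDITION_TARGET = function() {
      p <- basic()
      p$conditions$not_an_entity <- "1.5"
      p
    },
    FORMULA_SYNTAX = function() {
      p <- basic()
      p$observables$noiseFormula[1] <- "1 +"
      p
    },
    PLACEHOLDER_ARITY = function() {
      p <- with_placeholders()
      p$measurements$observableParameters[1] <- "0.7"
      p
    },
    PARAMETER_COVERAGE = function() {
      p <- basic()
      p$observables$observableFormula[1] <- "B * undefined_p"
      p
    },
    UNUSED_PARAMETER = function() {
      add_parameter_row(basic(), parameterId = "extra_p",
                        parameterScale = "lin", lowerBound = 0,
                        upperBound = 1, nominalValue = 0.5, estimate = 1)
    },
    BOUNDS_ORDER = function() {
      p <- basic()
      p$parameters$lowerBound[1] <- 200
      p$parameters$nominalValue[1] <- NA
      p
    },
    BOUNDS_LOG_POSITIVE = function() {
      p <- basic()
      p$parameters$parameterScale[1] <- "log10"
      p$parameters$lowerBound[1] <- -1
      p
    },
    ESTIMATE_FLAG = function() {
      p <- basic()
      p$parameters$estimate[1] <- 2
      p
    },
    BAD_SCALE = function() {
      p <- basic()
      p$parameters$parameterScale[1] <- "log2"
      p
    },
    BAD_TRANSFORMATION = function() {
      p <- basic()
      p$observables$observableTransformation[1] <- "exp"
      p
    },
    BAD_DISTRIBUTION = function() {
      p <- basic()
      p$observables$noiseDistribution[1] <- "cauchy"
      p
    },
    NEGATIVE_TIME = function() {
      p <- basic()
      p$measurements$time[1] <- -1
      p
    },
    MEASUREMENT_NOT_FINITE = function() {
      p <- basic()
      p$measurements$measurement[1] <- NA_real_
      p
    },
    LOG_MEASUREMENT_POSITIVE = function() {
      p <- log_case()
      p$measurements$measurement[1] <- -0.5
      p
    },
    PRIOR_PARAMETERS = function() {
      p <- basic()
      p$parameters$initializationPriorType <- c("normal", NA)
      p$parameters$initializationPriorParameters <- c("0.1", NA)
      p
    },
    NOMINAL_MISSING = function() {
      p <- generate_fixture(
        "Parametric observable parameter overrides in measurement table")$problem
      i <- which(p$parameters$parameterId == "offset_p")
      p$parameters$nominalValue[i] <- NA
      p
    },
    NOMINAL_OUT_OF_BOUNDS = function() {
      p <- basic()
      p$parameters$nominalValue[1] <- 1000
      p
    },
    REF_VISUALIZATION = function() {
      p <- basic()
      p$visualization <- petabkit:::.canonicalize_table(
        data.frame(plotId = "p1", plotType = "time_course",
                   yObservables = "obs_missing", stringsAsFactors = FALSE),
        "visualization")
      p
    },
    VIS_PLOT_TYPE = function() {
      p <- basic()
      p$visualization <- petabkit:::.canonicalize_table(
        data.frame(plotId = "p1", plotType = "waterfall",
                   yObservables = "obs_b", stringsAsFactors = FALSE),
        "visualization")
      p
    })
}
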