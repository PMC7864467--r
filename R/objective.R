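# Observation-model evaluation and objective functions: residuals on the
# observable's transformation scale, chi-square, and the negative
# log-likelihood under normal or Laplace noise on lin/log/log10 scales.
# Priors drive startpoint sampling only; they are not added to the
# objective.

#' Evaluate an observable formula
#'
#' @param observable One row of the observable table (data.frame or list).
#' @param state Named list/vector with species, parameter and `time` values
#'   at the measurement time.
#' @param overrides Named list binding placeholder symbols
#'   (`observableParameter{n}_<id>`, `noiseParameter{n}_<id>`) for the
#'   measurement.
#' @return The simulated observable value on linear scale.
#' @export
evaluate_observable <- function(observable, state, overrides = list()) {
  env <- utils::modifyList(as.list(state), as.list(overrides))
  evaluate_expression(observable$observableFormula[[1]], env)
}

#' Standardized residual on the observable's transformation scale
#'
#' `r = (T(y) - T(yhat)) / sigma` with `T` the identity, natural log or
#' base-10 log; for the log scales `sigma` is interpreted on the
#' transformed scale.
#'
#' @param y Measured value.
#' @param yhat Simulated observable value.
#' @param sigma Noise standard deviation (scale parameter for Laplace).
#' @param transformation `"lin"`, `"log"` or `"log10"`.
#' @return Numeric scalar.
#' @export
petab_residual <- function(y, yhat, sigma, transformation = "lin") {
  if (sigma <= 0) {
    petab_error("domain", sprintf("sigma must be positive, got %g", sigma),
                op = "residual", value = sigma)
  }
  tr <- switch(transformation,
    lin = identity,
    log = function(x) .checked_log(x, exp(1)),
    log10 = function(x) .checked_log(x, 10),
    petab_error("bad_scale",
                sprintf("unknown transformation '%s'", transformation)))
  (tr(y) - tr(yhat)) / sigma
}

# Negative log-density of one measurement under its noise model.
.point_nllh <- function(y, yhat, sigma, transformation, distribution) {
  if (sigma <= 0) {
    petab_error("domain", sprintf("sigma must be positive, got %g", sigma),
                op = "nllh", value = sigma)
  }
  r <- petab_residual(y, yhat, sigma, transformation)
  if (distribution == "normal") {
    jacobian <- switch(transformation,
      lin = 0,
      log = log(y),
      log10 = log(y) + log(log(10)))
    0.5 * log(2 * pi * sigma^2) + jacobian + 0.5 * r^2
  } else if (distribution == "laplace") {
    jacobian <- switch(transformation,
      lin = 0,
      log = log(y),
      log10 = log(y) + log(log(10)))
    log(2 * sigma) + jacobian + abs(r)
  } else {
    petab_error("bad_distribution",
                sprintf("unknown noise distribution '%s'", distribution))
  }
}

# Per-measurement records (yhat, sigma, transformation, distribution) from
# a simulation table.  The simulation table must mirror the measurement
# table row-for-row (same identifying columns in the same order), as
# produced by simulate_problem() or by an external tool following the
# simulation-table convention.
.simulation_records <- function(problem, simulations) {
  m <- problem$measurements
  if (nrow(simulations) != nrow(m)) {
    petab_error("bad_simulation_table",
                sprintf("simulation table has %d rows, measurement table %d",
                        nrow(simulations), nrow(m)))
  }
  if (!"simulation" %in% names(simulations)) {
    petab_error("bad_simulation_table",
                "simulation table lacks a 'simulation' column")
  }
  for (col in c("observableId", "simulationConditionId", "time")) {
    if (col %in% names(simulations) &&
        !isTRUE(all(simulations[[col]] == m[[col]] |
                    (is.na(simulations[[col]]) & is.na(m[[col]]))))) {
      petab_error("bad_simulation_table",
                  sprintf("simulation table column '%s' does not mirror the measurement table",
                          col))
    }
  }
  sigma <- attr(simulations, "sigma")
  param_values <- as.list(nominal_free_values(problem))
  if (nrow(m) == 0L) {
    return(data.frame(row = integer(0), y = numeric(0), yhat = numeric(0),
                      sigma = numeric(0), transformation = character(0),
                      distribution = character(0), stringsAsFactors = FALSE))
  }
  records <- data.frame(row = seq_len(nrow(m)),
                        y = m$measurement,
                        yhat = as.numeric(simulations$simulation),
                        sigma = NA_real_,
                        transformation = NA_character_,
                        distribution = NA_character_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    orow <- problem$observables[
      problem$observables$observableId == m$observableId[i], , drop = FALSE]
    if (nrow(orow) == 0L) {
      petab_error("unresolved_symbol",
                  sprintf("measurement row %d references unknown observable '%s'",
                          i, m$observableId[i]),
                  id = m$observableId[i], where = "measurement table")
    }
    records$transformation[i] <- orow$observableTransformation[1]
    records$distribution[i] <- orow$noiseDistribution[1]
    if (!is.null(sigma) && !is.na(sigma[i])) {
      records$sigma[i] <- sigma[i]
      next
    }
    env <- param_values
    k <- placeholder_count(orow[1, ], "noise")
    if (k > 0L) {
      cell <- if ("noiseParameters" %in% names(m)) m$noiseParameters[i]
              else NA_character_
      entries <- parse_override_list(cell)
      if (length(entries) != k) {
        petab_error("unresolved_symbol",
                    sprintf("measurement row %d: noiseParameters cell has %d entries, formula uses %d",
                            i, length(entries), k),
                    id = orow$observableId[1], where = "noiseParameters")
      }
      for (n in seq_len(k)) {
        sym <- sprintf("noiseParameter%d_%s", n, orow$observableId[1])
        e <- entries[[n]]
        env[[sym]] <- if (is.numeric(e)) e else {
          v <- param_values[[e]]
          if (is.null(v) || is.na(v)) {
            petab_error("unresolved_symbol",
                        sprintf("noise parameter '%s' has no value", e),
                        id = e, where = "noiseParameters")
          }
          v
        }
      }
    }
    env[[orow$observableId[1]]] <- records$yhat[i]
    records$sigma[i] <- evaluate_expression(orow$noiseFormula[1], env)
  }
  records
}

#' Chi-square objective
#'
#' Sum of squared standardized residuals over all measurements, each on its
#' observable's transformation scale.
#'
#' @param problem A `petab_problem`.
#' @param simulations Simulation table mirroring the measurement table with
#'   a `simulation` column (see [simulate_problem()]).
#' @return Numeric scalar.
#' @export
petab_chi2 <- function(problem, simulations) {
  rec <- .simulation_records(problem, simulations)
  if (nrow(rec) == 0L) return(0)
  sum(vapply(seq_len(nrow(rec)), function(i) {
    petab_residual(rec$y[i], rec$yhat[i], rec$sigma[i],
                   rec$transformation[i])^2
  }, numeric(1)))
}

#' Negative log-likelihood objective
#'
#' Sum over measurements of the negative log-density of the observed value
#' under the observable's noise model.  On log and log10 scales the density
#' is a density in the measured value itself (the change-of-variables term
#' is included), so it integrates to one over the data support.
#'
#' @inheritParams petab_chi2
#' @return Numeric scalar.
#' @export
petab_nllh <- function(problem, simulations) {
  rec <- .simulation_records(problem, simulations)
  if (nrow(rec) == 0L) return(0)
  sum(vapply(seq_len(nrow(rec)), function(i) {
    .point_nllh(rec$y[i], rec$yhat[i], rec$sigma[i], rec$transformation[i],
                rec$distribution[i])
  }, numeric(1)))
}

#' Chi-square, likelihood and residual table in one call
#'
#' @inheritParams petab_chi2
#' @return A list with elements `chi2`, `nllh` and `residuals` (one row per
#'   measurement: `row`, `y`, `yhat`, `sigma`, `transformation`,
#'   `distribution`, `residual`).
#' @export
petab_calculate <- function(problem, simulations = NULL) {
  if (is.null(simulations)) simulations <- simulate_problem(problem)
  rec <- .simulation_records(problem, simulations)
  rec$residual <- vapply(seq_len(nrow(rec)), function(i) {
    petab_residual(rec$y[i], rec$yhat[i], rec$sigma[i],
                   rec$transformation[i])
  }, numeric(1))
  nllh <- if (nrow(rec) == 0L) 0 else {
    sum(vapply(seq_len(nrow(rec)), function(i) {
      .point_nllh(rec$y[i], rec$yhat[i], rec$sigma[i], rec$transformation[i],
                  rec$distribution[i])
    }, numeric(1)))
  }
  list(chi2 = sum(rec$residual^2), nllh = nllh, residuals = rec)
}

# ---- startpoint sampling ---------------------------------------------------

.sample_laplace <- function(n, location, scale) {
  u <- stats::runif(n) - 0.5
  location - scale * sign(u) * log(1 - 2 * abs(u))
}

#' Sample startpoints for parameter estimation
#'
#' Draws `n` startpoint vectors for the estimated parameters on their
#' estimation scales.  Parameters with an initialization prior are sampled
#' from it (`parameterScale*` priors act directly on the estimation scale,
#' the others on the linear scale, then transformed); parameters without a
#' prior are sampled uniformly on their scaled bounds.  All draws are
#' clipped to the scaled bounds.
#'
#' @param problem A `petab_problem`.
#' @param n Number of startpoints.
#' @param seed Integer seed; the same seed yields the same matrix.
#' @return An `n` by `n_free` matrix, columns named by parameter id.
#' @export
sample_startpoints <- function(problem, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  free <- get_free_parameters(problem)
  p <- problem$parameters[problem$parameters$estimate == 1, , drop = FALSE]
  out <- matrix(NA_real_, nrow = n, ncol = nrow(free),
                dimnames = list(NULL, free$parameterId))
  for (j in seq_len(nrow(free))) {
    sc <- free$parameterScale[j]
    lb <- free$lowerBound[j]
    ub <- free$upperBound[j]
    type <- if ("initializationPriorType" %in% names(p)) {
      p$initializationPriorType[j]
    } else NA_character_
    pars <- if ("initializationPriorParameters" %in% names(p)) {
      unlist(parse_override_list(p$initializationPriorParameters[j]))
    } else NULL
    # linear-scale draws must be floored before a log transform
    to_scale <- function(x) {
      if (sc != "lin") x <- pmax(x, 1e-300)
      petab_scale(x, sc)
    }
    draws <- if (is.na(type)) {
      stats::runif(n, lb, ub)
    } else {
      switch(type,
        uniform = to_scale(stats::runif(n, pars[1], pars[2])),
        normal = to_scale(stats::rnorm(n, pars[1], pars[2])),
        laplace = to_scale(.sample_laplace(n, pars[1], pars[2])),
        logNormal = to_scale(stats::rlnorm(n, pars[1], pars[2])),
        parameterScaleUniform = stats::runif(n,
          if (length(pars) >= 2) pars[1] else lb,
          if (length(pars) >= 2) pars[2] else ub),
        parameterScaleNormal = stats::rnorm(n, pars[1], pars[2]),
        parameterScaleLaplace = .sample_laplace(n, pars[1], pars[2]),
        petab_error("bad_prior", sprintf("unknown prior type '%s'", type)))
    }
    out[, j] <- pmin(pmax(draws, lb), ub)
  }
  out
}
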