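# Generator for the sixteen toy test-problem categories, each bundled with
# analytic reference values.  All cases share one base model, the
# reversible conversion A <-> B (mass action, rates k1, k2), whose linear
# ODE admits exact closed forms for every semantics variant, including
# steady-state pre-equilibration:
#   A(t) = s + (A0 - s) * exp(-(k1 + k2) * t),  s = k2 * (A0 + B0) / (k1 + k2)
#   B(t) = (A0 + B0) - A(t)
# Expected simulations, chi-square and negative log-likelihood are computed
# here from these closed forms and from textbook densities (dnorm-based),
# deliberately NOT from the package's simulator or objective code, so the
# fixtures are an independent acceptance surface.

.fixture_names <- c(
  "Basic simulation",
  "Multiple simulation conditions",
  "Numeric initial compartment sizes in condition table",
  "Numeric initial concentration in condition table",
  "Numeric noise parameter overrides in measurement table",
  "Numeric observable parameter overrides in measurement table",
  "Observable transformations to log scale",
  "Observable transformations to log10 scale",
  "Parametric initial concentrations in condition table",
  "Parametric noise parameter overrides in measurement table",
  "Parametric observable parameter overrides in measurement table",
  "Parametric overrides in condition table",
  "Partial pre-equilibration",
  "Pre-equilibration",
  "Replicate measurements",
  "Time-point specific overrides in the measurement table")

#' Names of the generated test-problem categories
#' @return Character vector of the sixteen case names.
#' @export
fixture_names <- function() .fixture_names

# ---- closed forms ----------------------------------------------------------

.conv_A <- function(t, k1, k2, A0, B0) {
  s <- k2 * (A0 + B0) / (k1 + k2)
  s + (A0 - s) * exp(-(k1 + k2) * t)
}

.conv_B <- function(t, k1, k2, A0, B0) {
  (A0 + B0) - .conv_A(t, k1, k2, A0, B0)
}

.conv_steady <- function(k1, k2, A0, B0) {
  total <- A0 + B0
  c(A = k2 * total / (k1 + k2), B = k1 * total / (k1 + k2))
}

# Oracle negative log-density, via stats densities + change of variables
# (distinct route from the objective module's explicit formulas).
.oracle_point_nllh <- function(y, yhat, sigma, transformation, distribution) {
  dlaplace <- function(x, m, b) exp(-abs(x - m) / b) / (2 * b)
  dens <- switch(distribution,
    normal = switch(transformation,
      lin = stats::dnorm(y, yhat, sigma),
      log = stats::dnorm(log(y), log(yhat), sigma) / y,
      log10 = stats::dnorm(log10(y), log10(yhat), sigma) / (y * log(10))),
    laplace = switch(transformation,
      lin = dlaplace(y, yhat, sigma),
      log = dlaplace(log(y), log(yhat), sigma) / y,
      log10 = dlaplace(log10(y), log10(yhat), sigma) / (y * log(10))))
  -log(dens)
}

.oracle_chi2 <- function(y, yhat, sigma, transformation) {
  tr <- switch(transformation, lin = identity, log = log, log10 = log10)
  sum(((tr(y) - tr(yhat)) / sigma)^2)
}

# ---- SBML text for the conversion model ------------------------------------

conversion_model_sbml <- function(k1 = 0.8, k2 = 0.6, A0 = 1, B0 = 0,
                                  compartment_size = 1) {
  rate <- function(k, s) paste0(
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    "<apply><times/><ci>compartment</ci><ci>", k, "</ci><ci>", s,
    "</ci></apply></math>")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
    '  <model id="conversion_reaction">\n',
    '    <listOfCompartments>\n',
    sprintf('      <compartment id="compartment" size="%s"/>\n',
            format_petab_number(compartment_size)),
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n',
    sprintf('      <species id="A" compartment="compartment" initialConcentration="%s"/>\n',
            format_petab_number(A0)),
    sprintf('      <species id="B" compartment="compartment" initialConcentration="%s"/>\n',
            format_petab_number(B0)),
    '    </listOfSpecies>\n',
    '    <listOfParameters>\n',
    sprintf('      <parameter id="k1" value="%s"/>\n',
            format_petab_number(k1)),
    sprintf('      <parameter id="k2" value="%s"/>\n',
            format_petab_number(k2)),
    '    </listOfParameters>\n',
    '    <listOfReactions>\n',
    '      <reaction id="fwd" reversible="false">\n',
    '        <listOfReactants><speciesReference species="A"/></listOfReactants>\n',
    '        <listOfProducts><speciesReference species="B"/></listOfProducts>\n',
    '        <kineticLaw>', rate("k1", "A"), '</kineticLaw>\n',
    '      </reaction>\n',
    '      <reaction id="rev" reversible="false">\n',
    '        <listOfReactants><speciesReference species="B"/></listOfReactants>\n',
    '        <listOfProducts><speciesReference species="A"/></listOfProducts>\n',
    '        <kineticLaw>', rate("k2", "B"), '</kineticLaw>\n',
    '      </reaction>\n',
    '    </listOfReactions>\n',
    '  </model>\n',
    '</sbml>\n')
}

load_conversion_model <- function(...) {
  path <- tempfile("conversion_", fileext = ".xml")
  writeLines(conversion_model_sbml(...), path, useBytes = TRUE)
  on.exit(unlink(path))
  model <- load_sbml_model(path)
  model
}

# ---- case construction helpers ---------------------------------------------

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

.df <- function(...) data.frame(..., stringsAsFactors = FALSE,
                                check.names = FALSE)

.default_parameters <- function(extra = NULL) {
  base <- .df(parameterId = c("k1", "k2"),
              parameterScale = "lin",
              lowerBound = 0.01, upperBound = 100,
              nominalValue = c(0.8, 0.6),
              estimate = c(1, 1))
  if (is.null(extra)) return(base)
  cols <- union(names(base), names(extra))
  for (col in setdiff(cols, names(base))) base[[col]] <- NA
  for (col in setdiff(cols, names(extra))) extra[[col]] <- NA
  rbind(base[cols], extra[cols])
}

.obs_table <- function(formula = "B", noise = "1", transformation = "lin",
                       distribution = "normal") {
  .df(observableId = "obs_b",
      observableFormula = formula,
      noiseFormula = noise,
      observableTransformation = transformation,
      noiseDistribution = distribution)
}

# Assemble a fixture from its ingredients plus oracle-computed expectations.
.make_fixture <- function(name, conditions, measurements, observables,
                          parameters, yhat, sigma, seed,
                          model_args = list()) {
  model <- do.call(load_conversion_model, model_args)
  trans <- stats::setNames(observables$observableTransformation,
                           observables$observableId)
  dist <- stats::setNames(observables$noiseDistribution,
                          observables$observableId)
  tr_row <- trans[measurements$observableId]
  di_row <- dist[measurements$observableId]
  chi2 <- sum(vapply(seq_len(nrow(measurements)), function(i) {
    .oracle_chi2(measurements$measurement[i], yhat[i], sigma[i], tr_row[i])
  }, numeric(1)))
  nllh <- sum(vapply(seq_len(nrow(measurements)), function(i) {
    .oracle_point_nllh(measurements$measurement[i], yhat[i], sigma[i],
                       tr_row[i], di_row[i])
  }, numeric(1)))
  problem <- petab_problem(model = model, conditions = conditions,
                           measurements = measurements,
                           observables = observables,
                           parameters = parameters)
  structure(list(name = name, problem = problem,
                 expected_simulations = yhat, expected_sigma = sigma,
                 expected_chi2 = chi2, expected_nllh = nllh,
                 tolerance = 1e-6, seed = seed),
            class = "petab_fixture")
}

#' @export
print.petab_fixture <- function(x, ...) {
  cat(sprintf("Fixture '%s': %d measurements, chi2 = %.6g, nllh = %.6g\n",
              x$name, nrow(x$problem$measurements), x$expected_chi2,
              x$expected_nllh))
  invisible(x)
}

# ---- the sixteen cases -----------------------------------------------------

#' Generate one toy test problem with analytic reference values
#'
#' Each case is a complete, valid problem built on the reversible
#' conversion model A <-> B, together with expected simulated values,
#' chi-square and negative log-likelihood derived from the model's closed
#' form (never from the package's simulator or objective code).
#' Measurement values are the closed-form outputs plus reproducible
#' pseudo-random perturbations.
#'
#' @param name One of [fixture_names()].
#' @param seed Integer seed for the measurement perturbations.
#' @return An object of class `petab_fixture` with elements `name`,
#'   `problem`, `expected_simulations`, `expected_sigma`, `expected_chi2`,
#'   `expected_nllh`, `tolerance`.
#' @export
generate_fixture <- function(name, seed = 20210126L) {
  idx <- match(name, .fixture_names)
  if (is.na(idx)) {
    petab_error("unknown_case", sprintf("unknown fixture case '%s'", name))
  }
  .with_seed(seed + idx, .build_fixture(name, seed + idx))
}

.build_fixture <- function(name, seed) {
  k1 <- 0.8; k2 <- 0.6
  times <- c(0, 1, 2, 5, 10)
  noisy_lin <- function(yhat, sd = 0.1) yhat + stats::rnorm(length(yhat), 0, sd)
  noisy_log <- function(yhat, sd = 0.1) yhat * exp(stats::rnorm(length(yhat), 0, sd))

  if (name == "Basic simulation") {
    yhat <- .conv_B(times, k1, k2, 1, 0)
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat), time = times)
    return(.make_fixture(name, .df(conditionId = "c0"), meas, .obs_table(),
                         .default_parameters(), yhat,
                         rep(1, length(times)), seed))
  }

  if (name == "Multiple simulation conditions") {
    t2 <- c(1, 2, 5)
    k1_c1 <- 1.2
    yhat <- c(.conv_B(t2, k1, k2, 1, 0), .conv_B(t2, k1_c1, k2, 1, 0))
    conditions <- .df(conditionId = c("c0", "c1"),
                      k1 = format_petab_number(c(k1, k1_c1)))
    meas <- .df(observableId = "obs_b",
                simulationConditionId = rep(c("c0", "c1"), each = 3),
                measurement = noisy_lin(yhat), time = rep(t2, 2))
    return(.make_fixture(name, conditions, meas, .obs_table(),
                         .default_parameters(), yhat, rep(1, 6), seed))
  }

  if (name == "Numeric initial compartment sizes in condition table") {
    # concentration dynamics are volume-invariant for this model; the case
    # exercises the compartment-target override path
    yhat <- .conv_B(times, k1, k2, 1, 0)
    conditions <- .df(conditionId = "c0", compartment = "2")
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat), time = times)
    return(.make_fixture(name, conditions, meas, .obs_table(),
                         .default_parameters(), yhat,
                         rep(1, length(times)), seed))
  }

  if (name == "Numeric initial concentration in condition table") {
    yhat <- .conv_B(times, k1, k2, 2, 0)
    conditions <- .df(conditionId = "c0", A = "2")
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat), time = times)
    return(.make_fixture(name, conditions, meas, .obs_table(),
                         .default_parameters(), yhat,
                         rep(1, length(times)), seed))
  }

  if (name == "Numeric noise parameter overrides in measurement table") {
    yhat <- .conv_B(times, k1, k2, 1, 0)
    sigma <- c(0.5, 0.4, 0.3, 0.2, 0.5)
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat), time = times,
                noiseParameters = format_petab_number(sigma))
    obs <- .obs_table(noise = "noiseParameter1_obs_b")
    return(.make_fixture(name, .df(conditionId = "c0"), meas, obs,
                         .default_parameters(), yhat, sigma, seed))
  }

  if (name == "Numeric observable parameter overrides in measurement table") {
    scaling <- 0.7; offset <- 0.1
    yhat <- scaling * .conv_B(times, k1, k2, 1, 0) + offset
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat), time = times,
                observableParameters = paste(format_petab_number(scaling),
                                             format_petab_number(offset),
                                             sep = ";"))
    obs <- .obs_table(
      formula = "observableParameter1_obs_b * B + observableParameter2_obs_b")
    return(.make_fixture(name, .df(conditionId = "c0"), meas, obs,
                         .default_parameters(), yhat,
                         rep(1, length(times)), seed))
  }

  if (name %in% c("Observable transformations to log scale",
                  "Observable transformations to log10 scale")) {
    trans <- if (grepl("log10", name)) "log10" else "log"
    tpos <- c(1, 2, 5, 10)        # B(0) = 0 is outside the log domain
    sigma <- rep(0.3, length(tpos))
    yhat <- .conv_B(tpos, k1, k2, 1, 0)
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_log(yhat), time = tpos)
    obs <- .obs_table(noise = "0.3", transformation = trans)
    return(.make_fixture(name, .df(conditionId = "c0"), meas, obs,
                         .default_parameters(), yhat, sigma, seed))
  }

  if (name == "Parametric initial concentrations in condition table") {
    A0 <- 2
    yhat <- .conv_B(times, k1, k2, A0, 0)
    conditions <- .df(conditionId = "c0", A = "initial_a")
    params <- .default_parameters(.df(parameterId = "initial_a",
                                      parameterScale = "lin",
                                      lowerBound = 0.1, upperBound = 10,
                                      nominalValue = A0, estimate = 1))
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat), time = times)
    return(.make_fixture(name, conditions, meas, .obs_table(), params, yhat,
                         rep(1, length(times)), seed))
  }

  if (name == "Parametric noise parameter overrides in measurement table") {
    sigma_val <- 0.3
    yhat <- .conv_B(times, k1, k2, 1, 0)
    params <- .default_parameters(.df(parameterId = "noise_p",
                                      parameterScale = "log10",
                                      lowerBound = 1e-3, upperBound = 10,
                                      nominalValue = sigma_val,
                                      estimate = 1))
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat, 0.05), time = times,
                noiseParameters = "noise_p")
    obs <- .obs_table(noise = "noiseParameter1_obs_b")
    return(.make_fixture(name, .df(conditionId = "c0"), meas, obs, params,
                         yhat, rep(sigma_val, length(times)), seed))
  }

  if (name == "Parametric observable parameter overrides in measurement table") {
    scaling <- 0.7; offset <- 0.1
    yhat <- scaling * .conv_B(times, k1, k2, 1, 0) + offset
    params <- .default_parameters(
      .df(parameterId = c("scaling_p", "offset_p"),
          parameterScale = "lin",
          lowerBound = c(0.01, 0), upperBound = c(10, 1),
          nominalValue = c(scaling, offset),
          estimate = c(1, 0)))
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat), time = times,
                observableParameters = "scaling_p;offset_p")
    obs <- .obs_table(
      formula = "observableParameter1_obs_b * B + observableParameter2_obs_b")
    return(.make_fixture(name, .df(conditionId = "c0"), meas, obs, params,
                         yhat, rep(1, length(times)), seed))
  }

  if (name == "Parametric overrides in condition table") {
    k1_eff <- 1.1
    yhat <- .conv_B(times, k1_eff, k2, 1, 0)
    conditions <- .df(conditionId = "c0", k1 = "rate_p")
    params <- .default_parameters(.df(parameterId = "rate_p",
                                      parameterScale = "lin",
                                      lowerBound = 0.01, upperBound = 100,
                                      nominalValue = k1_eff, estimate = 1))
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat), time = times)
    return(.make_fixture(name, conditions, meas, .obs_table(), params, yhat,
                         rep(1, length(times)), seed))
  }

  if (name == "Partial pre-equilibration") {
    # equilibrate under c0 (A = 1, B = 0, k1 = 0.8), then switch to c1:
    # A reinitialized to 1, B carried over from equilibrium, k1 = 0.9
    k1_sim <- 0.9
    eq <- .conv_steady(k1, k2, 1, 0)
    yhat <- .conv_B(times, k1_sim, k2, 1, eq[["B"]])
    conditions <- .df(conditionId = c("c0", "c1"),
                      k1 = format_petab_number(c(k1, k1_sim)),
                      A = c("1", "1"),
                      B = c("0", NA))
    meas <- .df(observableId = "obs_b",
                preequilibrationConditionId = "c0",
                simulationConditionId = "c1",
                measurement = noisy_lin(yhat), time = times)
    return(.make_fixture(name, conditions, meas, .obs_table(),
                         .default_parameters(), yhat,
                         rep(1, length(times)), seed))
  }

  if (name == "Pre-equilibration") {
    # equilibrate under c0, carry the whole state, simulate under k1 = 1.2
    k1_sim <- 1.2
    eq <- .conv_steady(k1, k2, 1, 0)
    yhat <- .conv_B(times, k1_sim, k2, eq[["A"]], eq[["B"]])
    conditions <- .df(conditionId = c("c0", "c1"),
                      k1 = format_petab_number(c(k1, k1_sim)))
    meas <- .df(observableId = "obs_b",
                preequilibrationConditionId = "c0",
                simulationConditionId = "c1",
                measurement = noisy_lin(yhat), time = times)
    return(.make_fixture(name, conditions, meas, .obs_table(),
                         .default_parameters(), yhat,
                         rep(1, length(times)), seed))
  }

  if (name == "Replicate measurements") {
    t_rep <- c(1, 1, 2, 2, 5)
    yhat <- .conv_B(t_rep, k1, k2, 1, 0)
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat), time = t_rep,
                replicateId = c("r1", "r2", "r1", "r2", "r1"))
    return(.make_fixture(name, .df(conditionId = "c0"), meas, .obs_table(),
                         .default_parameters(), yhat,
                         rep(1, length(t_rep)), seed))
  }

  if (name == "Time-point specific overrides in the measurement table") {
    scalings <- c(0.7, 0.7, 1.0, 1.0)
    offsets <- c(0.1, 0.1, 0, 0)
    tt <- c(1, 2, 5, 10)
    yhat <- scalings * .conv_B(tt, k1, k2, 1, 0) + offsets
    sigma <- c(0.5, 0.5, 0.2, 0.2)
    meas <- .df(observableId = "obs_b", simulationConditionId = "c0",
                measurement = noisy_lin(yhat), time = tt,
                observableParameters = paste(format_petab_number(scalings),
                                             format_petab_number(offsets),
                                             sep = ";"),
                noiseParameters = format_petab_number(sigma))
    obs <- .obs_table(
      formula = "observableParameter1_obs_b * B + observableParameter2_obs_b",
      noise = "noiseParameter1_obs_b")
    return(.make_fixture(name, .df(conditionId = "c0"), meas, obs,
                         .default_parameters(), yhat, sigma, seed))
  }

  petab_error("unknown_case", sprintf("unknown fixture case '%s'", name))
}

#' Generate all sixteen fixture cases
#'
#' @param seed Base integer seed; per-case seeds are derived from it, so
#'   the same seed reproduces every case byte-for-byte.
#' @return Named list of `petab_fixture` objects.
#' @export
generate_all_fixtures <- function(seed = 20210126L) {
  out <- lapply(.fixture_names, generate_fixture, seed = seed)
  names(out) <- .fixture_names
  out
}

#' Write a fixture case to disk as a loadable problem
#'
#' Emits the standard problem directory (SBML + tables + YAML) plus an
#' `expected.tsv` holding the reference chi-square, negative
#' log-likelihood and per-row simulated values.
#'
#' @param fixture A `petab_fixture`.
#' @param directory Output directory.
#' @return The YAML path, invisibly.
#' @export
write_fixture <- function(fixture, directory) {
  yaml_path <- save_petab_problem(fixture$problem, directory)
  expected <- .df(chi2 = rep(fixture$expected_chi2,
                             length(fixture$expected_simulations)),
                  llh = rep(-fixture$expected_nllh,
                            length(fixture$expected_simulations)),
                  simulation = fixture$expected_simulations)
  utils::write.table(expected, file.path(directory, "expected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(yaml_path)
}
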