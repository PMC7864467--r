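# Reference ODE simulator for the restricted SBML subset, with steady-state
# pre-equilibration and partial state reinitialization.  Integration uses
# deSolve::lsoda at tight tolerances (rtol 1e-8, atol 1e-12 by default) so
# fixture trajectories can be compared against closed forms at 1e-6.

.default_rtol <- 1e-8
.default_atol <- 1e-12

# Build the deSolve rate function for a model under one materialized
# (fully numeric) entity map.
.make_rate_fn <- function(sys, map_values, dynamic) {
  fixed <- as.list(map_values[setdiff(names(map_values), dynamic)])
  langs <- sys$rhs_lang[dynamic]
  function(t, y, parms) {
    env <- list2env(fixed)
    for (s in dynamic) assign(s, y[[s]], envir = env)
    assign("time", t, envir = env)
    list(vapply(dynamic, function(s) eval(langs[[s]], env), numeric(1)))
  }
}

.initial_state <- function(sys, map_values) {
  miss <- setdiff(sys$species, names(map_values))
  if (length(miss) > 0L) {
    petab_error("unresolved_symbol",
                sprintf("no initial value for species %s",
                        paste(miss, collapse = ", ")),
                id = miss[1], where = "initial state")
  }
  map_values[sys$species]
}

#' Find the steady state of a model under one condition
#'
#' Integrates over geometrically growing horizons until the right-hand side
#' satisfies `max|dx/dt| < atol + rtol * max|x|`, or fails once the horizon
#' exceeds `t_max`.
#'
#' @param model A simulatable `petab_sbml_model`.
#' @param map_values Named numeric vector: fully materialized entity map for
#'   the condition (see [resolve_mapping()] and the `free_values` argument
#'   of [simulate_problem()]).
#' @param atol,rtol Steady-state tolerances (absolute / relative).
#' @param t_max Give up beyond this horizon.
#' @param state Optional start state overriding the mapped initial values.
#' @return Named numeric vector of steady-state species values.
#' @export
find_steady_state <- function(model, map_values, atol = 1e-10, rtol = 1e-8,
                              t_max = 1e10, state = NULL) {
  sys <- model_ode_system(model)
  rate_fn <- .make_rate_fn(sys, map_values, sys$species)
  y <- if (is.null(state)) .initial_state(sys, map_values) else state[sys$species]
  converged <- function(y, t) {
    dy <- rate_fn(t, as.list(y), NULL)[[1]]
    max(abs(dy)) < atol + rtol * max(abs(y))
  }
  if (converged(y, 0)) return(y)
  horizon <- 100
  t_now <- 0
  while (t_now < t_max) {
    t_end <- min(horizon, t_max)
    sol <- deSolve::lsoda(y = y, times = c(t_now, t_end), func = rate_fn,
                          parms = NULL, rtol = .default_rtol,
                          atol = .default_atol)
    y <- stats::setNames(as.numeric(sol[nrow(sol), sys$species]),
                         sys$species)
    if (any(!is.finite(y))) {
      petab_error("equilibration_failure",
                  sprintf("state diverged during pre-equilibration (t = %g)",
                          t_end),
                  t_max = t_end)
    }
    if (converged(y, t_end)) return(y)
    t_now <- t_end
    horizon <- horizon * 10
  }
  dy <- rate_fn(t_max, as.list(y), NULL)[[1]]
  petab_error("equilibration_failure",
              sprintf("no steady state up to t = %g (max|dx/dt| = %g)",
                      t_max, max(abs(dy))),
              t_max = t_max, residual = max(abs(dy)))
}

#' Simulate one condition pair
#'
#' Without pre-equilibration, integrates from the mapped initial state.
#' With pre-equilibration, first equilibrates under the pre-equilibration
#' map, then switches to the simulation map, reinitializing exactly the
#' species overridden by the simulation condition and carrying every other
#' state over from the equilibrium.
#'
#' @param model A simulatable `petab_sbml_model`.
#' @param mapping A `petab_mapping` from [resolve_mapping()].
#' @param times Numeric vector of requested output times (`Inf` entries are
#'   evaluated at the post-equilibrated state of the simulation condition).
#' @param free_values Named numeric vector of linear-scale values for the
#'   free parameters referenced by the mapping.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `petab_trajectory`: list with `times`, the
#'   species-by-time `states` matrix, `map_values` (the materialized
#'   simulation map) and `steady_state` (post-equilibration state, filled
#'   when any time is `Inf`).
#' @export
simulate_pair <- function(model, mapping, times, free_values = numeric(0),
                          rtol = .default_rtol, atol = .default_atol) {
  if (!model$simulation_supported) {
    petab_error("unsupported_model",
                paste("model not simulatable:",
                      paste(model$support_reasons, collapse = ", ")),
                reasons = model$support_reasons)
  }
  sys <- model_ode_system(model)
  map_sim <- materialize_map(mapping$map_sim, free_values)

  y0 <- .initial_state(sys, map_sim)
  if (!is.null(mapping$map_preeq)) {
    map_preeq <- materialize_map(mapping$map_preeq, free_values)
    ss <- find_steady_state(model, map_preeq)
    carry <- intersect(mapping$carryover_states, sys$species)
    y0[carry] <- ss[carry]
    # reinit_states keep their simulation-condition values from map_sim
  }

  finite_times <- sort(unique(times[is.finite(times)]))
  grid <- sort(unique(c(0, finite_times)))
  dynamic <- sys$species
  rate_fn <- .make_rate_fn(sys, map_sim, dynamic)
  states <- if (length(grid) == 1L) {
    matrix(y0, nrow = length(dynamic), dimnames = list(dynamic, grid))
  } else {
    sol <- deSolve::lsoda(y = y0, times = grid, func = rate_fn, parms = NULL,
                          rtol = rtol, atol = atol)
    if (nrow(sol) < length(grid)) {
      petab_error("integration_failure", "integrator returned early")
    }
    t(as.matrix(sol[, dynamic, drop = FALSE]))
  }
  dimnames(states) <- list(dynamic, format_petab_number(grid))
  if (any(!is.finite(states))) {
    petab_error("integration_failure", "non-finite state in trajectory")
  }

  steady_state <- NULL
  if (any(is.infinite(times))) {
    steady_state <- find_steady_state(model, map_sim, state = y0)
  }

  structure(list(preequilibrationConditionId =
                   mapping$preequilibrationConditionId,
                 simulationConditionId = mapping$simulationConditionId,
                 times = grid, states = states, map_values = map_sim,
                 steady_state = steady_state),
            class = "petab_trajectory")
}

# State environment (species + mapped entities + time) at one output time.
.state_env_at <- function(trajectory, time) {
  env <- as.list(trajectory$map_values)
  if (is.infinite(time)) {
    ss <- trajectory$steady_state
    for (s in names(ss)) env[[s]] <- ss[[s]]
    env$time <- Inf
    return(env)
  }
  idx <- which(abs(trajectory$times - time) <= 1e-12 * max(1, abs(time)))
  if (length(idx) == 0L) {
    petab_error("integration_failure",
                sprintf("time %g not on the trajectory grid", time))
  }
  for (s in rownames(trajectory$states)) {
    env[[s]] <- trajectory$states[s, idx[1]]
  }
  env$time <- time
  env
}

#' Simulate every measurement of a problem
#'
#' Runs one simulation job per condition pair and evaluates each
#' measurement's observable (and noise) formula at its time point, with
#' placeholder symbols bound from the measurement row.
#'
#' @param problem A valid, simulatable `petab_problem`.
#' @param free_values Named numeric vector of linear-scale values for the
#'   estimated parameters; defaults to their nominal values.
#' @param rtol,atol Integrator tolerances.
#' @return A data.frame shaped like the measurement table with the
#'   `measurement` column replaced by `simulation`; the evaluated noise
#'   standard deviations are attached as `attr(, "sigma")`.
#' @export
simulate_problem <- function(problem, free_values = NULL,
                             rtol = .default_rtol, atol = .default_atol) {
  if (is.null(free_values)) {
    est <- problem$parameters$estimate == 1
    free_values <- stats::setNames(problem$parameters$nominalValue[est],
                                   problem$parameters$parameterId[est])
    if (any(is.na(free_values))) {
      petab_error("unresolved_symbol",
                  "estimated parameters without nominal values; supply free_values",
                  id = names(free_values)[is.na(free_values)][1],
                  where = "simulate_problem")
    }
  }
  m <- problem$measurements
  sim_col <- rep(NA_real_, nrow(m))
  sigma_col <- rep(NA_real_, nrow(m))
  if (nrow(m) > 0L) {
    pairs <- get_condition_pairs(m)
    param_values <- as.list(nominal_free_values(problem))
    param_values[names(free_values)] <- as.list(free_values)
    for (pi in seq_len(nrow(pairs))) {
      mapping <- resolve_mapping(problem, pairs[pi, ])
      rows <- pairs$measurement_rows[[pi]]
      traj <- simulate_pair(problem$model, mapping, times = m$time[rows],
                            free_values = unlist(param_values),
                            rtol = rtol, atol = atol)
      for (ri in rows) {
        orow <- problem$observables[
          problem$observables$observableId == m$observableId[ri], , drop = FALSE]
        env <- .state_env_at(traj, m$time[ri])
        ph <- mapping$placeholders[[as.character(ri)]]
        if (!is.null(ph)) {
          for (k in names(ph)) {
            v <- ph[[k]]
            env[[k]] <- if (is.character(v)) param_values[[v]] else v
          }
        }
        # symbols still unresolved (e.g. output parameters used directly in
        # formulas) fall back to the parameter table
        env <- utils::modifyList(param_values, env[!vapply(env, is.null,
                                                           logical(1))])
        sim_col[ri] <- evaluate_expression(orow$observableFormula[1], env)
        env[[orow$observableId[1]]] <- sim_col[ri]
        sigma_col[ri] <- evaluate_expression(orow$noiseFormula[1], env)
      }
    }
  }
  out <- m
  out$measurement <- NULL
  out$simulation <- sim_col
  attr(out, "sigma") <- sigma_col
  out
}
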