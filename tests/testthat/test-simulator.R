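# Closed form used throughout: for A <-> B with rates k1, k2 and total
# T = A0 + B0, A(t) = s + (A0 - s) e^{-(k1+k2)t} with s = k2 T / (k1+k2).

test_that("trajectories match the closed form of the conversion model", {
  fx <- generate_fixture("Basic simulation")
  p <- fx$problem
  mp <- resolve_mapping(p, get_condition_pairs(p$measurements)[1, ])
  k1 <- 0.8; k2 <- 0.6
  traj <- simulate_pair(p$model, mp, times = c(0, 1, 2, 5, 10),
                        free_values = c(k1 = k1, k2 = k2))
  A_exact <- (k2 + k1 * exp(-(k1 + k2) * traj$times)) / (k1 + k2)
  expect_lt(max(abs(traj$states["A", ] - A_exact)), 1e-6)
  expect_lt(max(abs(traj$states["B", ] - (1 - A_exact))), 1e-6)
})

test_that("mass is conserved along the trajectory", {
  fx <- generate_fixture("Basic simulation")
  p <- fx$problem
  mp <- resolve_mapping(p, get_condition_pairs(p$measurements)[1, ])
  traj <- simulate_pair(p$model, mp, times = seq(0, 10, by = 0.5),
                        free_values = c(k1 = 0.8, k2 = 0.6))
  total <- colSums(traj$states)
  expect_lt(max(abs(total - total[1])), 1e-8)
})

test_that("halving the integrator tolerances barely moves the output", {
  fx <- generate_fixture("Basic simulation")
  sim1 <- simulate_problem(fx$problem)
  sim2 <- simulate_problem(fx$problem, rtol = 0.5e-8, atol = 0.5e-12)
  expect_lt(max(abs(sim1$simulation - sim2$simulation)), 1e-7)
})

test_that("steady states match the analytic fixed point from any start", {
  model <- petabkit:::load_conversion_model()
  for (start in list(c(A = 1, B = 0), c(A = 0.2, B = 1.7))) {
    map <- c(k1 = 0.8, k2 = 0.6, compartment = 1, start)
    ss <- find_steady_state(model, map)
    total <- sum(start)
    expect_lt(abs(ss[["A"]] - 0.6 * total / 1.4), 1e-6)
    expect_lt(abs(ss[["B"]] - 0.8 * total / 1.4), 1e-6)
  }
})

test_that("a start with zero net flux returns immediately", {
  model <- petabkit:::load_conversion_model()
  eq <- c(A = 0.6 / 1.4, B = 0.8 / 1.4)
  ss <- find_steady_state(model,
                          c(k1 = 0.8, k2 = 0.6, compartment = 1, eq))
  expect_equal(ss, eq, tolerance = 1e-12)
})

test_that("pure production has no steady state", {
  model <- load_sbml_text(production_model_sbml())
  expect_error(
    find_steady_state(model, c(v = 1, compartment = 1, X = 0), t_max = 1e6),
    class = "petab_equilibration_failure")
})

test_that("pre-equilibration without overrides gives a constant trajectory", {
  fx <- generate_fixture("Basic simulation")
  p <- fx$problem
  # same condition for preeq and sim, no reinitialization
  m <- p$measurements
  m$preequilibrationConditionId <- "c0"
  p$measurements <- petabkit:::.canonicalize_table(m, "measurement")
  mp <- resolve_mapping(p, get_condition_pairs(p$measurements)[1, ])
  traj <- simulate_pair(p$model, mp, times = c(0, 5, 10),
                        free_values = c(k1 = 0.8, k2 = 0.6))
  expect_lt(max(abs(traj$states - traj$states[, 1])), 1e-6)
  expect_lt(abs(traj$states["A", 1] - 0.6 / 1.4), 1e-6)
})

test_that("partial pre-equilibration reinitializes A and carries B", {
  fx <- generate_fixture("Partial pre-equilibration")
  p <- fx$problem
  mp <- resolve_mapping(p, get_condition_pairs(p$measurements)[1, ])
  traj <- simulate_pair(p$model, mp, times = c(0, 1),
                        free_values = c(k1 = 0.8, k2 = 0.6))
  expect_lt(abs(traj$states["A", 1] - 1), 1e-6)           # reinitialized
  expect_lt(abs(traj$states["B", 1] - 0.8 / 1.4), 1e-6)   # equilibrium value
})

test_that("whole problems simulate each measurement deterministically", {
  fx <- generate_fixture("Multiple simulation conditions")
  sim1 <- simulate_problem(fx$problem)
  sim2 <- simulate_problem(fx$problem)
  expect_identical(sim1$simulation, sim2$simulation)
  expect_equal(names(sim1)[names(sim1) != "simulation"],
               names(fx$problem$measurements)[
                 names(fx$problem$measurements) != "measurement"])
  expect_lt(max(abs(sim1$simulation - fx$expected_simulations)), 1e-6)
})

test_that("steady-state measurements (time inf) use the equilibrated state", {
  fx <- generate_fixture("Basic simulation")
  p <- fx$problem
  m <- p$measurements
  m$time[5] <- Inf
  p$measurements <- petabkit:::.canonicalize_table(m, "measurement")
  sim <- simulate_problem(p)
  expect_lt(abs(sim$simulation[5] - 0.8 / 1.4), 1e-6)
  # the literal token "inf" survives a table round-trip
  path <- tempfile(fileext = ".tsv")
  write_petab_table(p$measurements, "measurement", path)
  expect_true(any(grepl("\tinf$", readLines(path))))
  back <- read_petab_table(path, "measurement")
  expect_identical(back$time[5], Inf)
})

test_that("an empty measurement table yields an empty simulation table", {
  fx <- generate_fixture("Basic simulation")
  p <- fx$problem
  p$measurements <- p$measurements[0, ]
  sim <- simulate_problem(p)
  expect_equal(nrow(sim), 0)
  expect_true("simulation" %in% names(sim))
})
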