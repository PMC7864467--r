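test_that("condition pairs are unique and in first-appearance order", {
  m <- data.frame(
    observableId = "obs_b",
    simulationConditionId = c("c0", "c1", "c0", "c1"),
    measurement = 1, time = 1:4, stringsAsFactors = FALSE)
  pairs <- get_condition_pairs(petabkit:::.canonicalize_table(m, "measurement"))
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$simulationConditionId, c("c0", "c1"))
  expect_true(all(is.na(pairs$preequilibrationConditionId)))
  expect_equal(sort(unlist(pairs$measurement_rows)), 1:4)

  m$preequilibrationConditionId <- c("c0", "c0", NA, NA)
  m$simulationConditionId <- "c1"
  pairs <- get_condition_pairs(petabkit:::.canonicalize_table(m, "measurement"))
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$preequilibrationConditionId, c("c0", NA))
  expect_equal(pairs$measurement_rows, list(1:2, 3:4))
})

test_that("numeric condition cells override the model default directly", {
  fx <- generate_fixture("Multiple simulation conditions")
  pairs <- get_condition_pairs(fx$problem$measurements)
  mp <- resolve_mapping(fx$problem, pairs[2, ])
  expect_identical(mp$map_sim$k1, 1.2)
  # not touched by the condition: still the estimated free parameter
  expect_identical(mp$map_sim$k2, "k2")
  expect_identical(mp$scale_map[["k2"]], "lin")
})

test_that("identifier cells chain one step into the parameter table", {
  fx <- generate_fixture("Parametric overrides in condition table")
  pairs <- get_condition_pairs(fx$problem$measurements)
  mp <- resolve_mapping(fx$problem, pairs[1, ])
  # estimated: mapped to the free parameter id, scale from the table
  expect_identical(mp$map_sim$k1, "rate_p")
  expect_identical(mp$scale_map[["rate_p"]], "lin")

  # fixed parameters resolve to their nominal value
  p <- fx$problem
  i <- which(p$parameters$parameterId == "rate_p")
  p$parameters$estimate[i] <- 0
  mp2 <- resolve_mapping(p, pairs[1, ])
  expect_identical(mp2$map_sim$k1, 1.1)
})

test_that("placeholders are bound per measurement row", {
  fx <- generate_fixture(
    "Time-point specific overrides in the measurement table")
  pairs <- get_condition_pairs(fx$problem$measurements)
  mp <- resolve_mapping(fx$problem, pairs[1, ])
  expect_length(mp$placeholders, nrow(fx$problem$measurements))
  b1 <- mp$placeholders[["1"]]
  b3 <- mp$placeholders[["3"]]
  expect_equal(b1$observableParameter1_obs_b, 0.7)
  expect_equal(b3$observableParameter1_obs_b, 1.0)
  expect_equal(b1$noiseParameter1_obs_b, 0.5)
  expect_equal(b3$noiseParameter1_obs_b, 0.2)
})

test_that("pre-equilibration pairs split reinitialized and carried states", {
  fx <- generate_fixture("Partial pre-equilibration")
  pairs <- get_condition_pairs(fx$problem$measurements)
  expect_equal(pairs$preequilibrationConditionId, "c0")
  mp <- resolve_mapping(fx$problem, pairs[1, ])
  expect_identical(mp$map_preeq$k1, 0.8)
  expect_identical(mp$map_sim$k1, 0.9)
  expect_identical(mp$reinit_states, "A")
  expect_identical(mp$carryover_states, "B")

  fx_full <- generate_fixture("Pre-equilibration")
  mp_full <- resolve_mapping(fx_full$problem,
                             get_condition_pairs(fx_full$problem$measurements)[1, ])
  expect_length(mp_full$reinit_states, 0)
  expect_setequal(mp_full$carryover_states, c("A", "B"))
})

test_that("removing a higher-precedence source only reverts its own targets", {
  fx <- generate_fixture("Multiple simulation conditions")
  pairs <- get_condition_pairs(fx$problem$measurements)
  with_cond <- resolve_mapping(fx$problem, pairs[2, ])
  p <- fx$problem
  p$conditions$k1 <- NULL  # drop the condition override column
  without_cond <- resolve_mapping(p, pairs[2, ])
  expect_identical(without_cond$map_sim$k1, "k1")  # falls back one level
  same <- setdiff(names(with_cond$map_sim), "k1")
  expect_identical(with_cond$map_sim[same], without_cond$map_sim[same])
})

test_that("mapped symbols cover every formula and kinetic-law symbol", {
  for (nm in fixture_names()) {
    fx <- generate_fixture(nm)
    p <- fx$problem
    pairs <- get_condition_pairs(p$measurements)
    for (pi in seq_len(nrow(pairs))) {
      mp <- resolve_mapping(p, pairs[pi, ])
      mapped <- c(names(mp$map_sim),
                  unique(unlist(lapply(mp$placeholders, names))),
                  p$parameters$parameterId, "time")
      needed <- unique(unlist(c(
        lapply(p$observables$observableFormula, free_symbols),
        lapply(p$observables$noiseFormula, free_symbols),
        lapply(p$model$reactions, function(r) free_symbols(r$law)))))
      expect_true(all(needed %in% c(mapped, p$observables$observableId)),
                  info = nm)
    }
  }
})

test_that("scale and unscale are exact inverses on all three scales", {
  expect_equal(petab_scale(100, "log10"), 2)
  expect_equal(petab_unscale(0, "log"), 1)
  expect_equal(petab_scale(5, "lin"), 5)
  set.seed(7)
  x <- stats::runif(1000, 1e-8, 1e8)
  for (sc in c("lin", "log", "log10")) {
    back <- petab_unscale(petab_scale(x, sc), sc)
    expect_lt(max(abs(back - x) / x), 1e-12)
  }
  expect_error(petab_scale(-1, "log"), class = "petab_domain")
  expect_error(petab_scale(0, "log10"), class = "petab_domain")
})

test_that("free parameters come out in table order on the estimation scale", {
  fx <- generate_fixture("Parametric noise parameter overrides in measurement table")
  free <- get_free_parameters(fx$problem)
  expect_equal(free$parameterId, c("k1", "k2", "noise_p"))
  i <- which(free$parameterId == "noise_p")
  expect_equal(free$lowerBound[i], -3)   # log10(1e-3)
  expect_equal(free$upperBound[i], 1)    # log10(10)
  expect_equal(free$nominalValue[i], log10(0.3))

  # a 3-row table with 2 estimated rows yields length 2
  p <- fx$problem
  p$parameters$estimate[p$parameters$parameterId == "k2"] <- 0
  expect_equal(nrow(get_free_parameters(p)), 2)
})

test_that("a nominal value outside bounds passes mapping, lint warns", {
  fx <- generate_fixture("Basic simulation")
  p <- fx$problem
  p$parameters$nominalValue[1] <- 1000
  expect_silent(free <- get_free_parameters(p))
  expect_equal(free$nominalValue[1], 1000)
  issues <- lint_problem(p)
  expect_true("NOMINAL_OUT_OF_BOUNDS" %in% issues$code)
  expect_false(any(issues$severity == "error"))
})
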