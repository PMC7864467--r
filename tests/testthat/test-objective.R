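test_that("observable evaluation applies overrides on linear scale", {
  obs <- list(observableFormula = "B")
  expect_equal(evaluate_observable(obs, list(B = 0.5)), 0.5)
  obs2 <- list(observableFormula = "scaling_p * B")
  expect_equal(evaluate_observable(obs2, list(B = 0.5),
                                   list(scaling_p = 2)), 1.0)
})

test_that("residuals follow the observable's transformation", {
  for (tr in c("lin", "log", "log10")) {
    expect_equal(petab_residual(3, 3, 1.7, tr), 0, info = tr)
  }
  expect_equal(petab_residual(2, 1, 1, "lin"), 1)
  expect_equal(petab_residual(100, 10, 0.5, "log10"), 2.0)
  expect_error(petab_residual(2, 1, 0, "lin"), class = "petab_domain")
  expect_error(petab_residual(-1, 1, 1, "log"), class = "petab_domain")
})

test_that("chi-square sums squared standardized residuals", {
  fx <- generate_fixture("Basic simulation")
  p <- fx$problem
  # simulations equal to the data: chi2 is exactly zero
  sim <- p$measurements
  sim$simulation <- sim$measurement
  sim$measurement <- NULL
  expect_equal(petab_chi2(p, sim), 0)
  # residuals 1 and 2 -> 5
  sim$simulation <- p$measurements$measurement - c(1, 2, 0, 0, 0)
  expect_equal(petab_chi2(p, sim), 5)
})

test_that("single-point negative log-likelihoods match closed forms", {
  nllh1 <- petabkit:::.point_nllh
  expect_equal(nllh1(1.3, 1.3, 1, "lin", "normal"), 0.5 * log(2 * pi))
  expect_equal(nllh1(1.3, 1.3, 0.5, "lin", "laplace"), 0)  # ln(2 * 0.5)
  # explicit formula checks on the log scales
  y <- 2; yhat <- 1.5; s <- 0.4
  expect_equal(nllh1(y, yhat, s, "log", "normal"),
               0.5 * log(2 * pi * s^2 * y^2) +
                 0.5 * ((log(y) - log(yhat)) / s)^2)
  expect_equal(nllh1(y, yhat, s, "log10", "normal"),
               0.5 * log(2 * pi * s^2 * y^2 * log(10)^2) +
                 0.5 * ((log10(y) - log10(yhat)) / s)^2)
  expect_equal(nllh1(y, yhat, s, "log", "laplace"),
               log(2 * s * y) + abs(log(y) - log(yhat)) / s)
  expect_error(nllh1(1, 1, -1, "lin", "normal"), class = "petab_domain")
})

test_that("every noise density integrates to one over the data support", {
  yhat <- 1.5
  sigma <- 0.4
  for (dist in c("normal", "laplace")) {
    for (tr in c("lin", "log", "log10")) {
      dens <- function(y) {
        vapply(y, function(yy) {
          exp(-petabkit:::.point_nllh(yy, yhat, sigma, tr, dist))
        }, numeric(1))
      }
      lower <- if (tr == "lin") -Inf else 1e-12
      total <- stats::integrate(dens, lower, Inf, rel.tol = 1e-10,
                                abs.tol = 1e-10)$value
      expect_lt(abs(total - 1), 1e-6, label = paste(dist, tr))
    }
  }
})

test_that("nllh decomposes additively over measurement partitions", {
  fx <- generate_fixture("Multiple simulation conditions")
  p <- fx$problem
  sim <- simulate_problem(p)
  whole <- petab_nllh(p, sim)
  split_nllh <- 0
  for (rows in list(1:2, 3:6)) {
    ps <- p
    ps$measurements <- p$measurements[rows, ]
    sims <- sim[rows, ]
    attr(sims, "sigma") <- attr(sim, "sigma")[rows]
    split_nllh <- split_nllh + petab_nllh(ps, sims)
  }
  expect_equal(split_nllh, whole, tolerance = 1e-12)
})

test_that("for unit-variance normal noise, nllh = chi2/2 + (m/2) ln(2 pi)", {
  for (nm in c("Basic simulation", "Replicate measurements")) {
    fx <- generate_fixture(nm)
    sim <- simulate_problem(fx$problem)
    m <- nrow(fx$problem$measurements)
    expect_lt(abs(petab_nllh(fx$problem, sim) -
                    0.5 * petab_chi2(fx$problem, sim) -
                    (m / 2) * log(2 * pi)), 1e-10, label = nm)
  }
})

test_that("estimated noise parameters flow through to sigma", {
  fx <- generate_fixture("Parametric noise parameter overrides in measurement table")
  sim <- simulate_problem(fx$problem)
  expect_equal(attr(sim, "sigma"), rep(0.3, 5))
  # the table-only path re-derives sigma from the noiseParameters cell
  attr(sim, "sigma") <- NULL
  rec <- petabkit:::.simulation_records(fx$problem, sim)
  expect_equal(rec$sigma, rep(0.3, 5))
})

test_that("calculate aggregates chi2, nllh and the residual table", {
  fx <- generate_fixture("Basic simulation")
  res <- petab_calculate(fx$problem)
  expect_named(res, c("chi2", "nllh", "residuals"))
  expect_equal(res$chi2, sum(res$residuals$residual^2))
  expect_lt(abs(res$chi2 - fx$expected_chi2), 1e-6)
  # empty problem
  p <- fx$problem
  p$measurements <- p$measurements[0, ]
  res0 <- petab_calculate(p)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$nllh, 0)
  expect_equal(nrow(res0$residuals), 0)
})

test_that("startpoint sampling is seeded, bounded and prior-faithful", {
  fx <- generate_fixture("Basic simulation")
  p <- fx$problem
  sp1 <- sample_startpoints(p, 1000, seed = 11)
  sp2 <- sample_startpoints(p, 1000, seed = 11)
  expect_identical(sp1, sp2)
  expect_equal(colnames(sp1), c("k1", "k2"))
  expect_true(all(sp1 >= 0.01 & sp1 <= 100))

  # parameterScaleNormal(0, 1) on log10 scale: mean within 4 SE of 0
  p2 <- add_parameter_row(p, parameterId = "theta",
                          parameterScale = "log10",
                          lowerBound = 1e-10, upperBound = 1e10,
                          nominalValue = 1, estimate = 1,
                          initializationPriorType = "parameterScaleNormal",
                          initializationPriorParameters = "0;1")
  p2$observables$observableFormula <- "theta * B"
  sp <- sample_startpoints(p2, 10000, seed = 5)
  expect_lt(abs(mean(sp[, "theta"])), 4 / sqrt(10000))
  expect_true(all(sp[, "theta"] >= -10 & sp[, "theta"] <= 10))
})

test_that("linear-scale priors transform onto the estimation scale", {
  fx <- generate_fixture("Basic simulation")
  p <- add_parameter_row(fx$problem, parameterId = "theta",
                         parameterScale = "log10",
                         lowerBound = 1e-10, upperBound = 1e10,
                         nominalValue = 1, estimate = 1,
                         initializationPriorType = "uniform",
                         initializationPriorParameters = "10;100")
  p$observables$observableFormula <- "theta * B"
  sp <- sample_startpoints(p, 2000, seed = 3)
  expect_true(all(sp[, "theta"] >= 1 & sp[, "theta"] <= 2))
  expect_gt(max(sp[, "theta"]), 1.9)
  expect_lt(min(sp[, "theta"]), 1.1)
})
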