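test_that("the registry generates all sixteen cases", {
  cases <- generate_all_fixtures(seed = 1L)
  expect_length(cases, 16)
  expect_setequal(names(cases), fixture_names())
  for (f in cases) {
    expect_s3_class(f$problem, "petab_problem")
    expect_gt(nrow(f$problem$measurements), 0)
    expect_length(f$expected_simulations, nrow(f$problem$measurements))
    expect_true(is.finite(f$expected_chi2))
    expect_true(is.finite(f$expected_nllh))
  }
  expect_error(generate_fixture("No such case"),
               class = "petab_unknown_case")
})

test_that("generation is deterministic given the seed", {
  a <- generate_fixture("Basic simulation", seed = 42L)
  b <- generate_fixture("Basic simulation", seed = 42L)
  expect_identical(a$problem$measurements, b$problem$measurements)
  c <- generate_fixture("Basic simulation", seed = 43L)
  expect_false(identical(a$problem$measurements$measurement,
                         c$problem$measurements$measurement))

  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(a, d1)
  write_fixture(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("written cases load back to the generated problem", {
  f <- generate_fixture("Pre-equilibration")
  dir <- tempfile()
  yaml_path <- write_fixture(f, dir)
  p2 <- load_petab_problem(yaml_path)
  for (tab in c("conditions", "measurements", "observables", "parameters")) {
    expect_equal(p2[[tab]][names(f$problem[[tab]])], f$problem[[tab]],
                 ignore_attr = TRUE, info = tab)
  }
  expected <- utils::read.delim(file.path(dir, "expected.tsv"))
  expect_equal(expected$simulation, f$expected_simulations)
  expect_equal(expected$chi2[1], f$expected_chi2)
  expect_equal(expected$llh[1], -f$expected_nllh)
})

test_that("expected values are reproduced end-to-end by the implementation", {
  # the three-flag scheme: simulations, chi2 and likelihood all correct
  for (nm in fixture_names()) {
    f <- generate_fixture(nm)
    sim <- simulate_problem(f$problem)
    expect_lt(max(abs(sim$simulation - f$expected_simulations)),
              f$tolerance, label = paste(nm, "simulations"))
    expect_lt(abs(petab_chi2(f$problem, sim) - f$expected_chi2),
              f$tolerance, label = paste(nm, "chi2"))
    expect_lt(abs(petab_nllh(f$problem, sim) - f$expected_nllh),
              f$tolerance, label = paste(nm, "nllh"))
  }
})

test_that("replicate rows contribute to chi2 individually", {
  f <- generate_fixture("Replicate measurements")
  m <- f$problem$measurements
  dup <- which(duplicated(m[c("observableId", "time")]) |
                 duplicated(m[c("observableId", "time")], fromLast = TRUE))
  expect_gte(length(dup), 4)
  sim <- simulate_problem(f$problem)
  contributions <- (m$measurement - sim$simulation)^2
  expect_equal(petab_chi2(f$problem, sim), sum(contributions),
               tolerance = 1e-10)
})

test_that("log-scale cases include the change-of-variables term", {
  f <- generate_fixture("Observable transformations to log10 scale")
  sim <- simulate_problem(f$problem)
  m <- f$problem$measurements
  sigma <- 0.3
  r <- (log10(m$measurement) - log10(sim$simulation)) / sigma
  jacobians <- log(m$measurement) + log(log(10))
  expected <- sum(0.5 * log(2 * pi * sigma^2) + jacobians + 0.5 * r^2)
  expect_equal(petab_nllh(f$problem, sim), expected, tolerance = 1e-9)
})
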