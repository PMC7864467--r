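test_that("default visualization has one time-course plot per observable", {
  fx <- generate_fixture("Basic simulation")
  vis <- default_visualization(fx$problem)
  expect_equal(nrow(vis), 1)
  expect_equal(vis$plotId, "plot_obs_b")
  expect_equal(vis$plotType, "time_course")

  p <- fx$problem
  p$measurements <- p$measurements[0, ]
  expect_equal(nrow(default_visualization(p)), 0)
})

test_that("figure data pairs measured and simulated series", {
  fx <- generate_fixture("Basic simulation")
  sim <- simulate_problem(fx$problem)
  figs <- build_figure_data(fx$problem, sim)
  expect_length(figs, 1)
  expect_equal(figs[[1]]$plot_type, "time_course")
  sources <- vapply(figs[[1]]$series, `[[`, character(1), "source")
  expect_setequal(sources, c("measurement", "simulation"))
  for (s in figs[[1]]$series) {
    expect_false(is.unsorted(s$x))
    expect_length(s$y, length(s$x))
  }
})

test_that("replicates aggregate to mean and sample SD", {
  fx <- generate_fixture("Basic simulation")
  p <- fx$problem
  m <- p$measurements[c(1, 1, 1), ]
  m$time <- c(1, 1, 1)
  m$measurement <- c(1, 2, 3)
  p$measurements <- petabkit:::.canonicalize_table(m, "measurement")
  figs <- build_figure_data(p)
  s <- figs[[1]]$series[[1]]
  expect_equal(s$x, 1)
  expect_equal(s$y, 2)
  expect_equal(s$spread, 1)   # sample SD, n-1 denominator

  # a single replicate has no spread
  p$measurements <- petabkit:::.canonicalize_table(m[1, ], "measurement")
  s1 <- build_figure_data(p)[[1]]$series[[1]]
  expect_true(is.na(s1$spread))
})

test_that("dose-response plots take x from the condition table", {
  fx <- generate_fixture("Multiple simulation conditions")
  p <- fx$problem
  p$visualization <- petabkit:::.canonicalize_table(
    data.frame(plotId = "dr", plotType = "dose_response", xVariable = "k1",
               yObservables = "obs_b", grouping = "by_observable",
               stringsAsFactors = FALSE), "visualization")
  figs <- build_figure_data(p)
  expect_length(figs, 1)
  expect_equal(figs[[1]]$x_label, "k1")
  s <- figs[[1]]$series[[1]]
  expect_equal(s$x, c(0.8, 1.2))   # one x per simulation condition
  expect_error(build_figure_data({
    p$visualization$xVariable <- "not_a_column"; p
  }), class = "petab_missing_x_variable")
})

test_that("offsets shift series after aggregation", {
  fx <- generate_fixture("Basic simulation")
  p <- fx$problem
  p$visualization <- petabkit:::.canonicalize_table(
    data.frame(plotId = "p1", plotType = "time_course",
               yObservables = "obs_b", yOffset = 10, xOffset = 1,
               stringsAsFactors = FALSE), "visualization")
  base <- build_figure_data(fx$problem)[[1]]$series[[1]]
  shifted <- build_figure_data(p)[[1]]$series[[1]]
  expect_equal(shifted$x, base$x + 1)
  expect_equal(shifted$y, base$y + 10)
})

test_that("measurement and simulation series are visually distinguishable", {
  # style contract on the declarative spec: sources differ, labels differ
  fx <- generate_fixture("Multiple simulation conditions")
  figs <- build_figure_data(fx$problem, simulate_problem(fx$problem))
  labels <- vapply(figs[[1]]$series, `[[`, character(1), "label")
  expect_equal(anyDuplicated(labels), 0)
  expect_equal(sum(vapply(figs[[1]]$series, `[[`, character(1),
                          "source") == "simulation"),
               length(figs[[1]]$series) / 2)
})

test_that("figures render to files for every fixture", {
  dir <- tempfile()
  for (nm in c("Basic simulation", "Pre-equilibration")) {
    fx <- generate_fixture(nm)
    figs <- build_figure_data(fx$problem, simulate_problem(fx$problem))
    paths <- render_figures(figs, dir)
    expect_true(all(file.exists(paths)))
    expect_true(all(file.size(paths) > 0))
  }
})
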