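test_that("the conversion model's inventory is read completely", {
  model <- petabkit:::load_conversion_model()
  expect_setequal(model$species$id, c("A", "B"))
  expect_equal(model$species$initial[model$species$id == "A"], 1)
  expect_equal(model$species$initial[model$species$id == "B"], 0)
  expect_equal(model$parameters, c(k1 = 0.8, k2 = 0.6))
  expect_equal(model$compartments, c(compartment = 1))
  expect_length(model$reactions, 2)
  expect_true(model$simulation_supported)
})

test_that("the extracted right-hand side is the mass-action ODE", {
  model <- petabkit:::load_conversion_model()
  rhs <- petabkit:::ode_rhs_strings(model)
  norm <- function(s) gsub(" ", "", s)
  expect_equal(norm(rhs[["A"]]),
               "(-(compartment*k1*A)+compartment*k2*B)/compartment")
  expect_equal(norm(rhs[["B"]]),
               "(compartment*k1*A-compartment*k2*B)/compartment")
})

test_that("entity classification covers every class", {
  model <- petabkit:::load_conversion_model()
  expect_identical(has_entity(model, "k1"), "parameter")
  expect_identical(has_entity(model, "A"), "species")
  expect_identical(has_entity(model, "compartment"), "compartment")
  expect_identical(has_entity(model, "nonexistent"), "absent")
  expect_identical(has_entity(model, "time"), "absent")
})

test_that("models with events load but are flagged unsimulatable", {
  model <- load_sbml_text(conversion_with(event_snippet))
  expect_false(model$simulation_supported)
  expect_true("events" %in% model$support_reasons)
  # entity inventory still usable for mapping/validation
  expect_identical(has_entity(model, "k1"), "parameter")
  expect_error(simulate_pair(model, list(map_sim = list()), times = 1),
               class = "petab_unsupported_model")
})

test_that("assignment rules are captured symbolically", {
  model <- load_sbml_text(conversion_with_rule())
  expect_identical(has_entity(model, "obs_total"), "rule-target")
  expect_equal(expression_to_string(model$assignment_rules$obs_total),
               "A + B")
})

test_that("amounts are converted to concentrations on load", {
  txt <- sub('initialConcentration="1"', 'initialAmount="3"',
             petabkit:::conversion_model_sbml(), fixed = TRUE)
  txt <- sub('size="1"', 'size="2"', txt, fixed = TRUE)
  model <- load_sbml_text(txt)
  expect_equal(model$species$initial[model$species$id == "A"], 1.5)
})

test_that("non-SBML input is rejected with a typed error", {
  path <- tempfile(fileext = ".xml")
  writeLines("<notsbml/>", path)
  expect_error(load_sbml_model(path), class = "petab_not_sbml")
  expect_error(load_sbml_model(tempfile()), class = "petab_missing_file")
})
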