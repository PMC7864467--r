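test_that("all generated fixture problems lint clean", {
  for (nm in fixture_names()) {
    issues <- lint_problem(generate_fixture(nm)$problem)
    expect_equal(nrow(issues), 0, info = nm)
  }
})

test_that("each lint rule fires on exactly its seeded defect", {
  defects <- lint_defects()
  expect_setequal(names(defects), lint_rules()$code)
  for (code in names(defects)) {
    issues <- lint_problem(defects[[code]]())
    expect_identical(unique(issues$code), code, info = code)
    expect_identical(unique(issues$severity),
                     lint_rules()$severity[lint_rules()$code == code],
                     info = code)
  }
})

test_that("linting is pure and order-stable", {
  p <- lint_defects()$REF_CONDITION()
  before <- p
  i1 <- lint_problem(p)
  i2 <- lint_problem(p)
  expect_identical(i1, i2)
  expect_identical(p, before)
})

test_that("assert_petab_valid raises only on error-severity issues", {
  valid <- generate_fixture("Basic simulation")$problem
  expect_silent(assert_petab_valid(valid))

  broken <- lint_defects()$REF_CONDITION()
  err <- tryCatch(assert_petab_valid(broken), error = identity)
  expect_s3_class(err, "petab_validation")
  expect_match(conditionMessage(err), "REF_CONDITION")

  warn_only <- lint_defects()$NOMINAL_OUT_OF_BOUNDS()
  expect_silent(assert_petab_valid(warn_only))
})

test_that("constructing a table with duplicate ids is a typed error", {
  expect_error(
    petabkit:::.canonicalize_table(
      data.frame(conditionId = c("c0", "c0"), stringsAsFactors = FALSE),
      "condition"),
    class = "petab_duplicate_id")
})
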