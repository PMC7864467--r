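test_that("parsing yields the expected structure and free symbols", {
  e <- parse_expression("scaling_p * B + offset_p")
  expect_s3_class(e, "petab_expr")
  expect_equal(free_symbols(e), c("scaling_p", "B", "offset_p"))

  ph <- parse_expression("noiseParameter1_obs_a")
  expect_equal(ph$kind, "sym")
  expect_match(ph$name, "^noiseParameter[0-9]+_obs_a$")

  expect_equal(free_symbols("k1 * A + k1"), c("k1", "A"))
})

test_that("evaluation follows standard precedence and semantics", {
  env <- c(k1 = 0.8, A = 1.0)
  expect_equal(evaluate_expression("k1*A", env), 0.8)
  expect_equal(evaluate_expression("log10(100)"), 2)
  expect_equal(evaluate_expression("2 + 3 * 4"), 14)
  expect_equal(evaluate_expression("2 ^ 3 ^ 2"), 512)     # right-assoc
  expect_equal(evaluate_expression("-2 ^ 2"), -4)         # unary binds looser
  expect_equal(evaluate_expression("(2 + 3) * 4"), 20)
  expect_equal(evaluate_expression("piecewise(1, time < 5, 0)",
                                   c(time = 3)), 1)
  expect_equal(evaluate_expression("piecewise(1, time < 5, 0)",
                                   c(time = 7)), 0)
  expect_equal(evaluate_expression("min(2, 3) + max(2, 3)"), 5)
})

test_that("typed errors carry position / symbol information", {
  expect_error(parse_expression("a + * b"), class = "petab_expression_syntax")
  expect_error(parse_expression(""), class = "petab_expression_syntax")
  expect_error(parse_expression("foo(1)"), class = "petab_expression_syntax")
  expect_error(evaluate_expression("a + b", c(a = 1)),
               class = "petab_missing_symbol")
  expect_error(evaluate_expression("log(x)", c(x = -1)),
               class = "petab_domain")
  expect_error(evaluate_expression("log10(0)", c()), class = "petab_domain")
})

test_that("parse-print-parse is idempotent", {
  texts <- c("scaling_p * B + offset_p", "-(a + b)^2 / c",
             "piecewise(a, time <= 5, b / 2)", "exp(-k * time) + 1e-3",
             "2 ^ 3 ^ 2", "min(a, max(b, c)) - sqrt(abs(d))")
  for (txt in texts) {
    once <- parse_expression(txt)
    twice <- parse_expression(expression_to_string(once))
    expect_equal(twice, once, info = txt)
  }
})

test_that("evaluation agrees with base R's evaluator on random expressions", {
  # independent oracle: R's own parser/evaluator on the printed form
  set.seed(421)
  syms <- c("x1", "x2", "x3")
  rand_expr <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.3) {
      if (stats::runif(1) < 0.5) {
        return(format_petab_number(round(stats::runif(1, 0.5, 2), 3)))
      }
      return(sample(syms, 1))
    }
    pick <- sample(c("bin", "fun", "pow", "cmp"), 1,
                   prob = c(0.55, 0.25, 0.1, 0.1))
    if (pick == "bin") {
      op <- sample(c("+", "-", "*", "/"), 1)
      return(paste0("(", rand_expr(depth - 1), " ", op, " ",
                    rand_expr(depth - 1), ")"))
    }
    if (pick == "fun") {
      fn <- sample(c("sin", "cos", "exp", "abs", "tanh", "sqrt"), 1)
      inner <- rand_expr(depth - 1)
      if (fn == "sqrt") inner <- paste0("abs(", inner, ")")
      if (fn == "exp") inner <- paste0("tanh(", inner, ")")
      return(paste0(fn, "(", inner, ")"))
    }
    if (pick == "pow") {
      return(paste0("(abs(", rand_expr(depth - 1), ") + 0.5) ^ ",
                    format_petab_number(sample(2:3, 1))))
    }
    paste0("piecewise(", rand_expr(depth - 1), ", ",
           rand_expr(depth - 1), " < ", rand_expr(depth - 1), ", ",
           rand_expr(depth - 1), ")")
  }
  base_env <- list(piecewise = function(a, cond, b) if (cond != 0) a else b)
  max_diff <- 0
  for (i in 1:100) {
    txt <- rand_expr(3)
    env <- as.list(stats::setNames(stats::runif(3, 0.5, 2), syms))
    ours <- evaluate_expression(txt, env)
    oracle <- eval(parse(text = txt), envir = c(env, base_env))
    if (is.finite(ours) && is.finite(oracle)) {
      max_diff <- max(max_diff, abs(ours - oracle))
    } else {
      expect_identical(is.finite(ours), is.finite(oracle), info = txt)
    }
  }
  expect_lt(max_diff, 1e-12)
})

test_that("numbers render at full precision and round-trip", {
  x <- c(0.1, 1/3, 1e-15, 123456.789, 2, -7)
  back <- as.numeric(format_petab_number(x))
  expect_equal(back, x, tolerance = 1e-14)
  expect_identical(format_petab_number(2), "2")
  expect_identical(format_petab_number(NA_real_), "")
})
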