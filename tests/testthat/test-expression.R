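test_that("parsing produces the expected graph structure", {
  g <- parse_expression("x1 + 2", "x1")
  expect_s3_class(g, "expr_graph")
  expect_identical(g$root$kind, "binary")
  expect_identical(g$root$op, "+")
  expect_identical(g$root$children[[1]]$kind, "ref")
  expect_identical(g$root$children[[1]]$name, "x1")
  expect_identical(g$root$children[[2]]$kind, "constant")
  expect_identical(g$free_symbols, "x1")

  # the baroreflex Hill term: 2 divisions, 2 additions, 1 power
  g1 <- parse_expression("1/(1+(x2d/p0 + r1)^n_hill)",
                         c("x2d", "p0", "r1", "n_hill"))
  count_ops <- function(node) {
    own <- as.integer(node$kind %in% c("binary", "unary"))
    if (is.null(node$children)) return(own)
    own + sum(vapply(node$children, count_ops, integer(1)))
  }
  expect_identical(count_ops(g1$root), 5L)
  expect_setequal(g1$free_symbols, c("x2d", "p0", "r1", "n_hill"))
})

test_that("malformed and undeclared input is rejected with useful messages", {
  expect_error(parse_expression("x1 + * 2", "x1"),
               class = "ddesens_parse_error")
  expect_error(parse_expression("x1 + z", "x1"), regexp = "z",
               class = "ddesens_parse_error")
  expect_error(parse_expression("x1 + max(x1, 2)", "x1"),
               class = "ddesens_parse_error")
  expect_error(parse_expression("", "x1"), class = "ddesens_parse_error")
  expect_error(parse_expression("x@d1", "x"), regexp = "d1",
               class = "ddesens_parse_error")
})

test_that("precedence and associativity follow the grammar", {
  ev <- function(txt, ...) evaluate_graph(parse_expression(txt, character()),
                                          list(...))
  expect_equal(ev("-2^2"), -4)          # ^ binds tighter than unary minus
  expect_equal(ev("2^3^2"), 512)        # ^ is right-associative
  expect_equal(ev("8 - 4 - 2"), 2)      # left-associative
  expect_equal(ev("2 + 3 * 4"), 14)
  expect_equal(ev("sin(0)"), 0)
  expect_equal(ev("exp(1)"), exp(1))
})

test_that("evaluation hits the documented values and domain errors", {
  hill <- parse_expression("1/(1+(x2d/p0)^n)", c("x2d", "p0", "n"))
  b <- list(state = c(x2d = 100), parameters = c(p0 = 100, n = 8))
  expect_equal(evaluate_graph(hill, b), 0.5)

  inv <- parse_expression("1/(x-1)", "x")
  expect_error(evaluate_graph(inv, list(state = c(x = 1))),
               class = "ddesens_domain_error")
  lg <- parse_expression("log(x)", "x")
  expect_error(evaluate_graph(lg, list(state = c(x = -2))),
               class = "ddesens_domain_error")
  sq <- parse_expression("sqrt(x)", "x")
  expect_error(evaluate_graph(sq, list(state = c(x = -1))),
               class = "ddesens_domain_error")
})

test_that("forward partials apply power and chain rules exactly", {
  fp <- forward_partials(parse_expression("x^2", "x"),
                         list(state = c(x = 3)), "x")
  expect_equal(fp$value, 9)
  expect_equal(unname(fp$partials), 6)

  fp <- forward_partials(parse_expression("sin(2*x)", "x"),
                         list(state = c(x = 0)), "x")
  expect_equal(fp$value, 0)
  expect_equal(unname(fp$partials), 2)

  # integer exponent on a negative base uses the power rule
  fp <- forward_partials(parse_expression("x^3", "x"),
                         list(state = c(x = -2)), "x")
  expect_equal(fp$value, -8)
  expect_equal(unname(fp$partials), 12)
})

test_that("the Hill-term partial matches a central finite difference", {
  g1 <- parse_expression("1/(1+(x2d/p0 + r1)^n)", c("x2d", "p0", "r1", "n"))
  b <- list(state = c(x2d = 100), parameters = c(p0 = 100, r1 = 0, n = 8))
  fp <- forward_partials(g1, b, "x2d")
  expect_equal(fp$value, 0.5)
  expect_equal(unname(fp$partials), -0.02)
  h <- 1e-6 * 100
  bp <- b; bp$state["x2d"] <- 100 + h
  bm <- b; bm$state["x2d"] <- 100 - h
  fd <- (evaluate_graph(g1, bp) - evaluate_graph(g1, bm)) / (2 * h)
  expect_equal(unname(fp$partials), fd, tolerance = 1e-8)
})

test_that("value channel of forward_partials is bit-identical to evaluation", {
  exprs <- c("exp(-(x*y)) + sqrt(y)/x", "tanh(x)^3 - cos(x*y)",
             "(x + y)/(x - 0.25) * log(y + 2)")
  for (txt in exprs) {
    g <- parse_expression(txt, c("x", "y"))
    b <- list(state = c(x = 1.3, y = 0.7))
    expect_identical(forward_partials(g, b, c("x", "y"))$value,
                     evaluate_graph(g, b))
  }
})

test_that("differentiation is linear in the expression", {
  b <- list(state = c(x = 0.8, y = 1.4))
  ga <- parse_expression("sin(x*y)", c("x", "y"))
  gb <- parse_expression("exp(-x) + y^2", c("x", "y"))
  gsum <- parse_expression("sin(x*y) + (exp(-x) + y^2)", c("x", "y"))
  gscaled <- parse_expression("3*sin(x*y)", c("x", "y"))
  pa <- forward_partials(ga, b, c("x", "y"))$partials
  pb <- forward_partials(gb, b, c("x", "y"))$partials
  expect_equal(forward_partials(gsum, b, c("x", "y"))$partials, pa + pb)
  expect_equal(forward_partials(gscaled, b, c("x", "y"))$partials, 3 * pa)
})

test_that("fuzzed expression graphs agree with central differences", {
  worst <- 0
  for (seed in 1:40) {
    rx <- random_expression_generator(seed, depth = 4L)
    vars <- names(rx$binding$state)
    fp <- forward_partials(rx$graph, rx$binding, vars)
    expect_true(is.finite(fp$value))
    for (v in vars) {
      x <- rx$binding$state[[v]]
      h <- 1e-6 * max(1, abs(x))
      bp <- rx$binding; bp$state[[v]] <- x + h
      bm <- rx$binding; bm$state[[v]] <- x - h
      fd <- (evaluate_graph(rx$graph, bp) - evaluate_graph(rx$graph, bm)) /
        (2 * h)
      rel <- abs(fp$partials[[v]] - fd) / max(1, abs(fp$partials[[v]]))
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("abs at zero warns and uses the zero subgradient", {
  g <- parse_expression("abs(x)", "x")
  expect_warning(fp <- forward_partials(g, list(state = c(x = 0)), "x"),
                 regexp = "subgradient")
  expect_equal(unname(fp$partials), 0)
})

test_that("system_jacobians splits state, delay and parameter columns", {
  m <- build_model(c("[states]", "x = 1", "[parameters]", "k = 2",
                     "[equations]", "dx/dt = -k*x"))
  j <- system_jacobians(m, state = c(x = 5))
  expect_equal(unname(j$A), matrix(-2))
  expect_equal(ncol(j$B), 0)
  expect_equal(unname(j$C), matrix(-5))

  md <- build_model(c("[states]", "x = 1", "[parameters]", "k = 2",
                      "[delays]", "d1 = 1",
                      "[equations]", "dx/dt = -k*x@d1"))
  jd <- system_jacobians(md, state = c(x = 5), delayed = 7)
  expect_equal(unname(jd$A), matrix(0))
  expect_equal(unname(jd$B), matrix(-2))
  expect_equal(unname(jd$C), matrix(-7))
})

test_that("cardiovascular Jacobians match central finite differences", {
  model <- cardiovascular_model()$model
  x <- c(100, 100); y <- 100; tt <- 0.3
  j <- system_jacobians(model, state = x, delayed = y, time = tt)
  f0 <- function(x1, x2, x2d) cardio_hand_rhs(tt, x1, x2, x2d)
  h <- 1e-3
  fdA <- cbind((f0(x[1] + h, x[2], y) - f0(x[1] - h, x[2], y)) / (2 * h),
               (f0(x[1], x[2] + h, y) - f0(x[1], x[2] - h, y)) / (2 * h))
  fdB <- (f0(x[1], x[2], y + h) - f0(x[1], x[2], y - h)) / (2 * h)
  expect_rel_equal(unname(j$A), fdA, 1e-6)
  expect_rel_equal(unname(j$B), matrix(fdB), 1e-6)
  # parameter column spot check: beta
  pbase <- list(h0 = 100, p0 = 100, alpha = 15, beta = 10, nu = 9.63,
                delta = 0.8, gamma = 0.2, mu = 0.18, A1 = 0, A2 = 0.003,
                f_r = 0.17, tau = 3, phi = 3.14, n = 8, eps_h = 1, eps_p = 3)
  pp <- pbase; pp$beta <- 10 + h
  pm <- pbase; pm$beta <- 10 - h
  fdC <- (cardio_hand_rhs(tt, x[1], x[2], y, pp) -
            cardio_hand_rhs(tt, x[1], x[2], y, pm)) / (2 * h)
  expect_rel_equal(unname(j$C[, "beta"]), fdC, 1e-6)
})
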