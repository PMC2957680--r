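test_that("history interpolation is linear with a constant past", {
  h <- new_history <- ddesens:::new_history(0, 1.0)
  ddesens:::history_push(h, 1, 3.0)
  expect_equal(interpolate_history(h, 0.5), 2.0)
  expect_equal(interpolate_history(h, 1), 3.0)   # exact node lookup
  expect_equal(interpolate_history(h, 0), 1.0)
  h2 <- ddesens:::new_history(0, 7.0)
  expect_equal(interpolate_history(h2, -2), 7.0) # constant past
  expect_error(interpolate_history(h, 1.5), regexp = "beyond")
})

test_that("a single trapezoid step reproduces the scalar fixed point", {
  m <- decay_model(theta = 1)
  x1 <- iterate_state(m, eta = 0.1)
  expect_equal(unname(x1), 0.95 / 1.05, tolerance = 1e-9)
})

test_that("a delayed step integrates the constant-history segment exactly", {
  m <- delay_decay_model(1, 1, 1)
  x <- iterate_state(m, eta = 0.5)
  expect_equal(unname(x), 0.5, tolerance = 1e-12)
  expect_error(iterate_state(m, eta = 1.5), regexp = "delay")
})

test_that("the corrector diverges cleanly when the step is not contractive", {
  m <- decay_model(theta = 1000)
  cfg <- solver_config(epsilon = 1)   # disable the stiffness exit
  expect_error(iterate_state(m, eta = 1, cfg = cfg),
               class = "ddesens_nonconvergence_error")
})

test_that("step control reproduces the mu bound, clipping and stiffness exit", {
  m <- decay_model(theta = 2)         # dx/dt = -2x: n = 1, m = 0, mu = 2
  cs <- control_step(m, x_p = 1, eta = 1)
  expect_equal(cs$mu, 2)
  expect_equal(cs$eta, 0.45)          # 0.9 / mu
  cs2 <- control_step(m, x_p = 1, eta = 0.4)
  expect_equal(cs2$eta, 0.4)          # mu * eta = 0.8 <= 1: unchanged
  expect_error(control_step(m, x_p = 1, eta = 1, cfg = solver_config(epsilon = 0.5)),
               class = "ddesens_stiff_error")
  # with a delay the step is additionally capped at the smallest delay
  md <- delay_decay_model(0.1, 0.5, 1)
  csd <- control_step(md, x_p = 1, y_p = 1, eta = 2)
  expect_equal(csd$eta, 0.5)
})

test_that("a very stiff model aborts with the stiffness diagnosis", {
  m <- decay_model(theta = 1e6)
  expect_error(solve_dde(m, grid = 1), class = "ddesens_stiff_error")
})

test_that("linear decay is solved to the analytic solution", {
  m <- decay_model(theta = 1)
  tr <- solve_dde(m, grid = seq(0.01, 1, 0.01))
  expect_equal(unname(tr$states[101, 1]), exp(-1), tolerance = 1e-5)
})

test_that("the linear DDE matches the method-of-steps closed form", {
  fx <- linear_dde_fixture(1, 1, 1)
  # kink-aligned sparse grid: the RHS is piecewise linear, so the trapezoid
  # rule is exact as long as no step crosses a breakpoint
  tr <- solve_dde(fx$model, grid = c(1, 2))
  expect_equal(unname(tr$states[, 1]), c(1, 0, -0.5), tolerance = 1e-12)
  # dense grid
  trd <- solve_dde(fx$model, grid = seq(0.01, 2, 0.01))
  expect_lt(max(abs(trd$states[, 1] - fx$analytic_solution(trd$times))), 1e-5)
})

test_that("the scheme is second order on the linear DDE", {
  fx <- linear_dde_fixture(1, 1, 1)
  err <- vapply(c(0.1, 0.05), function(hh) {
    tr <- solve_dde(fx$model, grid = seq(hh, 4, hh))
    max(abs(tr$states[, 1] - fx$analytic_solution(tr$times)))
  }, numeric(1))
  ratio <- err[1] / err[2]
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("random linear ODE systems match the matrix exponential", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(1:4, 1)
    M <- matrix(stats::runif(n * n, -1, 1), n)
    x0 <- stats::runif(n, 0.5, 2)
    m <- linear_system_model(M, x0)
    tr <- solve_dde(m, grid = seq(0.005, 1, 0.005))
    exact <- as.numeric(Matrix::expm(M) %*% x0)
    expect_lt(max(abs(tr$states[nrow(tr$states), ] - exact)), 1e-4)
  }
})

test_that("accepted node times increase and nodes are reproduced exactly", {
  fx <- cardiovascular_model()
  tr <- solve_dde(fx$model, grid = seq(0.1, 3, 0.1))
  ht <- tr$history$times
  expect_true(all(diff(ht) > 0))
  expect_equal(ht[1], 0)
  # sampling points are hit exactly, no interpolation at outputs
  expect_true(all(seq(0.1, 3, 0.1) %in% ht))
  expect_gt(tr$eval_count, 0)
})

test_that("declared-but-unused delays leave the trajectory bit-identical", {
  base <- build_model(c("[states]", "x = 1", "[parameters]", "k = 1",
                        "[equations]", "dx/dt = -k*x"))
  with_delay <- build_model(c("[states]", "x = 1", "[parameters]", "k = 1",
                              "[delays]", "d1 = 0.3",
                              "[equations]", "dx/dt = -k*x"))
  g <- seq(0.05, 1, 0.05)
  expect_identical(solve_dde(base, g)$states, solve_dde(with_delay, g)$states)
})
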