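test_that("initial sensitivities are zeros for parameters, identity for x0", {
  m <- decay_model()
  expect_equal(unname(init_sensitivities(m)), cbind(0, 1))
  m2 <- build_model(c("[states]", "a = 1", "b = 2",
                      "[equations]", "da/dt = -a", "db/dt = -b"))
  expect_equal(unname(init_sensitivities(m2)), diag(2))
})

test_that("the sensitivity right-hand side implements A Phi + B Phi_d + C", {
  # product rule at t = 0 for dx/dt = -theta x
  out <- sensitivity_rhs(A = matrix(-1), B = matrix(0, 1, 0),
                         C = matrix(-1), phi = cbind(0, 1))
  expect_equal(unname(out), cbind(-1, -1))
  # delayed summand
  out2 <- sensitivity_rhs(A = matrix(0), B = matrix(-2), C = matrix(-3),
                          phi = cbind(0, 1), phi_delayed = cbind(0.5, 0.25))
  expect_equal(unname(out2), cbind(-2 * 0.5 - 3, -2 * 0.25))
  # conservation under all-zero Jacobians
  out3 <- sensitivity_rhs(A = matrix(0, 2, 2), B = matrix(0, 2, 0),
                          C = matrix(0, 2, 3), phi = matrix(5, 2, 5))
  expect_equal(unname(out3), matrix(0, 2, 5))
  expect_error(sensitivity_rhs(A = matrix(0), B = matrix(-1),
                               C = matrix(0, 1, 1), phi = cbind(0, 1)),
               regexp = "row per delay")
})

test_that("linear decay sensitivities match the analytic solution", {
  m <- decay_model(theta = 1)
  out <- solve_with_sensitivities(m, grid = seq(0.01, 1, 0.01))
  s <- sensitivity_slice(out$sensitivities, "x")
  tt <- out$sensitivities$times
  expect_lt(max(abs(s[, "theta"] - (-tt * exp(-tt)))), 1e-4)
  expect_lt(max(abs(s[, "x(0)"] - exp(-tt))), 1e-4)
  # relative sensitivity w.r.t. x0 is identically 1 for a linear system
  S <- s[, "x(0)"] / out$trajectory$states[, 1]
  expect_lt(max(abs(S - 1)), 1e-10)
})

test_that("initial-condition columns start at identity, parameters at zero", {
  fx <- cardiovascular_model()
  out <- solve_with_sensitivities(fx$model, grid = c(0.02, 0.04))
  phi0 <- out$sensitivities$matrices[[1]]
  expect_equal(unname(phi0[, 1:16]), matrix(0, 2, 16))
  expect_equal(unname(phi0[, 17:18]), diag(2))
})

test_that("delayed-model sensitivities respect homogeneity in the history", {
  # dx/dt = -x(t-1) with constant history c: the solution is homogeneous of
  # degree 1 in c, so s(x, c)(t) = x(t)/c at every time
  for (cc in c(1, 2)) {
    fx <- linear_dde_fixture(1, 1, cc)
    out <- solve_with_sensitivities(fx$model, grid = seq(0.01, 2, 0.01))
    s_c <- sensitivity_slice(out$sensitivities, "x")[, "x(0)"]
    expect_lt(max(abs(s_c - out$trajectory$states[, 1] / cc)), 1e-10)
  }
  # and s(x, theta)(2) = dx(2)/dtheta = -2 + theta = -1 analytically
  fx <- linear_dde_fixture(1, 1, 1)
  out <- solve_with_sensitivities(fx$model, grid = seq(0.01, 2, 0.01))
  s_th <- sensitivity_slice(out$sensitivities, "x")[, "theta"]
  expect_equal(s_th[length(s_th)], -1, tolerance = 1e-6)
})

test_that("propagating sensitivities leaves the state bit-identical", {
  fx <- cardiovascular_model()
  g <- seq(0.02, 2, 0.02)
  tr <- solve_dde(fx$model, grid = g)
  out <- solve_with_sensitivities(fx$model, grid = g)
  expect_identical(tr$states, out$trajectory$states)
  expect_identical(tr$history$times, out$trajectory$history$times)
})

test_that("EAMCM-style sensitivities agree with finite differences on the linear DDE", {
  fx <- linear_dde_fixture(1, 1, 1)
  g <- seq(0.02, 2, 0.02)
  out <- solve_with_sensitivities(fx$model, grid = g)
  s <- sensitivity_slice(out$sensitivities, "x")[, "theta"]
  errs <- vapply(c(0.1, 0.01, 0.001), function(sp) {
    fd <- finite_difference_sensitivities(fx$model, grid = g,
                                          spacing_ratio = sp,
                                          targets = "theta")
    sfd <- sensitivity_slice(fd, "x")[, "theta"]
    mask <- abs(s) > 0.05
    max(abs(sfd - s)[mask] / abs(s)[mask])
  }, numeric(1))
  expect_lt(errs[2], 0.02)                 # 1% spacing within 2% relative
  expect_true(all(diff(errs) < 0))         # monotone in the spacing ratio
})

test_that("iterate_sensitivity advances one step consistently with the solver", {
  m <- decay_model(theta = 1)
  h <- ddesens:::new_history(0, 1, unname(m$phi0))
  eta <- 0.1
  x1 <- iterate_state(m, eta = eta)
  phi1 <- iterate_sensitivity(m, h, t = 0, eta = eta, x_t = 1,
                              x_next = unname(x1), phi_t = m$phi0)
  out <- solve_with_sensitivities(m, grid = eta)
  expect_equal(unname(phi1), unname(out$sensitivities$matrices[[2]]))
})
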