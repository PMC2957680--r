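# Small models built in code and shared across test files.

decay_model <- function(theta = 1, x0 = 1) {
  build_model(c("[states]", sprintf("x = %.17g", x0),
                "[parameters]", sprintf("theta = %.17g", theta),
                "[equations]", "dx/dt = -theta*x"))
}

# dx/dt = -theta * x(t - tau), constant history c
delay_decay_model <- function(theta = 1, tau = 1, c = 1) {
  linear_dde_fixture(theta, tau, c)$model
}

# random stable-ish linear ODE system xdot = M x as a dde_model
linear_system_model <- function(M, x0) {
  n <- nrow(M)
  states <- paste0("x", seq_len(n))
  eqs <- vapply(seq_len(n), function(i) {
    terms <- sprintf("%.17g*%s", M[i, ], states)
    paste(terms, collapse = " + ")
  }, "")
  dde_model(states = stats::setNames(x0, states),
            equations = stats::setNames(eqs, states))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(1, max(abs(expected))), tol)
}

cardio_hand_rhs <- function(t, x1, x2, x2d, p = NULL) {
  # independent plain-R transcription of the cardiovascular right-hand side,
  # used as an oracle for the parsed model
  if (is.null(p)) {
    p <- list(h0 = 100, p0 = 100, alpha = 15, beta = 10, nu = 9.63,
              delta = 0.8, gamma = 0.2, mu = 0.18, A1 = 0, A2 = 0.003,
              f_r = 0.17, tau = 3, phi = 3.14, n = 8, eps_h = 1, eps_p = 3)
  }
  r1 <- p$A1 * sin(2 * pi * p$f_r * p$tau * (t - 1) - p$phi)
  r2 <- p$A2 * sin(2 * pi * p$f_r * p$tau * t - p$phi)
  g1 <- 1 / (1 + (x2d / p$p0 + r1)^p$n)
  g2 <- 1 - 1 / (1 + (x2 / p$p0 + r2)^p$n)
  c((p$h0 / p$eps_h) * (p$beta * g1 / (1 + p$gamma * g2) - p$nu * g2) +
      (p$delta / p$eps_h) * (p$h0 - x1),
    p$mu * p$p0 * x1 / (p$eps_p * p$h0) - x2 / (p$eps_p * (1 + p$alpha * g1)))
}
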