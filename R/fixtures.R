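# Shipped model fixtures and independent oracles: the cardiovascular control
# model, an analytically solvable linear test DDE, finite-difference
# sensitivities on an independent reference integrator (deSolve::dede), and a
# deterministic random-expression generator used to fuzz the AD engine.

.fixture <- function(model, analytic_solution = NULL, notes = "") {
  structure(list(model = model, analytic_solution = analytic_solution,
                 notes = notes), class = "model_fixture")
}

#' The baroreflex cardiovascular control model
#'
#' A two-state DDE model of heart rate (`x1`, bpm) and arterial blood
#' pressure (`x2`, mmHg): delayed sympathetic feedback (Hill function of the
#' pressure one dimensionless delay unit ago) competes with instantaneous
#' vagal feedback, with a small sinusoidal respiration term.  16 parameters;
#' time is dimensionless (real time divided by the sympathetic delay `tau`),
#' so the discrete delay is 1 and `tau` enters the equations only
#' algebraically through the respiration phase.
#'
#' Initial conditions `x1(0) = h0 = 100`, `x2(0) = p0 = 100` are an
#' assumption (the source parameter table does not fix the initial state);
#' this is recorded in the fixture notes.  The default sampling grid is
#' `t in [0, 200]` with step 0.02.
#'
#' @return a `model_fixture` with fields `model` (a [dde_model()]) and
#'   `notes`.
#' @examples
#' fx <- cardiovascular_model()
#' fx$model
#' @export
cardiovascular_model <- function() {
  path <- system.file("models", "cardiovascular.dde", package = "ddesens")
  if (!nzchar(path)) stop("cardiovascular model file not found")
  model <- read_model(path)
  .fixture(model, notes = paste(
    "Baroreflex cardiovascular control model, Table-value parameter set;",
    "initial conditions x1(0)=h0, x2(0)=p0 and the [0, 200] horizon are",
    "assumptions, not part of the published parameter table."))
}

#' Linear test DDE with closed-form solution
#'
#' `dx/dt = -theta * x(t - tau)` with constant history `c`, the standard
#' analytically solvable DDE.  The method-of-steps solution is the piecewise
#' polynomial `x(t) = c * sum_{j=0}^{floor(t/tau)+1} (-theta)^j
#' (t-(j-1)tau)^j / j!`, attached as `analytic_solution(t)`.
#'
#' @param theta decay rate.
#' @param tau delay (positive).
#' @param c constant initial history (and initial value).
#' @return a `model_fixture` with `model` and vectorized `analytic_solution`.
#' @examples
#' fx <- linear_dde_fixture(1, 1, 1)
#' fx$analytic_solution(c(1, 2)) # 0, -0.5
#' @export
linear_dde_fixture <- function(theta = 1, tau = 1, c = 1) {
  stopifnot(tau > 0)
  model <- build_model(c(
    "[states]", sprintf("x = %.17g", c),
    "[parameters]", sprintf("theta = %.17g", theta),
    "[delays]", sprintf("d1 = %.17g", tau),
    "[equations]", "dx/dt = -theta*x@d1",
    "[options]", "t0 = 0"))
  sol <- function(t) {
    vapply(t, function(tt) {
      if (tt <= 0) return(c)
      jmax <- floor(tt / tau) + 1
      j <- 0:jmax
      c * sum((-theta)^j * (tt - (j - 1) * tau)^j / factorial(j))
    }, numeric(1))
  }
  .fixture(model, analytic_solution = sol,
           notes = "linear decay DDE; method-of-steps piecewise polynomial")
}

#' The TNF-alpha apoptosis signalling fixture (not shipped)
#'
#' The 31-state, 29-parameter TNF-alpha signal transduction model with
#' 20-minute transcription delays is defined only in supplementary material
#' that is not distributed with this package; calling this raises an error of
#' class `ddesens_fixture_missing` describing how to transcribe it into the
#' model file format.
#' @export
tnf_model <- function() {
  stop(structure(
    class = c("ddesens_fixture_missing", "error", "condition"),
    list(message = paste(
      "TNF-alpha fixture not available: transcribe the supplementary model",
      "(31 delay differential equations, 29 parameters, 20-minute",
      "transcription delays for cIAP and IkB, initial conditions per the",
      "supplementary table) into the model file format ([states],",
      "[parameters], [delays], [equations]) and load it with read_model()."),
      call = NULL)))
}

# ---- independent reference integrator --------------------------------------

#' Solve a model with the independent reference integrator
#'
#' Integrates the same parsed model with `deSolve::dede` (adaptive lsoda with
#' its own history interpolation) — an implementation entirely independent of
#' the package's trapezoidal solver, used as an oracle in tests and for
#' finite-difference sensitivities.
#'
#' @param model a [dde_model()].
#' @param grid sampling grid (numeric vector or [sampling_grid()]).
#' @param rtol,atol tolerances handed to `deSolve`.
#' @return matrix of states at `c(t0, grid)` (one row per time), with a
#'   `times` attribute.
#' @export
reference_trajectory <- function(model, grid = NULL, rtol = 1e-10,
                                 atol = 1e-10) {
  pts <- .as_grid(model, grid)
  n <- model$n; m <- model$m
  t0 <- model$t0
  x0 <- unname(model$x0)
  taus <- model$delay_terms$tau
  sidx <- model$delay_terms$state_index
  func <- function(t, y, parms) {
    ylag <- if (m > 0) {
      vapply(seq_len(m), function(k) {
        tl <- t - taus[k]
        if (tl <= t0) x0[sidx[k]] else deSolve::lagvalue(tl, sidx[k])
      }, numeric(1))
    } else numeric(0)
    list(.model_f(model, t, y, ylag))
  }
  out <- deSolve::dede(y = x0, times = c(t0, pts), func = func, parms = NULL,
                       rtol = rtol, atol = atol,
                       control = list(mxhist = 1e5))
  states <- unname(as.matrix(out[, -1, drop = FALSE]))
  colnames(states) <- model$states
  attr(states, "times") <- c(t0, pts)
  states
}

#' Finite-difference dynamic sensitivities (validation oracle)
#'
#' Approximates absolute sensitivities by forward differences: each target
#' parameter or initial condition is perturbed by `spacing_ratio * theta`
#' (absolute fallback `1e-6` when `theta = 0`), the model is re-solved with
#' the independent reference integrator, and `(x_pert - x_base) / delta` is
#' formed at the grid points.  The spacing ratio trades bias against noise;
#' the approximation converges to the exact sensitivity as the ratio goes to
#' zero.
#'
#' @param model a [dde_model()].
#' @param grid sampling grid.
#' @param spacing_ratio relative perturbation size, in (0, 0.5].
#' @param targets character vector of parameter names and/or state names
#'   suffixed `"(0)"` for initial conditions; default: all parameters and
#'   initial conditions.
#' @param solver function `(model, grid) -> states matrix` used for all
#'   solves; defaults to [reference_trajectory()].
#' @return a `sensitivity_series` (same shape as
#'   [solve_with_sensitivities()]'s, restricted to `targets`).
#' @export
finite_difference_sensitivities <- function(model, grid = NULL,
                                            spacing_ratio = 0.01,
                                            targets = NULL,
                                            solver = reference_trajectory) {
  stopifnot(spacing_ratio > 0, spacing_ratio <= 0.5)
  pts <- .as_grid(model, grid)
  all_names <- c(model$param_names, paste0(model$states, "(0)"))
  if (is.null(targets)) targets <- all_names
  bad <- setdiff(targets, all_names)
  if (length(bad)) stop("unknown sensitivity target: ", bad[1])
  theta_all <- stats::setNames(c(model$parameters, model$x0), all_names)
  base <- solver(model, pts)
  k <- nrow(base); n <- model$n
  sens <- array(0, dim = c(k, n, length(targets)))
  for (j in seq_along(targets)) {
    tg <- targets[j]
    th <- theta_all[[tg]]
    delta <- if (th != 0) spacing_ratio * th else 1e-6
    pm <- if (tg %in% model$param_names) {
      set_values(model, parameters = stats::setNames(th + delta, tg))
    } else {
      st <- sub("\\(0\\)$", "", tg)
      set_values(model, x0 = stats::setNames(th + delta, st))
    }
    pert <- solver(pm, pts)
    sens[, , j] <- (pert - base) / delta
  }
  structure(list(
    times = c(model$t0, pts),
    matrices = lapply(seq_len(k), function(ki) {
      phi <- matrix(sens[ki, , ], nrow = n, ncol = length(targets))
      dimnames(phi) <- list(model$states, targets)
      phi
    }),
    state_names = model$states,
    column_names = targets,
    n_parameters = sum(targets %in% model$param_names),
    theta = theta_all[targets]
  ), class = "sensitivity_series")
}

# ---- random expression fuzzing ---------------------------------------------

#' Deterministic random expression generator
#'
#' Draws a random expression graph over the supported operator/intrinsic set
#' together with a binding that keeps every intermediate away from domain
#' boundaries (log and sqrt arguments >= 0.1, |denominators| >= 0.1, |abs
#' arguments| >= 0.1, bounded magnitudes), for fuzz-testing forward-mode AD
#' against finite differences.  Deterministic in `seed`; the global RNG state
#' is left untouched.
#'
#' @param seed integer seed.
#' @param depth maximum expression depth (<= 6).
#' @param n_vars number of free variables (named `v1`, `v2`, ...).
#' @return list with `graph` (an `expr_graph`), `text`, and `binding` (a
#'   binding list whose `state` entry holds the variable values).
#' @export
random_expression_generator <- function(seed, depth = 4L, n_vars = 3L) {
  stopifnot(depth <= 6L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vars <- paste0("v", seq_len(n_vars))
  gen <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.25) {
      if (stats::runif(1) < 0.5) {
        return(sprintf("%.6f", stats::runif(1, 0.5, 2)))
      }
      return(sample(vars, 1))
    }
    kind <- sample(c("bin", "neg", "call"), 1, prob = c(0.55, 0.15, 0.30))
    if (kind == "bin") {
      op <- sample(c("+", "-", "*", "/", "^"), 1,
                   prob = c(0.28, 0.22, 0.28, 0.14, 0.08))
      if (op == "^") {
        return(sprintf("(%s)^%d", gen(d - 1L), sample(2:4, 1)))
      }
      return(sprintf("(%s %s %s)", gen(d - 1L), op, gen(d - 1L)))
    }
    if (kind == "neg") return(sprintf("-(%s)", gen(d - 1L)))
    fun <- sample(c("sin", "cos", "tan", "exp", "log", "sqrt", "abs", "tanh"), 1)
    sprintf("%s(%s)", fun, gen(d - 1L))
  }
  for (attempt in seq_len(200L)) {
    text <- gen(depth)
    graph <- parse_expression(text, vars)
    if (length(graph$free_symbols) == 0L) next
    for (btry in seq_len(50L)) {
      vals <- stats::setNames(stats::runif(n_vars, 0.5, 2), vars)
      binding <- list(state = vals)
      if (.binding_is_safe(graph, binding)) {
        return(list(graph = graph, text = text, binding = binding))
      }
    }
  }
  stop("could not generate a domain-safe expression; widen the limits")
}

# All intermediate node values must stay clear of domain boundaries, both at
# the binding and under the +/- h perturbations a finite-difference check
# will apply.
.binding_is_safe <- function(graph, binding) {
  bs <- .binding_slots(binding)
  tape <- .compile_tape(list(graph), bs$slots)
  tape$roots <- seq_len(tape$n_nodes)
  vals <- tryCatch(.eval_tape(tape, bs$inputs)$values,
                   error = function(e) NULL)
  if (is.null(vals) || any(!is.finite(vals))) return(FALSE)
  if (any(abs(vals) > 1e4)) return(FALSE)
  margin <- 0.1
  for (i in seq_len(tape$n_nodes)) {
    o <- tape$op[i]
    if (o == .OP_DIV && abs(vals[tape$a2[i]]) < margin) return(FALSE)
    if (o %in% c(.OP_LOG, .OP_SQRT) && vals[tape$a1[i]] < margin) return(FALSE)
    if (o == .OP_ABS && abs(vals[tape$a1[i]]) < margin) return(FALSE)
    if (o == .OP_TAN && abs(cos(vals[tape$a1[i]])) < margin) return(FALSE)
    if (o == .OP_POW && vals[tape$a1[i]] >= 0 && vals[tape$a1[i]] < 1e-3)
      return(FALSE)
  }
  TRUE
}
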