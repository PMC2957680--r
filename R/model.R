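# DDE model container.
#
# A model is the system dx/dt = f(x(t), x(t - tau_1), ..., x(t - tau_m); theta)
# with constant initial history x(t) = x0 for t <= t0, together with the
# initial sensitivity matrix Phi0 (n x q, q = p + n: parameter columns first,
# then initial-condition columns, which default to zeros and the identity).

#' Solver configuration
#'
#' @param epsilon stiffness tolerance: the run aborts when `mu * epsilon >= 1`,
#'   where `mu = n(m+n) max|a_ij|` bounds the spectral norm of the Jacobian
#'   over state and delayed-state columns.
#' @param iteration_limit maximum number of corrector iterations per step.
#' @param convergence_rtol,convergence_atol mixed relative/absolute tolerance
#'   for the fixed-point corrector: convergence when every component update
#'   satisfies `|delta| <= atol + rtol * |value|`.
#' @return a `solver_config` list.
#' @export
solver_config <- function(epsilon = 1e-3, iteration_limit = 20L,
                          convergence_rtol = 1e-8, convergence_atol = 1e-12) {
  stopifnot(epsilon > 0, iteration_limit >= 1,
            convergence_rtol > 0, convergence_atol > 0)
  structure(list(epsilon = epsilon,
                 iteration_limit = as.integer(iteration_limit),
                 convergence_rtol = convergence_rtol,
                 convergence_atol = convergence_atol),
            class = "solver_config")
}

#' Sampling grid
#'
#' @param points strictly increasing numeric vector of output times, all
#'   greater than `t0`.
#' @param t0 initial time used for validation.
#' @return numeric vector of class `sampling_grid`.
#' @export
sampling_grid <- function(points, t0 = 0) {
  points <- as.numeric(points)
  if (length(points) == 0) stop("empty sampling grid")
  if (any(diff(points) <= 0)) stop("sampling points must be strictly increasing")
  if (points[1] <= t0) stop("sampling points must all be greater than t0")
  structure(points, class = "sampling_grid")
}

.model_error <- function(msg) {
  stop(structure(
    class = c("ddesens_parse_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Construct a DDE model from parts
#'
#' Lower-level constructor used by [build_model()]; validates cross-references
#' and installs the default initial sensitivity matrix when `phi0` is absent.
#'
#' @param states named numeric vector of initial values (names define the
#'   state order).
#' @param parameters named numeric vector of nominal parameter values.
#' @param delays named numeric vector of delay durations (names are the delay
#'   labels used in `state@label` references).
#' @param equations named character vector (one expression per state, names
#'   matching states) or list of `expr_graph`s.
#' @param t0 initial time (history is `x0` for all `t <= t0`).
#' @param phi0 optional n x q initial sensitivity matrix, q = p + n with
#'   parameter columns first; defaults to `[0 | I]`.
#' @param grid optional default sampling grid (numeric vector).
#' @param config optional default [solver_config()].
#' @return object of class `dde_model`.
#' @export
dde_model <- function(states, parameters = numeric(), delays = numeric(),
                      equations, t0 = 0, phi0 = NULL, grid = NULL,
                      config = solver_config()) {
  if (is.null(names(states)) || any(!nzchar(names(states))))
    .model_error("states must be a named numeric vector")
  n <- length(states)
  p <- length(parameters)
  if (p > 0 && (is.null(names(parameters)) || any(!nzchar(names(parameters)))))
    .model_error("parameters must be named")
  m <- length(delays)
  if (m > 0) {
    if (is.null(names(delays)) || any(!nzchar(names(delays))))
      .model_error("delays must be named (label = duration)")
    if (any(delays <= 0)) .model_error("delay durations must be positive")
  }
  all_names <- c(names(states), names(parameters), names(delays))
  if (anyDuplicated(all_names))
    .model_error(paste0("duplicate identifier: ",
                        all_names[duplicated(all_names)][1]))
  reserved <- intersect(all_names, c("t", "pi"))
  if (length(reserved))
    .model_error(paste0("reserved identifier used: ", reserved[1]))

  declared <- all_names
  if (is.character(equations)) {
    eqs <- lapply(equations, parse_expression, declared_symbols = declared)
    names(eqs) <- names(equations)
  } else {
    eqs <- equations
  }
  if (length(eqs) != n)
    .model_error(sprintf("%d states but %d equations", n, length(eqs)))
  if (!is.null(names(eqs))) {
    missing_eq <- setdiff(names(states), names(eqs))
    if (length(missing_eq))
      .model_error(paste0("no equation for state ", missing_eq[1]))
    eqs <- eqs[names(states)]
  }

  # delayed references: collect the delay terms actually used, in order of
  # first appearance; each is a (state, label) pair y_k = x_j(t - tau_label)
  used <- unique(unlist(lapply(eqs, function(g) g$free_symbols)))
  delayed_used <- grep("@", used, value = TRUE, fixed = TRUE)
  delay_terms <- NULL
  if (length(delayed_used)) {
    parts <- strsplit(delayed_used, "@", fixed = TRUE)
    delay_terms <- data.frame(
      name = delayed_used,
      state = vapply(parts, `[`, "", 1L),
      label = vapply(parts, `[`, "", 2L),
      stringsAsFactors = FALSE
    )
    bad <- !(delay_terms$state %in% names(states))
    if (any(bad))
      .model_error(paste0("delayed reference to non-state: ",
                          delay_terms$name[bad][1]))
    bad <- !(delay_terms$label %in% names(delays))
    if (any(bad))
      .model_error(paste0("unknown delay label in: ", delay_terms$name[bad][1]))
    delay_terms$tau <- unname(delays[delay_terms$label])
    delay_terms$state_index <- match(delay_terms$state, names(states))
  } else {
    delay_terms <- data.frame(name = character(), state = character(),
                              label = character(), tau = numeric(),
                              state_index = integer(), stringsAsFactors = FALSE)
  }
  plain_used <- setdiff(used, delayed_used)
  unknown <- setdiff(plain_used, declared)
  if (length(unknown))
    .model_error(paste0("undeclared symbol: ", unknown[1]))

  q <- p + n
  sens_names <- c(names(parameters), paste0(names(states), "(0)"))
  if (is.null(phi0)) {
    phi0 <- cbind(matrix(0, n, p), diag(1, n, n))
  } else {
    phi0 <- as.matrix(phi0)
    if (!all(dim(phi0) == c(n, q)))
      .model_error(sprintf("phi0 must be %d x %d", n, q))
  }
  dimnames(phi0) <- list(names(states), sens_names)

  m_terms <- nrow(delay_terms)
  model <- structure(list(
    states = names(states),
    x0 = as.numeric(states),
    parameters = as.numeric(parameters),
    param_names = names(parameters),
    delays = as.numeric(delays),
    delay_labels = names(delays),
    delay_terms = delay_terms,
    equations = eqs,
    t0 = t0,
    phi0 = phi0,
    sens_names = sens_names,
    n = n, p = p, m = m_terms, q = q,
    grid = grid,
    config = config,
    .cache = new.env(parent = emptyenv())
  ), class = "dde_model")
  names(model$x0) <- model$states
  names(model$parameters) <- model$param_names
  names(model$delays) <- model$delay_labels
  model
}

#' @export
print.dde_model <- function(x, ...) {
  cat(sprintf("DDE model: %d state(s), %d parameter(s), %d delay term(s)\n",
              x$n, x$p, x$m))
  for (i in seq_len(x$n)) {
    cat(sprintf("  d%s/dt = %s\n", x$states[i], deparse_graph(x$equations[[i]])))
  }
  if (x$m > 0) {
    cat("  delays:",
        paste(sprintf("%s = %g", x$delay_terms$name, x$delay_terms$tau),
              collapse = ", "), "\n")
  }
  cat(sprintf("  t0 = %g, x0 = (%s)\n", x$t0,
              paste(format(x$x0), collapse = ", ")))
  invisible(x)
}

# ---- model file format ------------------------------------------------------
#
# Sectioned plain text, '#' comments, LF or CRLF:
#   [states]      name = initial_value      (order defines state indices)
#   [parameters]  name = value
#   [delays]      label = duration
#   [equations]   dname/dt = expression     (delayed refs as state@label)
#   [phi0]        name = v1 v2 ...          (optional, one row per state)
#   [options]     t0 = ..., sampling = start:stop:step | comma list,
#                 epsilon, iteration_limit, rtol, atol

#' Build a DDE model from model-file text
#'
#' @param model_text character scalar (entire file) or character vector of
#'   lines in the model file format described in the package README.
#' @return a validated [dde_model()].
#' @examples
#' m <- build_model(c("[states]", "x = 1", "[parameters]", "k = 1",
#'                    "[equations]", "dx/dt = -k*x"))
#' @export
build_model <- function(model_text) {
  if (length(model_text) == 1L && grepl("\n", model_text)) {
    model_text <- strsplit(model_text, "\r?\n")[[1]]
  }
  lines <- sub("\r$", "", model_text)
  lines <- sub("#.*$", "", lines)
  section <- ""
  states <- c(); params <- c(); delays <- c()
  eq_names <- character(); eq_texts <- character()
  phi0_rows <- list()
  opts <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    sec <- regmatches(line, regexec("^\\[([a-zA-Z0-9_]+)\\]$", line))[[1]]
    if (length(sec)) {
      section <- tolower(sec[2])
      if (!section %in% c("states", "parameters", "delays", "equations",
                          "phi0", "options"))
        .model_error(sprintf("line %d: unknown section [%s]", ln, section))
      next
    }
    if (section == "")
      .model_error(sprintf("line %d: content before any [section]", ln))
    eq_pos <- regexpr("=", line, fixed = TRUE)
    if (eq_pos < 0)
      .model_error(sprintf("line %d: expected name = value", ln))
    lhs <- trimws(substr(line, 1, eq_pos - 1))
    rhs <- trimws(substr(line, eq_pos + 1, nchar(line)))
    if (section == "equations") {
      mt <- regmatches(lhs, regexec("^d\\s*([a-zA-Z_][a-zA-Z0-9_]*)\\s*/\\s*dt$",
                                    lhs))[[1]]
      if (length(mt) != 2)
        .model_error(sprintf("line %d: equations must be dstate/dt = expr", ln))
      eq_names <- c(eq_names, mt[2]); eq_texts <- c(eq_texts, rhs)
    } else if (section == "options") {
      opts[[tolower(lhs)]] <- rhs
    } else if (section == "phi0") {
      vals <- suppressWarnings(as.numeric(strsplit(rhs, "[,[:space:]]+")[[1]]))
      if (anyNA(vals))
        .model_error(sprintf("line %d: non-numeric phi0 entry", ln))
      phi0_rows[[lhs]] <- vals
    } else {
      val <- suppressWarnings(as.numeric(rhs))
      if (is.na(val))
        .model_error(sprintf("line %d: non-numeric value \"%s\"", ln, rhs))
      if (!grepl("^[a-zA-Z_][a-zA-Z0-9_]*$", lhs))
        .model_error(sprintf("line %d: invalid identifier \"%s\"", ln, lhs))
      v <- stats::setNames(val, lhs)
      if (section == "states") states <- c(states, v)
      else if (section == "parameters") params <- c(params, v)
      else delays <- c(delays, v)
    }
  }
  if (!length(states)) .model_error("model defines no states")
  if (!length(eq_names)) .model_error("model defines no equations")
  dup <- eq_names[duplicated(eq_names)]
  if (length(dup)) .model_error(paste0("duplicate equation for ", dup[1]))
  extra_eq <- setdiff(eq_names, names(states))
  if (length(extra_eq))
    .model_error(paste0("equation for undeclared state ", extra_eq[1]))
  missing_eq <- setdiff(names(states), eq_names)
  if (length(missing_eq))
    .model_error(paste0("no equation for state ", missing_eq[1]))
  equations <- stats::setNames(eq_texts, eq_names)[names(states)]

  t0 <- if (!is.null(opts$t0)) as.numeric(opts$t0) else 0
  grid <- if (!is.null(opts$sampling)) .parse_sampling(opts$sampling, t0) else NULL
  cfg <- solver_config(
    epsilon = if (!is.null(opts$epsilon)) as.numeric(opts$epsilon) else 1e-3,
    iteration_limit = if (!is.null(opts$iteration_limit))
      as.integer(opts$iteration_limit) else 20L,
    convergence_rtol = if (!is.null(opts$rtol)) as.numeric(opts$rtol) else 1e-8,
    convergence_atol = if (!is.null(opts$atol)) as.numeric(opts$atol) else 1e-12
  )
  phi0 <- NULL
  if (length(phi0_rows)) {
    q <- length(params) + length(states)
    phi0 <- matrix(0, length(states), q)
    for (nm in names(phi0_rows)) {
      i <- match(nm, names(states))
      if (is.na(i)) .model_error(paste0("phi0 row for unknown state ", nm))
      if (length(phi0_rows[[nm]]) != q)
        .model_error(sprintf("phi0 row %s must have %d entries", nm, q))
      phi0[i, ] <- phi0_rows[[nm]]
    }
  }
  dde_model(states, params, delays, equations, t0 = t0, phi0 = phi0,
            grid = grid, config = cfg)
}

.parse_sampling <- function(text, t0) {
  text <- trimws(text)
  if (grepl(":", text, fixed = TRUE)) {
    parts <- as.numeric(strsplit(text, ":", fixed = TRUE)[[1]])
    if (length(parts) != 3 || anyNA(parts))
      .model_error("sampling must be start:stop:step or a comma list")
    pts <- seq(parts[1], parts[2], by = parts[3])
  } else {
    pts <- as.numeric(strsplit(text, ",", fixed = TRUE)[[1]])
  }
  pts <- pts[pts > t0]
  sampling_grid(pts, t0)
}

#' Read a model file from disk
#' @param path path to a model file.
#' @return a [dde_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) .model_error(paste0("model file not found: ", path))
  build_model(readLines(path, warn = FALSE))
}

#' Serialize a model back to model-file text
#'
#' The output parses back (via [build_model()]) to an identical model.
#' @param model a [dde_model()].
#' @return character vector of lines.
#' @export
write_model <- function(model) {
  num <- function(x) format(x, digits = 17)
  out <- c("[states]",
           sprintf("%s = %s", model$states, num(model$x0)))
  if (model$p > 0)
    out <- c(out, "[parameters]",
             sprintf("%s = %s", model$param_names, num(model$parameters)))
  if (length(model$delays) > 0)
    out <- c(out, "[delays]",
             sprintf("%s = %s", model$delay_labels, num(model$delays)))
  out <- c(out, "[equations]",
           sprintf("d%s/dt = %s", model$states,
                   vapply(model$equations, deparse_graph, "")))
  default_phi0 <- cbind(matrix(0, model$n, model$p), diag(1, model$n, model$n))
  if (!isTRUE(all.equal(unname(model$phi0), default_phi0))) {
    out <- c(out, "[phi0]",
             vapply(seq_len(model$n), function(i) {
               sprintf("%s = %s", model$states[i],
                       paste(num(model$phi0[i, ]), collapse = " "))
             }, ""))
  }
  out <- c(out, "[options]", sprintf("t0 = %s", num(model$t0)))
  if (!is.null(model$grid))
    out <- c(out, sprintf("sampling = %s",
                          paste(num(as.numeric(model$grid)), collapse = ",")))
  cfg <- model$config
  out <- c(out,
           sprintf("epsilon = %s", num(cfg$epsilon)),
           sprintf("iteration_limit = %d", cfg$iteration_limit),
           sprintf("rtol = %s", num(cfg$convergence_rtol)),
           sprintf("atol = %s", num(cfg$convergence_atol)))
  out
}

#' Constant initial history
#'
#' The initial function on `(-Inf, t0]` is the constant `x0`.
#' @param model a [dde_model()].
#' @param t time at or before `model$t0`.
#' @return named state vector `x0`.
#' @export
initial_history <- function(model, t) {
  stopifnot(t <= model$t0)
  model$x0
}

# ---- compiled system tape ---------------------------------------------------

# Slot layout for the system tape: t, states (n), delayed terms (m), params (p).
.model_tape <- function(model) {
  cache <- model$.cache
  if (!is.null(cache$tape)) return(cache$tape)
  nms <- c("t", model$states, model$delay_terms$name, model$param_names)
  slots <- seq_along(nms); names(slots) <- nms
  tape <- .compile_tape(model$equations, slots)
  n <- model$n; m <- model$m; p <- model$p
  nw <- n + m + p
  seeds <- rep(list(numeric(nw)), length(slots))
  for (j in seq_len(nw)) seeds[[1L + j]][j] <- 1  # slot 1 is time
  cache$tape <- tape
  cache$seeds <- seeds
  tape
}

# f(t, x, y) value only; x, y plain numeric vectors (y in delay-term order)
.model_f <- function(model, t, x, y) {
  tape <- .model_tape(model)
  .eval_tape(tape, c(t, x, y, model$parameters))$values
}

# One AD pass: f values plus A = df/dx (n x n), B = df/dy (n x m),
# C = df/dtheta (n x p), all evaluated at (t, x, y).
.model_jacobians <- function(model, t, x, y) {
  tape <- .model_tape(model)
  out <- .eval_tape(tape, c(t, x, y, model$parameters), model$.cache$seeds)
  n <- model$n; m <- model$m; p <- model$p
  gr <- out$grads
  list(f = out$values,
       A = gr[, seq_len(n), drop = FALSE],
       B = if (m > 0) gr[, n + seq_len(m), drop = FALSE]
           else matrix(0, n, 0),
       C = if (p > 0) gr[, n + m + seq_len(p), drop = FALSE]
           else matrix(0, n, 0))
}

#' System Jacobians by automatic differentiation
#'
#' Evaluates, in a single forward-AD pass per equation system, the Jacobians
#' `A = df/dx` (states), `B = df/dy` (delayed-state terms, one column per
#' delay term in order of first appearance) and `C = df/dtheta` (parameters)
#' at a given point.
#'
#' @param model a [dde_model()].
#' @param state named or plain numeric vector of current state values.
#' @param delayed numeric vector of delayed-state term values (order
#'   `model$delay_terms$name`); may be omitted for ODE systems.
#' @param time evaluation time.
#' @return list with matrices `A` (n x n), `B` (n x m), `C` (n x p) and the
#'   right-hand-side values `f`.
#' @export
system_jacobians <- function(model, state, delayed = numeric(0),
                             time = model$t0) {
  stopifnot(inherits(model, "dde_model"))
  x <- as.numeric(state)
  if (length(x) != model$n) stop("state has wrong length")
  y <- as.numeric(delayed)
  if (length(y) != model$m) stop("delayed has wrong length")
  out <- .model_jacobians(model, time, x, y)
  dimnames(out$A) <- list(model$states, model$states)
  if (model$m > 0) dimnames(out$B) <- list(model$states, model$delay_terms$name)
  if (model$p > 0) dimnames(out$C) <- list(model$states, model$param_names)
  out
}

# Replace parameter values (returns a new model, caches rebuilt lazily).
#' Modify nominal parameter or initial values
#'
#' @param model a [dde_model()].
#' @param parameters named numeric vector of parameter values to replace.
#' @param x0 named numeric vector of initial values to replace.
#' @return a new `dde_model`.
#' @export
set_values <- function(model, parameters = NULL, x0 = NULL) {
  pars <- model$parameters
  if (!is.null(parameters)) {
    bad <- setdiff(names(parameters), model$param_names)
    if (length(bad)) stop("unknown parameter: ", bad[1])
    pars[names(parameters)] <- parameters
  }
  ini <- model$x0
  if (!is.null(x0)) {
    bad <- setdiff(names(x0), model$states)
    if (length(bad)) stop("unknown state: ", bad[1])
    ini[names(x0)] <- x0
  }
  dde_model(states = ini, parameters = pars,
            delays = stats::setNames(model$delays, model$delay_labels),
            equations = model$equations, t0 = model$t0,
            phi0 = model$phi0, grid = model$grid, config = model$config)
}
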