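# Supported grammar: binary + - * / ^, unary -, unary +, and the intrinsic
# set below.  Delayed state references are written name@label; the model file
# maps labels to delay durations.  `pi` and `t` are built-in (constant and
# time reference respectively).
.ddesens_intrinsics <- c("sin", "cos", "tan", "exp", "log", "sqrt", "abs", "tanh")
.ddesens_binops <- c("+", "-", "*", "/", "^")

.parse_error <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("ddesens_parse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.domain_error <- function(msg) {
  stop(structure(
    class = c("ddesens_domain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Parse a model expression into an expression graph
#'
#' Parses a single right-hand-side expression (as used in model files) into a
#' tree of elementary operations suitable for evaluation and forward-mode
#' automatic differentiation.  The grammar is restricted to the five
#' arithmetic operators `+ - * / ^` (usual precedence, `^` right-associative),
#' unary minus, the intrinsics `sin, cos, tan, exp, log, sqrt, abs, tanh`,
#' numeric literals, `pi`, the time symbol `t`, plain identifiers, and delayed
#' state references written `state@label`.
#'
#' @param text single character string with the expression.
#' @param declared_symbols character vector of identifiers that may appear in
#'   the expression (state names, parameter names and delay labels).  Any
#'   other identifier is rejected.
#' @return an object of class `expr_graph` with fields `root` (the node tree)
#'   and `free_symbols` (identifiers actually referenced; delayed references
#'   appear as `"state@label"`).
#' @examples
#' g <- parse_expression("x1 + 2", "x1")
#' evaluate_graph(g, list(state = c(x1 = 3)))
#' @export
parse_expression <- function(text, declared_symbols = character()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) .parse_error("empty expression")
  lang <- tryCatch(
    str2lang(text),
    error = function(e) .parse_error(paste0("syntax error in \"", text, "\": ",
                                            conditionMessage(e)))
  )
  root <- .convert_ast(lang, declared_symbols, text)
  g <- structure(
    list(root = root, free_symbols = sort(unique(.collect_symbols(root)))),
    class = "expr_graph"
  )
  g
}

.convert_ast <- function(e, declared, text) {
  if (is.numeric(e)) {
    return(list(kind = "constant", value = as.numeric(e)))
  }
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm == "pi") return(list(kind = "constant", value = pi))
    if (nm == "t") return(list(kind = "time"))
    if (!(nm %in% declared)) {
      .parse_error(paste0("undeclared symbol \"", nm, "\" in \"", text, "\""))
    }
    return(list(kind = "ref", name = nm))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- as.list(e)[-1]
    if (op == "(") {
      return(.convert_ast(args[[1]], declared, text))
    }
    if (op == "@") {
      if (!is.symbol(args[[1]]) || !is.symbol(args[[2]])) {
        .parse_error(paste0("delayed reference must be state@label in \"",
                            text, "\""))
      }
      nm <- as.character(args[[1]]); lab <- as.character(args[[2]])
      if (!(nm %in% declared)) {
        .parse_error(paste0("undeclared symbol \"", nm, "\" in \"", text, "\""))
      }
      if (!(lab %in% declared)) {
        .parse_error(paste0("undeclared delay label \"", lab, "\" in \"",
                            text, "\""))
      }
      return(list(kind = "delayed_ref", name = nm, label = lab))
    }
    if (op %in% c("-", "+") && length(args) == 1L) {
      return(list(kind = "unary", op = op,
                  children = list(.convert_ast(args[[1]], declared, text))))
    }
    if (op %in% .ddesens_binops && length(args) == 2L) {
      return(list(kind = "binary", op = op,
                  children = list(.convert_ast(args[[1]], declared, text),
                                  .convert_ast(args[[2]], declared, text))))
    }
    if (op %in% .ddesens_intrinsics) {
      if (length(args) != 1L) {
        .parse_error(paste0("intrinsic ", op, "() takes exactly one argument"))
      }
      return(list(kind = "call", fun = op,
                  children = list(.convert_ast(args[[1]], declared, text))))
    }
    .parse_error(paste0("unsupported operator or function \"", op,
                        "\" in \"", text, "\""))
  }
  .parse_error(paste0("unsupported token in \"", text, "\""))
}

.collect_symbols <- function(node) {
  switch(node$kind,
    constant = character(),
    time = character(),
    ref = node$name,
    delayed_ref = paste0(node$name, "@", node$label),
    unlist(lapply(node$children, .collect_symbols), use.names = FALSE)
  )
}

#' Deparse an expression graph back to text
#'
#' Produces a string that reparses to an identical graph (used for model
#' round-trips and error labels).
#' @param g an `expr_graph` or internal node.
#' @return character string.
#' @export
deparse_graph <- function(g) {
  node <- if (inherits(g, "expr_graph")) g$root else g
  .deparse_node(node)
}

.deparse_node <- function(node) {
  switch(node$kind,
    constant = {
      v <- node$value
      if (isTRUE(all.equal(v, pi, tolerance = 1e-15)) && identical(v, pi)) "pi"
      else format(v, digits = 17)
    },
    time = "t",
    ref = node$name,
    delayed_ref = paste0(node$name, "@", node$label),
    unary = paste0(node$op, "(", .deparse_node(node$children[[1]]), ")"),
    binary = paste0("(", .deparse_node(node$children[[1]]), " ", node$op, " ",
                    .deparse_node(node$children[[2]]), ")"),
    call = paste0(node$fun, "(", .deparse_node(node$children[[1]]), ")")
  )
}

# ---- tape compilation -------------------------------------------------------
#
# An expression graph (or a list of them, for a whole system) is flattened
# into a topologically ordered "tape" of elementary operations.  One forward
# pass over the tape computes values; the same pass optionally carries a
# gradient vector per node (forward-mode chain rule, one rule per elementary
# operator), so partial derivatives are exact to round-off.

.OP_CONST <- 1L; .OP_INPUT <- 2L; .OP_ADD <- 3L; .OP_SUB <- 4L
.OP_MUL <- 5L; .OP_DIV <- 6L; .OP_POW <- 7L; .OP_NEG <- 8L
.OP_SIN <- 9L; .OP_COS <- 10L; .OP_TAN <- 11L; .OP_EXP <- 12L
.OP_LOG <- 13L; .OP_SQRT <- 14L; .OP_ABS <- 15L; .OP_TANH <- 16L

# slots: named integer vector mapping input names ("t", states, delayed names,
# parameters) to positions in the flat input vector handed to .eval_tape.
.compile_tape <- function(graphs, slots) {
  env <- new.env(parent = emptyenv())
  env$op <- integer(0); env$a1 <- integer(0); env$a2 <- integer(0)
  env$cval <- numeric(0); env$inp <- integer(0); env$lab <- character(0)
  emit <- function(op, a1 = 0L, a2 = 0L, cval = NA_real_, inp = 0L, lab = "") {
    k <- length(env$op) + 1L
    env$op[k] <- op; env$a1[k] <- a1; env$a2[k] <- a2
    env$cval[k] <- cval; env$inp[k] <- inp; env$lab[k] <- lab
    k
  }
  rec <- function(node) {
    switch(node$kind,
      constant = emit(.OP_CONST, cval = node$value),
      time = {
        if (is.na(slots["t"])) .parse_error("expression uses t but no time slot")
        emit(.OP_INPUT, inp = unname(slots["t"]), lab = "t")
      },
      ref = {
        idx <- slots[node$name]
        if (is.na(idx)) .parse_error(paste0("unresolved symbol ", node$name))
        emit(.OP_INPUT, inp = unname(idx), lab = node$name)
      },
      delayed_ref = {
        nm <- paste0(node$name, "@", node$label)
        idx <- slots[nm]
        if (is.na(idx)) .parse_error(paste0("unresolved delayed symbol ", nm))
        emit(.OP_INPUT, inp = unname(idx), lab = nm)
      },
      unary = {
        c1 <- rec(node$children[[1]])
        if (node$op == "-") emit(.OP_NEG, a1 = c1, lab = .deparse_node(node))
        else c1 # unary plus is the identity
      },
      binary = {
        c1 <- rec(node$children[[1]]); c2 <- rec(node$children[[2]])
        code <- switch(node$op, "+" = .OP_ADD, "-" = .OP_SUB, "*" = .OP_MUL,
                       "/" = .OP_DIV, "^" = .OP_POW)
        emit(code, a1 = c1, a2 = c2, lab = .deparse_node(node))
      },
      call = {
        c1 <- rec(node$children[[1]])
        code <- switch(node$fun, sin = .OP_SIN, cos = .OP_COS, tan = .OP_TAN,
                       exp = .OP_EXP, log = .OP_LOG, sqrt = .OP_SQRT,
                       abs = .OP_ABS, tanh = .OP_TANH)
        emit(code, a1 = c1, lab = .deparse_node(node))
      }
    )
  }
  roots <- vapply(graphs, function(g) {
    rec(if (inherits(g, "expr_graph")) g$root else g)
  }, integer(1))
  list(op = env$op, a1 = env$a1, a2 = env$a2, cval = env$cval,
       inp = env$inp, lab = env$lab, roots = roots, slots = slots,
       n_nodes = length(env$op))
}

# Forward pass over a tape.  inputs: numeric vector in slot order.
# seeds: NULL for value-only evaluation, otherwise a list (one numeric
# gradient vector per slot) seeding d(input)/d(wrt).
# Returns list(values = root values, grads = matrix n_roots x n_wrt or NULL).
.eval_tape <- function(tape, inputs, seeds = NULL) {
  op <- tape$op; a1 <- tape$a1; a2 <- tape$a2
  cval <- tape$cval; inp <- tape$inp
  nn <- tape$n_nodes
  vals <- numeric(nn)
  want_grad <- !is.null(seeds)
  if (want_grad) {
    nw <- length(seeds[[1]])
    zero <- numeric(nw)
    g <- vector("list", nn)
  }
  for (i in seq_len(nn)) {
    o <- op[i]
    if (o == .OP_MUL) {
      va <- vals[a1[i]]; vb <- vals[a2[i]]
      vals[i] <- va * vb
      if (want_grad) g[[i]] <- vb * g[[a1[i]]] + va * g[[a2[i]]]
    } else if (o == .OP_ADD) {
      vals[i] <- vals[a1[i]] + vals[a2[i]]
      if (want_grad) g[[i]] <- g[[a1[i]]] + g[[a2[i]]]
    } else if (o == .OP_INPUT) {
      vals[i] <- inputs[inp[i]]
      if (want_grad) g[[i]] <- seeds[[inp[i]]]
    } else if (o == .OP_CONST) {
      vals[i] <- cval[i]
      if (want_grad) g[[i]] <- zero
    } else if (o == .OP_SUB) {
      vals[i] <- vals[a1[i]] - vals[a2[i]]
      if (want_grad) g[[i]] <- g[[a1[i]]] - g[[a2[i]]]
    } else if (o == .OP_DIV) {
      vb <- vals[a2[i]]
      if (vb == 0) .domain_error(paste0("division by zero in ", tape$lab[i]))
      va <- vals[a1[i]]
      vals[i] <- va / vb
      if (want_grad) g[[i]] <- (g[[a1[i]]] - vals[i] * g[[a2[i]]]) / vb
    } else if (o == .OP_NEG) {
      vals[i] <- -vals[a1[i]]
      if (want_grad) g[[i]] <- -g[[a1[i]]]
    } else if (o == .OP_POW) {
      u <- vals[a1[i]]; v <- vals[a2[i]]
      if (u < 0 && v != round(v)) {
        .domain_error(paste0("negative base with non-integer exponent in ",
                             tape$lab[i]))
      }
      if (u == 0 && v < 0) {
        .domain_error(paste0("zero base with negative exponent in ",
                             tape$lab[i]))
      }
      vals[i] <- u ^ v
      if (want_grad) {
        gv <- g[[a2[i]]]
        if (any(gv != 0)) {
          # exponent depends on the differentiation variables
          if (u <= 0) {
            .domain_error(paste0(
              "derivative of u^v with varying exponent needs u > 0 in ",
              tape$lab[i]))
          }
          g[[i]] <- v * u ^ (v - 1) * g[[a1[i]]] + vals[i] * log(u) * gv
        } else {
          # constant exponent: power rule, valid for all u when v is an
          # integer (the Hill exponent case) and for u > 0 otherwise
          if (u == 0 && v < 1 && v != 0) {
            .domain_error(paste0("derivative of u^v unbounded at u = 0 in ",
                                 tape$lab[i]))
          }
          g[[i]] <- if (v == 0) zero else v * u ^ (v - 1) * g[[a1[i]]]
        }
      }
    } else if (o == .OP_EXP) {
      vals[i] <- exp(vals[a1[i]])
      if (want_grad) g[[i]] <- vals[i] * g[[a1[i]]]
    } else if (o == .OP_SIN) {
      va <- vals[a1[i]]
      vals[i] <- sin(va)
      if (want_grad) g[[i]] <- cos(va) * g[[a1[i]]]
    } else if (o == .OP_COS) {
      va <- vals[a1[i]]
      vals[i] <- cos(va)
      if (want_grad) g[[i]] <- -sin(va) * g[[a1[i]]]
    } else if (o == .OP_TAN) {
      va <- vals[a1[i]]
      vals[i] <- tan(va)
      if (want_grad) g[[i]] <- (1 + vals[i] * vals[i]) * g[[a1[i]]]
    } else if (o == .OP_LOG) {
      va <- vals[a1[i]]
      if (va <= 0) .domain_error(paste0("log of non-positive value in ",
                                        tape$lab[i]))
      vals[i] <- log(va)
      if (want_grad) g[[i]] <- g[[a1[i]]] / va
    } else if (o == .OP_SQRT) {
      va <- vals[a1[i]]
      if (va < 0) .domain_error(paste0("sqrt of negative value in ",
                                       tape$lab[i]))
      vals[i] <- sqrt(va)
      if (want_grad) {
        if (va == 0 && any(g[[a1[i]]] != 0)) {
          .domain_error(paste0("derivative of sqrt unbounded at 0 in ",
                               tape$lab[i]))
        }
        g[[i]] <- if (va == 0) zero else g[[a1[i]]] / (2 * vals[i])
      }
    } else if (o == .OP_ABS) {
      va <- vals[a1[i]]
      vals[i] <- abs(va)
      if (want_grad) {
        if (va == 0 && any(g[[a1[i]]] != 0)) {
          warning("abs() differentiated at 0; using subgradient 0",
                  call. = FALSE)
        }
        g[[i]] <- sign(va) * g[[a1[i]]]
      }
    } else if (o == .OP_TANH) {
      vals[i] <- tanh(vals[a1[i]])
      if (want_grad) g[[i]] <- (1 - vals[i] * vals[i]) * g[[a1[i]]]
    }
  }
  r <- tape$roots
  if (want_grad) {
    gm <- matrix(0, nrow = length(r), ncol = length(seeds[[1]]))
    for (k in seq_along(r)) gm[k, ] <- g[[r[k]]]
    list(values = vals[r], grads = gm)
  } else {
    list(values = vals[r], grads = NULL)
  }
}

# Build slot table and input vector from a Binding-style list.
.binding_slots <- function(b) {
  nms <- c("t", names(b$state), names(b$delayed_state), names(b$parameters))
  vals <- c(if (is.null(b$time)) 0 else b$time,
            unname(b$state), unname(b$delayed_state), unname(b$parameters))
  if (anyDuplicated(nms)) .parse_error("duplicate names in binding")
  slots <- seq_along(nms); names(slots) <- nms
  list(slots = slots, inputs = as.numeric(vals))
}

#' Evaluate an expression graph under a binding
#'
#' @param g an `expr_graph` from [parse_expression()].
#' @param binding list with optional components `time` (scalar), `state`,
#'   `delayed_state` and `parameters` (named numeric vectors).  Delayed values
#'   are keyed by the composite name `"state@label"`.
#' @return the numeric value of the expression.
#' @export
evaluate_graph <- function(g, binding) {
  bs <- .binding_slots(binding)
  tape <- .compile_tape(list(g), bs$slots)
  .eval_tape(tape, bs$inputs)$values
}

#' Value and exact partial derivatives by forward-mode AD
#'
#' Performs a single bottom-up pass over the expression graph carrying a
#' (value, gradient) pair per node: each elementary operator applies its own
#' differentiation rule and combines child gradients by the chain rule.  The
#' value channel is computed by the same pass and is identical to
#' [evaluate_graph()].
#'
#' @inheritParams evaluate_graph
#' @param wrt character vector of reference names (state, delayed state as
#'   `"state@label"`, or parameter) to differentiate with respect to.
#' @return list with `value` (numeric scalar) and `partials` (named numeric
#'   vector, one entry per `wrt` name).
#' @examples
#' g <- parse_expression("sin(2 * x)", "x")
#' forward_partials(g, list(state = c(x = 0)), "x")
#' @export
forward_partials <- function(g, binding, wrt) {
  bs <- .binding_slots(binding)
  tape <- .compile_tape(list(g), bs$slots)
  nw <- length(wrt)
  seeds <- rep(list(numeric(nw)), length(bs$slots))
  for (j in seq_along(wrt)) {
    idx <- bs$slots[wrt[j]]
    if (is.na(idx)) .parse_error(paste0("wrt name not in binding: ", wrt[j]))
    seeds[[idx]][j] <- 1
  }
  out <- .eval_tape(tape, bs$inputs, seeds)
  partials <- drop(out$grads)
  names(partials) <- wrt
  list(value = out$values, partials = partials)
}
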