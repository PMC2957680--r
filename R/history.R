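# Append-only history of accepted nodes (time, state, optional sensitivity),
# with linear interpolation between bracketing nodes and the constant past
# x(t) = x0 for t <= t0.  Node times are strictly increasing; the first node
# sits at t0.  Storage doubles on demand and is never pruned within a run.

new_history <- function(t0, x0, phi0 = NULL) {
  h <- new.env(parent = emptyenv())
  n <- length(x0)
  cap <- 1024L
  h$t0 <- t0
  h$constant_past <- as.numeric(x0)
  h$n <- n
  h$times <- numeric(cap)
  h$states <- matrix(NA_real_, n, cap)
  h$k <- 0L
  h$with_sens <- !is.null(phi0)
  if (h$with_sens) {
    h$q <- ncol(phi0)
    h$sens <- vector("list", cap)
  }
  history_push(h, t0, x0, phi0)
  h
}

history_push <- function(h, t, x, phi = NULL) {
  k <- h$k
  if (k > 0L && t <= h$times[k]) {
    stop("history node times must be strictly increasing")
  }
  if (k == length(h$times)) {
    h$times <- c(h$times, numeric(k))
    h$states <- cbind(h$states, matrix(NA_real_, h$n, k))
    if (h$with_sens) h$sens <- c(h$sens, vector("list", k))
  }
  k <- k + 1L
  h$times[k] <- t
  h$states[, k] <- x
  if (h$with_sens) h$sens[[k]] <- phi
  h$k <- k
  invisible(h)
}

history_latest_time <- function(h) h$times[h$k]

# Locate t in the node list: returns list(exact = idx or 0, lo, hi).
.history_bracket <- function(h, t) {
  k <- h$k
  times <- h$times
  # findInterval over the filled prefix; binary search
  i <- findInterval(t, times[seq_len(k)])
  if (i >= 1L && times[i] == t) return(list(exact = i))
  if (i >= k) {
    stop(sprintf("history lookup at t = %.17g beyond latest node %.17g (step-size bug)",
                 t, times[k]))
  }
  list(exact = 0L, lo = i, hi = i + 1L)
}

#' Interpolate the state history
#'
#' Returns the constant past `x0` for `t <= t0`, the stored state at an exact
#' node time, and otherwise the linear interpolant between the two bracketing
#' accepted nodes.
#'
#' @param h a history buffer as used internally by [solve_dde()] (also
#'   returned in the trajectory's `history` field).
#' @param t lookup time; must not exceed the latest accepted node.
#' @return numeric state vector.
#' @export
interpolate_history <- function(h, t) {
  if (t <= h$t0) return(h$constant_past)
  br <- .history_bracket(h, t)
  if (br$exact > 0L) return(h$states[, br$exact])
  ta <- h$times[br$lo]; tb <- h$times[br$hi]
  w <- (t - ta) / (tb - ta)
  h$states[, br$lo] + w * (h$states[, br$hi] - h$states[, br$lo])
}

# Sensitivity history lookup: Phi0 whenever the lookup time falls at or
# before t0 (the initial sensitivity extends through the constant history),
# stored matrix at exact nodes, linear interpolation otherwise.
history_sens <- function(h, t, phi0) {
  if (t <= h$t0) return(phi0)
  br <- .history_bracket(h, t)
  if (br$exact > 0L) return(h$sens[[br$exact]])
  ta <- h$times[br$lo]; tb <- h$times[br$hi]
  w <- (t - ta) / (tb - ta)
  h$sens[[br$lo]] + w * (h$sens[[br$hi]] - h$sens[[br$lo]])
}

# Delayed-state vector y(t): one entry per delay term of the model.
.delayed_states <- function(model, h, t) {
  m <- model$m
  if (m == 0L) return(numeric(0))
  vapply(seq_len(m), function(k) {
    interpolate_history(h, t - model$delay_terms$tau[k])[model$delay_terms$state_index[k]]
  }, numeric(1))
}

# Delayed sensitivity rows: m x q matrix, row k = Phi(t - tau_k)[state_k, ].
.delayed_sens <- function(model, h, t, phi0) {
  m <- model$m
  q <- model$q
  out <- matrix(0, m, q)
  for (k in seq_len(m)) {
    phi <- history_sens(h, t - model$delay_terms$tau[k], phi0)
    out[k, ] <- phi[model$delay_terms$state_index[k], ]
  }
  out
}
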