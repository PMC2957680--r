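# Sensitivity measures and ranking.
#
# Absolute sensitivities s(x_i, theta_j) = dx_i/dtheta_j are converted to the
# dimensionless relative form S = (theta_j / x_i) s, or the semi-relative form
# S~ = theta_j s when a state passes through zero, and summarized by the
# time-averaged magnitude S_bar = (1/tf) int_0^tf |S| dt for ranking.

#' Relative (log-log) sensitivity
#'
#' `S = (theta / x) * s`, the dimensionless elasticity of a state with
#' respect to a parameter.  Division by a vanishing state is numerically
#' unstable; values of `x` whose magnitude falls below `floor` trigger a
#' warning of class `ddesens_instability_warning` (the semi-relative form is
#' the usual remedy).
#'
#' @param s absolute sensitivity value(s).
#' @param x state value(s), same length as `s` or scalar.
#' @param theta nominal parameter value.
#' @param floor instability floor; defaults to `1e-12 * max(|x|)`.
#' @return numeric vector of relative sensitivities.
#' @export
relative_sensitivity <- function(s, x, theta, floor = NULL) {
  if (is.null(floor)) floor <- 1e-12 * max(abs(x))
  if (any(abs(x) <= floor)) {
    warning(structure(
      class = c("ddesens_instability_warning", "warning", "condition"),
      list(message = paste0(
        "state magnitude at or below instability floor ", format(floor),
        "; relative sensitivities are unreliable (consider semi-relative)"),
        call = NULL)))
  }
  (theta / x) * s
}

#' Semi-relative sensitivity
#'
#' `S~ = theta * s`; carries the units of the state and avoids division by a
#' vanishing state.
#' @inheritParams relative_sensitivity
#' @return numeric vector.
#' @export
semi_relative_sensitivity <- function(s, theta) {
  theta * s
}

#' Time-averaged sensitivity magnitude
#'
#' Trapezoidal quadrature of `|S|` over the sampling grid divided by the
#' window length: `S_bar = 1/(tf - t0) * int |S| dt`.
#'
#' @param times increasing numeric vector of sampling times.
#' @param values sensitivity values at those times.
#' @param t_start,t_f optional averaging window (defaults to the full series;
#'   only grid points inside the window are used).
#' @return nonnegative scalar.
#' @export
time_averaged <- function(times, values, t_start = NULL, t_f = NULL) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (!is.null(t_start) || !is.null(t_f)) {
    lo <- if (is.null(t_start)) -Inf else t_start
    hi <- if (is.null(t_f)) Inf else t_f
    keep <- times >= lo & times <= hi
    times <- times[keep]; values <- values[keep]
    if (length(times) < 2) stop("averaging window contains fewer than 2 points")
  }
  a <- abs(values)
  dt <- diff(times)
  sum(0.5 * dt * (a[-1] + a[-length(a)])) / (times[length(times)] - times[1])
}

# Convert an absolute sensitivity series into relative or semi-relative form.
# Returns a list of matrices aligned with series$matrices.
.convert_series <- function(series, trajectory, mode, allow_unstable = FALSE) {
  mode <- match.arg(mode, c("absolute", "relative", "semi-relative"))
  theta <- series$theta
  if (mode == "absolute") return(series$matrices)
  if (mode == "semi-relative") {
    return(lapply(series$matrices, function(phi) sweep(phi, 2, theta, `*`)))
  }
  if (is.null(trajectory) ||
      !isTRUE(all.equal(series$times, trajectory$times)))
    stop("relative mode needs the trajectory on the same sampling times")
  xmat <- trajectory$states
  floor_per_state <- 1e-12 * apply(abs(xmat), 2, max)
  unstable <- vapply(seq_along(series$state_names), function(i) {
    any(abs(xmat[, i]) <= floor_per_state[i])
  }, logical(1))
  if (any(unstable) && !allow_unstable) {
    stop(structure(
      class = c("ddesens_instability_error", "error", "condition"),
      list(message = paste0(
        "state(s) ", paste(series$state_names[unstable], collapse = ", "),
        " pass through the instability floor; use semi-relative mode or allow_unstable = TRUE"),
        call = NULL)))
  }
  lapply(seq_along(series$times), function(k) {
    phi <- sweep(series$matrices[[k]], 2, theta, `*`)
    phi / xmat[k, ]
  })
}

#' Ranking table of time-averaged sensitivities
#'
#' Builds, for one target state, the ranking of all sensitivity columns
#' (parameters followed by initial conditions) by time-averaged relative or
#' semi-relative sensitivity magnitude.  Percentages are taken against the
#' total over all q columns; ties keep the original column order.
#'
#' @param series a `sensitivity_series` from [solve_with_sensitivities()].
#' @param trajectory the matching `dde_trajectory` (needed for relative mode).
#' @param target_state state name to rank sensitivities for.
#' @param mode `"relative"` or `"semi-relative"`.
#' @param t_start,t_f optional averaging window passed to [time_averaged()].
#' @param allow_unstable set `TRUE` to force relative mode through a state
#'   that passes near zero.
#' @return a `ranking_table` data frame with columns `parameter`,
#'   `time_averaged` and `percentage`, sorted by decreasing value, with
#'   attributes `target_state` and `mode`.
#' @export
rank_table <- function(series, trajectory = NULL, target_state,
                       mode = c("relative", "semi-relative"),
                       t_start = NULL, t_f = NULL, allow_unstable = FALSE) {
  mode <- match.arg(mode)
  i <- match(target_state, series$state_names)
  if (is.na(i)) stop("unknown state: ", target_state)
  conv <- .convert_series(series, trajectory, mode, allow_unstable)
  times <- series$times
  q <- length(series$column_names)
  vals <- vapply(seq_len(q), function(j) {
    sj <- vapply(conv, function(phi) phi[i, j], numeric(1))
    time_averaged(times, sj, t_start = t_start, t_f = t_f)
  }, numeric(1))
  total <- sum(vals)
  pct <- if (total > 0) 100 * vals / total else rep(0, q)
  ord <- order(-vals, seq_len(q))
  out <- data.frame(parameter = series$column_names[ord],
                    time_averaged = vals[ord],
                    percentage = pct[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranking_table", "data.frame"),
            target_state = target_state, mode = mode,
            is_parameter = ord <= series$n_parameters)
}

#' @export
print.ranking_table <- function(x, top = 10L, ...) {
  cat(sprintf("Time-averaged %s sensitivity ranking for %s\n",
              attr(x, "mode"), attr(x, "target_state")))
  df <- as.data.frame(x)
  df$time_averaged <- signif(df$time_averaged, 5)
  df$percentage <- sprintf("%.2f%%", df$percentage)
  print(utils::head(df, top), row.names = TRUE)
  if (nrow(df) > top) cat("  ... ", nrow(df) - top, " more rows\n")
  invisible(x)
}

#' Stacked sensitivity fractions across states
#'
#' Arranges one ranking table per state as columns of fractions of the total
#' sensitivity (each column sums to 1), the data behind 100%-stacked column
#' charts of parameter importance.
#'
#' @param tables list of [rank_table()] results, one per state.
#' @return matrix with one column per state and one row per sensitivity
#'   column, each matrix column summing to 1.
#' @export
stacked_fractions <- function(tables) {
  stopifnot(length(tables) >= 1)
  cols <- lapply(tables, function(tb) {
    v <- stats::setNames(tb$time_averaged, tb$parameter)
    v / sum(v)
  })
  rows <- names(cols[[1]])
  out <- vapply(cols, function(v) v[rows], numeric(length(rows)))
  out <- matrix(out, nrow = length(rows),
                dimnames = list(rows, vapply(tables, attr, "", "target_state")))
  out
}

# ---- exports to disk --------------------------------------------------------

.fmt17 <- function(x) sprintf("%.17g", x)

#' Write a long-format sensitivity series to CSV
#'
#' Columns: `time, state, parameter, absolute, relative, semi_relative`.
#' Numbers are written with 17 significant digits so that re-running a
#' configuration reproduces byte-identical files.
#'
#' @param series a `sensitivity_series`.
#' @param trajectory the matching `dde_trajectory`.
#' @param path output file.
#' @param allow_unstable passed to the relative conversion; when the relative
#'   form is unstable the relative column is written as `NA`.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(series, trajectory, path,
                                  allow_unstable = TRUE) {
  semi <- .convert_series(series, trajectory, "semi-relative")
  rel <- tryCatch(
    .convert_series(series, trajectory, "relative", allow_unstable),
    ddesens_instability_error = function(e) NULL)
  k <- length(series$times)
  nms <- series$column_names
  states <- series$state_names
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("time,state,parameter,absolute,relative,semi_relative", con)
  for (ki in seq_len(k)) {
    abs_k <- series$matrices[[ki]]
    rel_k <- if (is.null(rel)) NULL else rel[[ki]]
    semi_k <- semi[[ki]]
    for (i in seq_along(states)) {
      writeLines(paste(
        .fmt17(series$times[ki]), states[i], nms,
        .fmt17(abs_k[i, ]),
        if (is.null(rel_k)) "NA" else .fmt17(rel_k[i, ]),
        .fmt17(semi_k[i, ]), sep = ","), con)
    }
  }
  invisible(path)
}

#' Write a trajectory to CSV
#' @param trajectory a `dde_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("time", colnames(trajectory$states)), collapse = ","), con)
  for (k in seq_along(trajectory$times)) {
    writeLines(paste(c(.fmt17(trajectory$times[k]),
                       .fmt17(trajectory$states[k, ])), collapse = ","), con)
  }
  invisible(path)
}

#' Write a ranking table to CSV
#' @param table a [rank_table()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(table, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# target_state=%s mode=%s",
                     attr(table, "target_state"), attr(table, "mode")), con)
  writeLines("rank,parameter,time_averaged,percentage", con)
  for (i in seq_len(nrow(table))) {
    writeLines(paste(i, table$parameter[i], .fmt17(table$time_averaged[i]),
                     .fmt17(table$percentage[i]), sep = ","), con)
  }
  invisible(path)
}

#' Write stacked fractions as JSON
#' @param fractions matrix from [stacked_fractions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stacked_json <- function(fractions, path) {
  obj <- lapply(seq_len(ncol(fractions)), function(j) {
    as.list(stats::setNames(fractions[, j], rownames(fractions)))
  })
  names(obj) <- colnames(fractions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
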