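#' Simulate the network model
#'
#' Integrates the 18-variable model with a stiff-capable variable-order
#' multistep solver (`deSolve::ode`, method `"lsoda"`). Integration restarts
#' at every protocol breakpoint so smoking-intensity discontinuities (e.g.
#' cessation) are handled exactly rather than smoothed across. Default
#' initial state is the resting lung (all zeros); default tolerances are
#' `rtol = 1e-8`, `atol = 1e-10`, tight because cell and cytokine scales
#' span several orders of magnitude. Negative undershoots within `10 * atol`
#' are clamped to zero after integration; larger negatives abort with a
#' diagnostic.
#'
#' @param params A `copd_params` table (see [reference_params()]).
#' @param protocol A [smoking_protocol()] or a single constant intensity
#'   (which spans `[0, t_end]`).
#' @param t_end Simulation horizon (days). Defaults to the protocol span.
#' @param initial Initial 18-entry state; default [initial_state()].
#' @param dt_out Output grid spacing in days (the solver's internal steps are
#'   adaptive and unrelated).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param method `deSolve` integration method; default `"lsoda"`.
#' @param maxsteps Maximum internal solver steps per protocol segment.
#' @param on_failure What to do when the solver cannot continue (e.g. a
#'   parameter draw with net positive cell growth overflows): `"error"`
#'   (default) aborts with the failing time; `"partial"` returns the
#'   trajectory up to the failure, marked with attribute `failed = TRUE`
#'   (used by batch drivers such as [run_sensitivity()]).
#' @return A `copd_sim` object: list with `times` (days), `trajectories`
#'   (matrix, one column per state variable), `protocol`, `params`, and
#'   `diagnostics` (tolerances, method, per-segment solver step counts).
#' @examples
#' \donttest{
#' sim <- simulate_copd(reference_params(), constant_smoking(1.67), t_end = 200)
#' peak_time(sim, "M1", window = c(0, 60))
#' }
#' @export
simulate_copd <- function(params, protocol, t_end = NULL,
                          initial = initial_state(), dt_out = 1,
                          rtol = 1e-8, atol = 1e-10, method = "lsoda",
                          maxsteps = 50000, on_failure = c("error", "partial")) {
  on_failure <- match.arg(on_failure)
  params <- as_copd_params(params)
  if (!inherits(protocol, "smoking_protocol")) {
    if (is.null(t_end)) stop("t_end is required with a constant intensity", call. = FALSE)
    protocol <- constant_smoking(protocol, t_end)
  }
  span_end <- protocol$end_day[length(protocol$end_day)]
  if (is.null(t_end)) t_end <- span_end
  if (t_end <= 0 || t_end > span_end) {
    stop("t_end must lie in (0, protocol span]", call. = FALSE)
  }
  validate_state(initial)

  rhs <- make_rhs_fun(params)
  deriv <- function(t, y, parms) list(rhs(t, y, parms))

  y <- unname(initial)
  times_all <- NULL
  traj_all <- NULL
  steps <- integer(0)
  t0 <- 0
  failed <- FALSE
  for (i in seq_along(protocol$S)) {
    if (protocol$start_day[i] >= t_end) break
    seg_end <- min(protocol$end_day[i], t_end)
    times <- unique(c(seq(t0, seg_end, by = dt_out), seg_end))
    out <- suppressWarnings(
      deSolve::ode(y = y, times = times, func = deriv,
                   parms = protocol$S[i], method = method,
                   rtol = rtol, atol = atol, maxsteps = maxsteps))
    bad <- attr(out, "istate")[1L] < 0 || any(!is.finite(out))
    if (bad) {
      out <- out[stats::complete.cases(out) & apply(is.finite(out), 1, all), ,
                 drop = FALSE]
      bad_t <- if (nrow(out)) out[nrow(out), 1L] else t0
      if (on_failure == "error") {
        stop(sprintf("solver failed at t = %.3f days (segment %d, S = %g)",
                     bad_t, i, protocol$S[i]), call. = FALSE)
      }
      failed <- TRUE
      if (nrow(out) == 0) break
    }
    steps <- c(steps, attr(out, "istate")[3L])
    y <- out[nrow(out), -1L]
    keep <- if (is.null(times_all)) seq_len(nrow(out)) else -1L
    times_all <- c(times_all, out[keep, 1L])
    traj_all <- rbind(traj_all, out[keep, -1L, drop = FALSE])
    t0 <- seg_end
    if (failed || seg_end >= t_end) break
  }
  if (is.null(traj_all) || nrow(traj_all) == 0) {
    stop("solver failed immediately; no trajectory available", call. = FALSE)
  }

  neg <- traj_all < 0
  if (any(neg)) {
    # undershoots below solver resolution are clamped; anything larger is a
    # real solver failure
    limit <- max(1e4 * atol, 1e-6 * max(abs(traj_all)))
    worst <- min(traj_all[neg])
    if (worst < -limit && !failed && on_failure == "error") {
      stop(sprintf("integration produced negative values beyond tolerance (min %.3e)",
                   worst), call. = FALSE)
    }
    traj_all[neg] <- 0
  }
  colnames(traj_all) <- state_names()
  structure(list(
    times = as.numeric(times_all),
    trajectories = traj_all,
    protocol = protocol,
    params = params,
    diagnostics = list(rtol = rtol, atol = atol, method = method,
                       solver_steps = steps, failed = failed)
  ), class = "copd_sim")
}

#' @export
print.copd_sim <- function(x, ...) {
  final <- final_state(x)
  cat("<copd_sim> ", length(x$times), " time points over [",
      min(x$times), ", ", max(x$times), "] days\n", sep = "")
  cat("  protocol: ", format(x$protocol), "\n", sep = "")
  cat(sprintf("  final TD = %.1f%% (%s)\n", td_percent(final[["TD"]]),
              classify_copd(final)))
  invisible(x)
}

#' Extract the state at the end of a simulation
#' @param result A `copd_sim`.
#' @return Named 18-entry state vector at the last time point.
#' @export
final_state <- function(result) {
  stopifnot(inherits(result, "copd_sim"))
  stats::setNames(result$trajectories[nrow(result$trajectories), ], state_names())
}

#' State at the steady-state anchor (t = 4000 days)
#'
#' Returns the state at t = 4000 days, the anchor used for all steady-state
#' readouts, with a convergence flag: the run is flagged "not converged"
#' (attribute `converged = FALSE`, plus a warning) if any variable changes
#' by more than `rel_tol` relative over the final 10% of the simulated span.
#'
#' @param result A `copd_sim` spanning at least `at` days.
#' @param rel_tol Maximum tolerated relative change over the final 10% of
#'   the span.
#' @param at Anchor time in days (default 4000).
#' @return Named state vector with attribute `converged` (logical).
#' @export
steady_state <- function(result, rel_tol = 1e-3, at = 4000) {
  stopifnot(inherits(result, "copd_sim"))
  tmax <- max(result$times)
  if (tmax < at) {
    stop(sprintf("simulation spans only %.0f days; steady state is read at t = %.0f",
                 tmax, at), call. = FALSE)
  }
  i_at <- which.min(abs(result$times - at))
  state <- stats::setNames(result$trajectories[i_at, ], state_names())
  i_tail <- result$times >= 0.9 * tmax
  tail_traj <- result$trajectories[i_tail, , drop = FALSE]
  scale <- pmax(apply(abs(tail_traj), 2, max), 1e-12)
  rel_change <- apply(tail_traj, 2, function(v) diff(range(v))) / scale
  converged <- max(rel_change) <= rel_tol
  if (!converged) {
    warning(sprintf("not converged: max relative change %.2e over final 10%% of span",
                    max(rel_change)), call. = FALSE)
  }
  attr(state, "converged") <- converged
  state
}

#' Time of a variable's peak
#'
#' Locates the global maximum of one state variable inside a time window on
#' the solver output grid, then refines it by fitting a local quadratic
#' through the maximum and its two neighbours. Flat trajectories resolve to
#' the earliest time, with a warning.
#'
#' @param result A `copd_sim`.
#' @param variable One of [state_names()].
#' @param window Length-2 day interval to search (default: whole span).
#' @return Peak time in days.
#' @export
peak_time <- function(result, variable, window = range(result$times)) {
  stopifnot(inherits(result, "copd_sim"))
  if (!variable %in% state_names()) stop("unknown variable: ", variable, call. = FALSE)
  sel <- result$times >= window[1] & result$times <= window[2]
  if (!any(sel)) stop("window outside simulation span", call. = FALSE)
  tt <- result$times[sel]
  vv <- result$trajectories[sel, variable]
  if (diff(range(vv)) == 0) {
    warning("flat trajectory in window; returning earliest time", call. = FALSE)
    return(tt[1L])
  }
  i <- which.max(vv)
  if (i == 1L || i == length(vv)) return(tt[i])
  # quadratic through the three points around the grid maximum
  t3 <- tt[(i - 1):(i + 1)]; v3 <- vv[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(v3 ~ t3 + I(t3^2)))
  if (!is.finite(co[3]) || co[3] >= 0) return(tt[i])
  tpk <- -co[2] / (2 * co[3])
  if (tpk < t3[1] || tpk > t3[3]) tt[i] else unname(tpk)
}

#' Tidy and wide exports of a simulation
#'
#' @param x A `copd_sim`.
#' @param row.names,optional,... Ignored; present for the S3 generic.
#' @param long If `TRUE` (default) return tidy columns
#'   `(time_day, variable, value)`; otherwise one column per variable.
#' @return A data frame.
#' @export
as.data.frame.copd_sim <- function(x, row.names = NULL, optional = FALSE,
                                   long = TRUE, ...) {
  wide <- data.frame(time_day = x$times, x$trajectories, check.names = FALSE)
  if (!long) return(wide)
  data.frame(
    time_day = rep(x$times, times = 18L),
    variable = rep(state_names(), each = length(x$times)),
    value = as.vector(x$trajectories),
    stringsAsFactors = FALSE
  )
}

#' Write a simulation result to CSV with a JSON metadata sidecar
#'
#' Writes the tidy long-format trajectory table to `path` and a
#' `<path>.manifest.json` sidecar recording the parameter hash, protocol,
#' solver settings and package version, sufficient to re-run the
#' simulation.
#'
#' @param result A `copd_sim`.
#' @param path Output CSV path.
#' @param long Write tidy long format (default) or wide format.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(result, path, long = TRUE) {
  stopifnot(inherits(result, "copd_sim"))
  utils::write.csv(as.data.frame(result, long = long), path, row.names = FALSE)
  manifest <- run_manifest(
    experiment = "simulate", params = result$params,
    protocol = result$protocol, seed = NULL,
    solver = result$diagnostics
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
plot.copd_sim <- function(x, variables = c("M1", "M2", "TD"), ...) {
  old <- graphics::par(mfrow = c(length(variables), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (v in variables) {
    ylab <- if (v == "TD") "TD (%)" else v
    yv <- if (v == "TD") td_percent(x$trajectories[, v]) else x$trajectories[, v]
    graphics::plot(x$times, yv, type = "l", xlab = "day", ylab = ylab, ...)
  }
  invisible(x)
}
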