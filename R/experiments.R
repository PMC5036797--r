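# Experiment battery: dose-response, smoking cessation, susceptibility
# sweeps and smoker classification, knockout screen, loop screen.
#
# Context-specific tissue-repair rates are stated per experiment, never set
# globally: susceptibility experiments use d_TD = 3.4e-3/day, knockout and
# loop experiments d_TD = 2.9e-3/day.

set_param <- function(params, ...) {
  p <- unclass(as_copd_params(params))
  mods <- c(...)
  p[names(mods)] <- mods
  as_copd_params(p)
}

#' Simulate smoking followed by cessation
#'
#' Constant intensity `S` on `[0, cessation_day)`, zero thereafter,
#' simulated to `t_end` (default 6000 days, long enough to observe
#' post-cessation relaxation). `cessation_day = 0` is the never-smoked run.
#'
#' @param params A `copd_params` table.
#' @param S Smoking intensity before cessation.
#' @param cessation_day Day smoking stops.
#' @param t_end Horizon in days.
#' @param ... Passed to [simulate_copd()].
#' @return A `copd_sim`.
#' @export
run_cessation <- function(params, S, cessation_day, t_end = 6000, ...) {
  simulate_copd(params, cessation_protocol(S, cessation_day, t_end), ...)
}

#' Bisection threshold finder
#'
#' Localises the point where a monotone scalar objective crosses `target`
#' inside `bracket`, by bisection to an interval shorter than `tol`. Every
#' evaluation is recorded.
#'
#' @param objective Function of one numeric argument returning a scalar.
#' @param target Level to cross.
#' @param bracket Length-2 interval whose objective values straddle `target`.
#' @param tol Final bracket width.
#' @return The bracket midpoint, with attribute `evaluations` (data frame of
#'   all `(x, value)` pairs).
#' @examples
#' find_threshold(function(x) x, 0.5, c(0, 1), tol = 1e-6)
#' @export
find_threshold <- function(objective, target, bracket, tol = 1) {
  lo <- bracket[1]; hi <- bracket[2]
  stopifnot(hi > lo, tol > 0)
  f_lo <- objective(lo) - target
  f_hi <- objective(hi) - target
  evals <- data.frame(x = c(lo, hi), value = c(f_lo, f_hi) + target)
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf("no sign change in bracket: f(%g) = %g, f(%g) = %g vs target %g",
                 lo, f_lo + target, hi, f_hi + target, target), call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- objective(mid) - target
    evals <- rbind(evals, data.frame(x = mid, value = f_mid + target))
    if (f_mid == 0) { lo <- mid; hi <- mid; break }
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  structure((lo + hi) / 2, evaluations = evals)
}

#' Classify a smoker's COPD susceptibility
#'
#' Simulates chronic smoking at intensity `S` (steady state read at
#' `t = 4000` days) and smoking followed by cessation at `cessation_day`
#' (read at `t_end`), plus the never-smoked baseline, and applies the
#' three-regime rule: `resistant` if smoking never drives TD above 30%;
#' `reversible` if it does but cessation returns TD to baseline
#' (operationalised as post-cessation TD below twice the never-smoked
#' baseline TD); `severe` if TD stays above 30% even after cessation.
#'
#' @param params A `copd_params` table (set the experiment's `d_TD` first).
#' @param S Smoking intensity.
#' @param cessation_day Cessation day for the cessation arm.
#' @param t_end Post-cessation horizon (days).
#' @param ... Passed to [simulate_copd()].
#' @return A `smoker_class` object: list with `label` and the TD evidence.
#' @export
classify_smoker <- function(params, S, cessation_day = 2500, t_end = 6000, ...) {
  sim_smoke <- simulate_copd(params, constant_smoking(S, max(4000, t_end)),
                             dt_out = 5, ...)
  st_smoke <- steady_state(sim_smoke)
  td_smoke <- st_smoke[["TD"]]
  sim_base <- simulate_copd(params, constant_smoking(0, 4000), dt_out = 5, ...)
  td_base <- steady_state(sim_base)[["TD"]]
  provisional <- !attr(st_smoke, "converged")
  if (td_smoke <= 0.30) {
    label <- "resistant"
    td_cess <- NA_real_
  } else {
    sim_cess <- run_cessation(params, S, cessation_day, t_end, dt_out = 5, ...)
    td_cess <- final_state(sim_cess)[["TD"]]
    label <- if (td_cess > 0.30) "severe" else "reversible"
    if (label == "reversible" && td_cess >= 2 * max(td_base, 1e-4)) {
      # below the COPD line but not back to baseline: still reversible by
      # the 30% rule, flagged provisional
      provisional <- TRUE
    }
  }
  structure(list(label = label, td_smoking = td_smoke,
                 td_post_cessation = td_cess, td_baseline = td_base,
                 provisional = provisional),
            class = "smoker_class")
}

#' @export
print.smoker_class <- function(x, ...) {
  cat("<smoker_class> ", x$label,
      if (x$provisional) " (provisional)", "\n", sep = "")
  cat(sprintf("  TD smoking %.1f%%; post-cessation %s; never-smoked %.2f%%\n",
              td_percent(x$td_smoking),
              if (is.na(x$td_post_cessation)) "-" else
                sprintf("%.1f%%", td_percent(x$td_post_cessation)),
              td_percent(x$td_baseline)))
  invisible(x)
}

#' In-silico knockout screen
#'
#' One knockout simulation per element (wild type included) at constant
#' intensity `S`, reporting steady-state (t = 4000 days) TD and the
#' TNF-alpha, IL-6 and IL-17 levels. The screen's repair rate defaults to
#' the knockout-experiment context `d_TD = 2.9e-3`/day.
#'
#' @param params A `copd_params` table.
#' @param S Smoking intensity (default 1.67).
#' @param elements Elements to knock out (default: the full manifest).
#' @param d_TD Tissue-repair rate used for the screen.
#' @param ... Passed to [simulate_copd()].
#' @return Data frame with one row per scenario: `element`, `TD` (fraction),
#'   `TD_pct`, `Ia`, `I6`, `I17`, `copd`.
#' @export
knockout_screen <- function(params, S = 1.67,
                            elements = names(knockout_manifest()),
                            d_TD = 2.9e-3, ...) {
  params <- set_param(params, d_TD = d_TD)
  run_one <- function(p) {
    st <- steady_state(simulate_copd(p, constant_smoking(S, 4000), dt_out = 5, ...))
    c(TD = st[["TD"]], Ia = st[["Ia"]], I6 = st[["I6"]], I17 = st[["I17"]])
  }
  rows <- lapply(elements, function(el) {
    run_one(apply_intervention(params, intervention("knockout", el)))
  })
  out <- as.data.frame(do.call(rbind, c(list(run_one(params)), rows)))
  out <- cbind(element = c("WT", elements), out)
  out$TD_pct <- td_percent(out$TD)
  out$copd <- vapply(out$TD, classify_copd, "")
  rownames(out) <- NULL
  out
}

#' Feedback-loop screen
#'
#' Runs the four loop-breaking scenarios and the three single-loop
#' activation (sufficiency) scenarios against wild type, at constant
#' intensity `S` with the loop-experiment repair rate
#' `d_TD = 2.9e-3`/day, and reports the steady-state TD together with the
#' endotype signature populations (M1 vs M2 dominance, Th17/CD8 vs Treg
#' dominance).
#'
#' @inheritParams knockout_screen
#' @return Data frame with one row per scenario: `scenario`, `TD`, `TD_pct`,
#'   `M1`, `M2`, `T8`, `T17`, `Tg`, `copd`.
#' @export
loop_screen <- function(params, S = 1.67, d_TD = 2.9e-3, ...) {
  params <- set_param(params, d_TD = d_TD)
  scen <- c(
    list(WT = params),
    stats::setNames(lapply(names(LOOP_BREAK), function(l) {
      apply_intervention(params, intervention("loop_break", l))
    }), paste0("break_", names(LOOP_BREAK))),
    stats::setNames(lapply(names(LOOP_ACTIVATE), function(l) {
      apply_intervention(params, intervention("loop_activate", l))
    }), paste0("activate_", names(LOOP_ACTIVATE)))
  )
  rows <- lapply(scen, function(p) {
    st <- steady_state(simulate_copd(p, constant_smoking(S, 4000), dt_out = 5, ...))
    st[c("TD", "M1", "M2", "T8", "T17", "Tg")]
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(scenario = names(scen), out)
  out$TD_pct <- td_percent(out$TD)
  out$copd <- vapply(out$TD, classify_copd, "")
  rownames(out) <- NULL
  out
}

#' Steady-state dose-response sweep
#'
#' Steady-state (t = 4000 days) TD across a grid of smoking intensities.
#'
#' @param params A `copd_params` table.
#' @param S_grid Intensities to sweep.
#' @param ... Passed to [simulate_copd()].
#' @return Data frame `(S, TD, TD_pct, copd)`.
#' @export
dose_response <- function(params, S_grid = seq(0.1, 2, by = 0.1), ...) {
  td <- vapply(S_grid, function(S) {
    steady_state(simulate_copd(params, constant_smoking(S, 4000),
                               dt_out = 5, ...))[["TD"]]
  }, numeric(1))
  data.frame(S = S_grid, TD = td, TD_pct = td_percent(td),
             copd = vapply(td, classify_copd, ""))
}

#' Critical cessation day
#'
#' Bisection over the cessation day for the prevent/persist boundary: the
#' earliest cessation day for which long-run TD (at `t_end`) stays above the
#' COPD line instead of relaxing to baseline.
#'
#' @param params A `copd_params` table.
#' @param S Smoking intensity before cessation.
#' @param bracket Day interval to search.
#' @param t_end Horizon for the long-run readout.
#' @param tol Bisection tolerance in days.
#' @param criterion Long-run TD level separating relapse from recovery
#'   (default: the 30% COPD line).
#' @param ... Passed to [simulate_copd()].
#' @return Critical day (with bisection `evaluations` attribute).
#' @export
critical_cessation_day <- function(params, S = 1.67, bracket = c(100, 2500),
                                   t_end = 6000, tol = 1, criterion = 0.30,
                                   ...) {
  objective <- function(day) {
    final_state(run_cessation(params, S, day, t_end, ...))[["TD"]]
  }
  find_threshold(objective, criterion, bracket, tol = tol)
}
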