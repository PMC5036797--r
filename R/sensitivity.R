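# Global sensitivity analysis of steady-state tissue damage: Latin
# hypercube sampling over all (sampled) parameters, partial rank
# correlation coefficients with t-test p-values.

#' Latin hypercube sample of parameter tables
#'
#' Stratified uniform sampling per parameter dimension: each parameter's `n`
#' values occupy distinct equal-probability strata of
#' `[lo_frac, hi_frac] * baseline` (the default mirrors the 10%-200% range
#' used for the sensitivity analysis). Structural parameters (Hill
#' coefficient, variant switches) and zero-baseline parameters are excluded
#' (the latter with a warning), since a multiplicative range degenerates
#' there.
#'
#' @param params Baseline `copd_params` table.
#' @param lo_frac,hi_frac Range of the sampled multiplier.
#' @param n Number of samples (>= 2).
#' @param seed Integer seed; the sample is deterministic given it.
#' @param exclude Additional parameter keys to hold at baseline.
#' @return List with `matrix` (`n` x sampled-parameters multiplier-scaled
#'   values), `tables` (list of `n` `copd_params`), `keys`, `range`, `seed`.
#' @export
lhs_sample <- function(params, lo_frac = 0.1, hi_frac = 2.0, n = 2000,
                       seed, exclude = character(0)) {
  params <- as_copd_params(params)
  stopifnot(lo_frac > 0, hi_frac > lo_frac, n >= 2)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  sch <- param_schema()
  keys <- setdiff(sch$key[sch$sampled], exclude)
  zero <- keys[unclass(params)[keys] == 0]
  if (length(zero)) {
    warning("excluding zero-baseline parameter(s): ",
            paste(zero, collapse = ", "), call. = FALSE)
    keys <- setdiff(keys, zero)
  }
  set.seed(seed)
  u <- lhs::randomLHS(n, length(keys))
  base <- matrix(unclass(params)[keys], nrow = n, ncol = length(keys),
                 byrow = TRUE)
  m <- base * (lo_frac + u * (hi_frac - lo_frac))
  colnames(m) <- keys
  tables <- lapply(seq_len(n), function(i) {
    p <- unclass(params)
    p[keys] <- m[i, ]
    as_copd_params(p)
  })
  list(matrix = m, tables = tables, keys = keys,
       range = c(lo_frac, hi_frac), seed = seed)
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every parameter column and the outcome (average ranks on
#' ties), then, for each parameter, correlates the residuals of its ranks
#' regressed on all other parameters' ranks with the residuals of the
#' outcome ranks regressed on the same covariates. p-values come from the
#' t statistic with `n - 2 - q` degrees of freedom (`q` = number of
#' covariates partialled out). Rows with `p >= alpha` are flagged
#' not-significant per the reporting rule.
#'
#' @param samples Numeric matrix, one column per parameter (e.g.
#'   `lhs_sample()$matrix`).
#' @param outcomes Numeric vector of outcomes aligned with the rows (e.g.
#'   steady-state TD at 4000 days).
#' @param alpha Significance level for the `significant` flag.
#' @return A `sensitivity_result` data frame: `parameter`, `prcc`,
#'   `p_value`, `significant`, plus attributes `n` and `alpha`.
#' @export
prcc <- function(samples, outcomes, alpha = 0.01) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (length(outcomes) != n) stop("samples/outcomes misaligned", call. = FALSE)
  if (any(apply(samples, 2, function(v) diff(range(v)) == 0))) {
    stop("constant parameter column(s): ",
         paste(colnames(samples)[apply(samples, 2, stats::sd) == 0],
               collapse = ", "), call. = FALSE)
  }
  rX <- apply(samples, 2, rank)
  ry <- rank(outcomes)
  k <- ncol(rX)
  if (n < k + 3) {
    stop(sprintf("PRCC needs n > #parameters + 2 samples (n = %d, parameters = %d)",
                 n, k), call. = FALSE)
  }
  qr_all <- vector("list", k)
  prcc_v <- p_v <- numeric(k)
  for (j in seq_len(k)) {
    Z <- cbind(1, rX[, -j, drop = FALSE])
    fit <- qr(Z)
    if (fit$rank < ncol(Z)) {
      stop("rank-deficient covariate matrix when partialling out for '",
           colnames(rX)[j], "'", call. = FALSE)
    }
    res_x <- qr.resid(fit, rX[, j])
    res_y <- qr.resid(fit, ry)
    r <- stats::cor(res_x, res_y)
    df <- n - 2 - (k - 1)
    tval <- r * sqrt(df / (1 - r^2))
    prcc_v[j] <- r
    p_v[j] <- 2 * stats::pt(-abs(tval), df)
  }
  out <- data.frame(parameter = colnames(samples), prcc = prcc_v,
                    p_value = p_v, significant = p_v < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "alpha") <- alpha
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' @export
print.sensitivity_result <- function(x, top = 10, ...) {
  n <- attr(x, "n", exact = TRUE)
  cat("<sensitivity_result> n =", if (is.null(n)) nrow(x) else n,
      "samples;", sum(x$significant), "parameters significant at",
      attr(x, "alpha", exact = TRUE), "\n")
  o <- order(-abs(x$prcc))
  print.data.frame(utils::head(x[o, ], top), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the full global sensitivity analysis
#'
#' Draws a Latin hypercube sample of parameter tables, simulates each to the
#' steady-state anchor (t = 4000 days) at constant smoking intensity `S`,
#' and computes PRCCs of TD at t = 4000 against every sampled parameter.
#' Non-converged runs are included in the outcome vector and counted in the
#' result's `n_not_converged` attribute.
#'
#' @inheritParams lhs_sample
#' @param S Smoking intensity for the outcome simulations.
#' @param rtol,atol Solver tolerances for the batch runs (looser than the
#'   single-run defaults; see the methods vignette).
#' @param maxsteps Per-segment solver step cap; draws that exhaust it (net
#'   positive growth overflows) are recorded at their last attained state
#'   and flagged not-converged.
#' @param progress Print progress every 200 runs.
#' @return A `sensitivity_result` (see [prcc()]), with attributes `seed`,
#'   `range`, `S`, `n_not_converged`, and `outcomes`/`samples` for audit.
#' @export
run_sensitivity <- function(params, S = 1.67, lo_frac = 0.1, hi_frac = 2.0,
                            n = 2000, seed, exclude = character(0),
                            rtol = 1e-6, atol = 1e-8, maxsteps = 2000,
                            progress = FALSE) {
  sample <- lhs_sample(params, lo_frac, hi_frac, n, seed, exclude)
  not_conv <- 0L
  outcomes <- vapply(seq_len(n), function(i) {
    sim <- simulate_copd(sample$tables[[i]], constant_smoking(S, 4000),
                         dt_out = 20, rtol = rtol, atol = atol,
                         maxsteps = maxsteps, on_failure = "partial")
    if (progress && i %% 200 == 0) message("  sensitivity run ", i, "/", n)
    if (sim$diagnostics$failed || max(sim$times) < 4000) {
      # overflow draws (net positive growth) saturate damage before the
      # solver gives up; record the last attained TD, flagged not-converged
      not_conv <<- not_conv + 1L
      return(final_state(sim)[["TD"]])
    }
    st <- withCallingHandlers(
      steady_state(sim),
      warning = function(w) {
        if (grepl("not converged", conditionMessage(w))) {
          not_conv <<- not_conv + 1L
          invokeRestart("muffleWarning")
        }
      })
    st[["TD"]]
  }, numeric(1))
  res <- prcc(sample$matrix, outcomes)
  attr(res, "seed") <- seed
  attr(res, "range") <- sample$range
  attr(res, "S") <- S
  attr(res, "n_not_converged") <- not_conv
  attr(res, "outcomes") <- outcomes
  res
}
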