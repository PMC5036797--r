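# Synthetic virtual-smoker cohorts: per-individual perturbations of a
# baseline parameter table plus sampled smoking protocols. All outputs are
# synthetic conventions of this package (no published inter-individual
# distribution exists); they are labelled as such in exports.

#' Generate a synthetic baseline parameter table
#'
#' A plausible stand-in baseline: the packaged reference table with every
#' sampled (non-structural) parameter jittered by an independent
#' log-uniform factor. Deterministic under `seed`. The default jitter is
#' modest (`[0.8, 1.25]`) so generated baselines keep the reference
#' regime structure while exercising every pipeline stage with distinct
#' values; widen it to stress-test.
#'
#' @param seed Integer seed.
#' @param jitter Length-2 multiplicative factor range.
#' @param base Table to perturb (default [reference_params()]).
#' @return A `copd_params` table (synthetic).
#' @export
make_baseline_table <- function(seed, jitter = c(0.8, 1.25),
                                base = reference_params()) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(jitter[1] > 0, jitter[2] >= jitter[1])
  set.seed(seed)
  p <- unclass(as_copd_params(base))
  sch <- param_schema()
  keys <- sch$key[sch$sampled]
  fac <- exp(stats::runif(length(keys), log(jitter[1]), log(jitter[2])))
  p[keys] <- p[keys] * fac
  as_copd_params(p)
}

#' Specify a virtual-smoker cohort
#'
#' @param n_individuals Cohort size (>= 1).
#' @param perturb Named list mapping parameter keys to length-2 ranges of
#'   multiplicative factors (log-uniform), or absolute value ranges when
#'   `absolute = TRUE`. Default: every sampled parameter log-uniform on
#'   `[0.1, 2]` times baseline, mirroring the sensitivity ranges.
#' @param absolute Interpret `perturb` ranges as absolute parameter values
#'   rather than multipliers of the baseline.
#' @param S_range Length-2 range (or single value) of smoking intensities
#'   sampled uniformly per individual.
#' @param cessation_range Length-2 range (or single value) of cessation
#'   days, or `NA` for no cessation.
#' @param seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_individuals, perturb = NULL, absolute = FALSE,
                        S_range = 1.67, cessation_range = NA, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_individuals >= 1)
  if (is.null(perturb)) {
    sch <- param_schema()
    perturb <- stats::setNames(rep(list(c(0.1, 2)), sum(sch$sampled)),
                               sch$key[sch$sampled])
  }
  stopifnot(all(vapply(perturb, length, 0L) == 2L),
            all(vapply(perturb, function(r) r[1] > 0 && r[2] >= r[1], TRUE)))
  structure(list(n_individuals = as.integer(n_individuals), perturb = perturb,
                 absolute = absolute,
                 S_range = rep(S_range, length.out = 2),
                 cessation_range = if (all(is.na(cessation_range))) NA else
                   rep(cessation_range, length.out = 2),
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a virtual-smoker cohort
#'
#' Draws `n_individuals` independently perturbed parameter tables and
#' smoking protocols from a [cohort_spec()]. Perturbed parameters are drawn
#' log-uniformly within their ranges; reproducible under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param baseline Baseline `copd_params` table the perturbations apply to.
#' @param t_end Protocol span (days).
#' @return A `copd_cohort`: list of individuals, each with `id`, `params`,
#'   `protocol`, `S`, `cessation_day`; plus a `manifest()`-able summary via
#'   [cohort_manifest()].
#' @export
generate_cohort <- function(spec, baseline = reference_params(), t_end = 6000) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- unclass(as_copd_params(baseline))
  keys <- names(spec$perturb)
  bad <- setdiff(keys, names(base))
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  set.seed(spec$seed)
  inds <- lapply(seq_len(spec$n_individuals), function(i) {
    p <- base
    for (k in keys) {
      r <- spec$perturb[[k]]
      val <- exp(stats::runif(1, log(r[1]), log(r[2])))
      p[k] <- if (spec$absolute) val else p[k] * val
    }
    S <- stats::runif(1, spec$S_range[1], spec$S_range[2])
    cess <- if (all(is.na(spec$cessation_range))) NA_real_ else
      stats::runif(1, spec$cessation_range[1], spec$cessation_range[2])
    protocol <- if (is.na(cess)) constant_smoking(S, t_end) else
      cessation_protocol(S, cess, t_end)
    list(id = sprintf("ind_%04d", i), params = as_copd_params(p),
         protocol = protocol, S = S, cessation_day = cess)
  })
  structure(list(individuals = inds, spec = spec), class = "copd_cohort")
}

#' @export
print.copd_cohort <- function(x, ...) {
  cat("<copd_cohort> ", length(x$individuals), " synthetic individuals (seed ",
      x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Cohort manifest table
#'
#' One row per individual: id, seed, smoking intensity, cessation day, the
#' individual's values of the perturbed parameters, and (optionally) the
#' computed smoker class.
#'
#' @param cohort A `copd_cohort`.
#' @param classify If `TRUE`, run [classify_smoker()] per individual (slow).
#' @param d_TD Repair rate used when classifying (susceptibility context).
#' @return A data frame.
#' @export
cohort_manifest <- function(cohort, classify = FALSE, d_TD = 3.4e-3) {
  stopifnot(inherits(cohort, "copd_cohort"))
  keys <- names(cohort$spec$perturb)
  rows <- lapply(cohort$individuals, function(ind) {
    row <- data.frame(id = ind$id, seed = cohort$spec$seed, S = ind$S,
                      cessation_day = ind$cessation_day,
                      stringsAsFactors = FALSE)
    cbind(row, as.data.frame(as.list(unclass(ind$params)[keys])))
  })
  out <- do.call(rbind, rows)
  if (classify) {
    out$class <- vapply(cohort$individuals, function(ind) {
      p <- set_param(ind$params, d_TD = d_TD)
      cd <- if (is.na(ind$cessation_day)) 2500 else ind$cessation_day
      classify_smoker(p, ind$S, cd)$label
    }, "")
  }
  out
}

#' Export a cohort to disk
#'
#' Writes one `key = value` parameter file per individual plus a
#' `cohort_manifest.csv`, all clearly labelled as synthetic.
#'
#' @param cohort A `copd_cohort`.
#' @param dir Output directory (created if needed).
#' @param ... Passed to [cohort_manifest()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, ...) {
  stopifnot(inherits(cohort, "copd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ind in cohort$individuals) {
    save_params(ind$params, file.path(dir, paste0(ind$id, "_params.cfg")),
                header = paste("synthetic virtual-smoker parameters,", ind$id))
  }
  utils::write.csv(cohort_manifest(cohort, ...),
                   file.path(dir, "cohort_manifest.csv"), row.names = FALSE)
  invisible(dir)
}
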