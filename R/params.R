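# Parameter table: every rate, half-saturation and decay constant of the
# network model, as a flat named numeric vector of class "copd_params".
# Keys follow the model's symbol names (k1..k15, K1..K12, kI6_TD, d_TD, ...).

# One row per parameter: key, group, unit, short description, and whether the
# parameter is included in global sensitivity sampling (structural switches
# such as the Hill coefficient are not).
PARAM_SCHEMA <- local({
  row <- function(key, group, unit, desc, sampled = TRUE) {
    data.frame(key = key, group = group, unit = unit, description = desc,
               sampled = sampled, stringsAsFactors = FALSE)
  }
  rbind(
    row("k1",  "cell_rate", "cell/(ml day)", "CS-driven M0 -> M1 differentiation (M0 pool pre-folded)"),
    row("k2",  "cell_rate", "cell/(ml day)", "cytokine (IFN-g, TNF-a) driven M0 -> M1 differentiation"),
    row("k3",  "cell_rate", "cell/(ml day)", "tissue-damage driven monocyte recruitment to M1 (Loop 1 edge TD -> M1)"),
    row("k4",  "cell_rate", "cell/(ml day)", "IL-4 / IL-10 driven M0 -> M2 differentiation"),
    row("k5",  "cell_rate", "cell/(ml day)", "CS-driven dendritic-cell maturation (D0 pool pre-folded)"),
    row("k6",  "cell_rate", "cell/(ml day)", "damage-signal driven dendritic-cell maturation"),
    row("k7",  "cell_rate", "cell/(ml day)", "IL-12 driven Th1 differentiation"),
    row("k8",  "cell_rate", "cell/(ml day)", "IL-4 driven Th2 differentiation"),
    row("k9",  "cell_rate", "cell/(ml day)", "IL-21 driven CD8+ T differentiation"),
    row("k10", "cell_rate", "cell/(ml day)", "TGF-b + IL-6 driven Th17 differentiation"),
    row("k11", "cell_rate", "cell/(ml day)", "TGF-b driven Treg differentiation"),
    row("k12", "td_rate", "1/day",          "direct CS -> tissue damage"),
    row("k13", "td_rate", "ml/(cell day)",  "M1-induced tissue damage (proteases, ROS, neutrophil recruitment)"),
    row("k14", "td_rate", "ml/(cell day)",  "CD8+ T-induced tissue damage (granzyme/perforin)"),
    row("k15", "td_rate", "1/day",          "IFN-g / IL-17 induced tissue damage"),
    row("kp1",  "cell_rate", "1/day", "Th1 self-proliferation"),
    row("kp2",  "cell_rate", "1/day", "Th2 self-proliferation"),
    row("kp8",  "cell_rate", "1/day", "CD8+ T self-proliferation"),
    row("kp17", "cell_rate", "1/day", "Th17 self-proliferation"),
    row("kgp",  "cell_rate", "cell/(ml day)", "constant Treg source (IL-10 inhibited)"),
    row("kI4_T2",   "secretion", "pmol ml/(L cell day)", "IL-4 secretion by Th2"),
    row("kI4_TD",   "secretion", "pmol/(L day)",         "IL-4 production by damaged tissue (per unit TD)"),
    row("kI6_M1",   "secretion", "pmol ml/(L cell day)", "IL-6 secretion by M1"),
    row("kI6_TD",   "secretion", "pmol/(L day)",         "IL-6 production by damaged tissue (Loop 2 edge TD -> IL-6)"),
    row("kI10_M2",  "secretion", "pmol ml/(L cell day)", "IL-10 secretion by M2"),
    row("kI10_Tg",  "secretion", "pmol ml/(L cell day)", "IL-10 secretion by Treg"),
    row("kI12_M1",  "secretion", "pmol ml/(L cell day)", "IL-12 secretion by M1 (Loop 3 edge M1 -> IL-12)"),
    row("kI17_T17", "secretion", "pmol ml/(L cell day)", "IL-17 secretion by Th17"),
    row("kI21_T17", "secretion", "pmol ml/(L cell day)", "IL-21 secretion by Th17"),
    row("kIa_M1",   "secretion", "pmol ml/(L cell day)", "TNF-a secretion by M1"),
    row("kIg_T1",   "secretion", "pmol ml/(L cell day)", "IFN-g secretion by Th1"),
    row("kIg_T8",   "secretion", "pmol ml/(L cell day)", "IFN-g secretion by CD8+ T"),
    row("kIb_M2",   "secretion", "pmol ml/(L cell day)", "TGF-b secretion by M2"),
    row("K1",  "half_sat", "pmol/L", "IL-10 inhibition of CS-driven M1 differentiation"),
    row("K2",  "half_sat", "pmol/L", "IFN-g half-saturation in M1 differentiation"),
    row("K3",  "half_sat", "pmol/L", "TNF-a half-saturation in M1 differentiation"),
    row("K4",  "half_sat", "pmol/L", "IL-10 inhibition inside the M1 cytokine-drive term"),
    row("K5",  "half_sat", "pmol/L", "IL-10 inhibition of TD-driven M1 recruitment"),
    row("K6",  "half_sat", "pmol/L", "IL-4 half-saturation in M2 differentiation"),
    row("K7",  "half_sat", "pmol/L", "IL-10 half-saturation in M2 differentiation"),
    row("K8",  "half_sat", "pmol/L", "IL-10 inhibition of CS-driven DC maturation"),
    row("K9",  "half_sat", "pmol/L", "IL-10 inhibition of TD-driven DC maturation"),
    row("K10", "half_sat", "pmol/L", "IL-10 inhibition of CS -> TD generation"),
    row("K11", "half_sat", "pmol/L", "IL-10 inhibition of M1 -> TD generation"),
    row("K12", "half_sat", "pmol/L", "IL-10 inhibition of CD8+T -> TD generation"),
    row("K_TD_Ig",  "half_sat", "pmol/L", "IFN-g half-saturation in cytokine-driven TD term"),
    row("K_TD_I17", "half_sat", "pmol/L", "IL-17 half-saturation in cytokine-driven TD term"),
    row("K_TD_I10", "half_sat", "pmol/L", "IL-10 inhibition in cytokine-driven TD term"),
    row("K_TD_Ib",  "half_sat", "pmol/L", "TGF-b inhibition in cytokine-driven TD term"),
    row("KT1", "half_sat", "pmol/L", "IL-12 half-saturation in Th1 differentiation"),
    row("KT2", "half_sat", "pmol/L", "IL-4 half-saturation in Th2 differentiation"),
    row("KT8", "half_sat", "pmol/L", "IL-21 half-saturation in CD8+ T differentiation"),
    row("KT1_10",  "half_sat", "pmol/L", "IL-10 inhibition of Th1 differentiation"),
    row("KT2_10",  "half_sat", "pmol/L", "IL-10 inhibition of Th2 differentiation"),
    row("KT8_10",  "half_sat", "pmol/L", "IL-10 inhibition of CD8+ T differentiation"),
    row("KT17_10", "half_sat", "pmol/L", "IL-10 inhibition of Th17 differentiation"),
    row("KT1_I10p",  "half_sat", "pmol/L", "IL-10 inhibition of Th1 proliferation"),
    row("KT2_I10p",  "half_sat", "pmol/L", "IL-10 inhibition of Th2 proliferation"),
    row("KT8_I10p",  "half_sat", "pmol/L", "IL-10 inhibition of CD8+ T proliferation"),
    row("KT17_I10p", "half_sat", "pmol/L", "IL-10 inhibition of Th17 proliferation"),
    row("K_T17_I6",  "half_sat", "(pmol/L)^2", "TGF-b x IL-6 product half-saturation in Th17 differentiation"),
    row("K_Tg",      "half_sat", "pmol/L", "TGF-b half-saturation in Treg differentiation"),
    row("K_Tg_I6",   "half_sat", "pmol/L", "IL-6 inhibition of Treg differentiation (Loop 4 edge IL-6 -| Treg)"),
    row("K_pTg_I10", "half_sat", "pmol/L", "IL-10 inhibition of the constant Treg source"),
    row("K_M1_I10",  "half_sat", "pmol/L", "IL-10 inhibition of M1 cytokine secretion"),
    row("K_M2_I10",  "half_sat", "pmol/L", "IL-10 inhibition of M2 cytokine secretion"),
    row("K_T1_I10",  "half_sat", "pmol/L", "IL-10 inhibition of Th1 cytokine secretion"),
    row("K_T2_I10",  "half_sat", "pmol/L", "IL-10 inhibition of Th2 cytokine secretion"),
    row("K_T8_I10",  "half_sat", "pmol/L", "IL-10 inhibition of CD8+ T cytokine secretion"),
    row("K_T17_I10", "half_sat", "pmol/L", "IL-10 inhibition of Th17 cytokine secretion"),
    row("K_I4_I10",  "half_sat", "pmol/L", "IL-10 inhibition of TD-derived IL-4 production"),
    row("K_I6_I10",  "half_sat", "pmol/L", "IL-10 inhibition of TD-derived IL-6 production"),
    row("K_I10_I10", "half_sat", "pmol/L", "IL-10 self-inhibition"),
    row("d_M1",  "decay", "1/day", "M1 decay"),
    row("d_M2",  "decay", "1/day", "M2 decay"),
    row("d_DC",  "decay", "1/day", "DC decay"),
    row("d_T1",  "decay", "1/day", "Th1 decay"),
    row("d_T2",  "decay", "1/day", "Th2 decay"),
    row("d_T8",  "decay", "1/day", "CD8+ T decay"),
    row("d_T17", "decay", "1/day", "Th17 decay"),
    row("d_Tg",  "decay", "1/day", "Treg decay"),
    row("d_I4",  "decay", "1/day", "IL-4 decay"),
    row("d_I6",  "decay", "1/day", "IL-6 decay"),
    row("d_I10", "decay", "1/day", "IL-10 decay"),
    row("d_I12", "decay", "1/day", "IL-12 decay"),
    row("d_I17", "decay", "1/day", "IL-17 decay"),
    row("d_I21", "decay", "1/day", "IL-21 decay"),
    row("d_Ia",  "decay", "1/day", "TNF-a decay"),
    row("d_Ig",  "decay", "1/day", "IFN-g decay"),
    row("d_Ib",  "decay", "1/day", "TGF-b decay"),
    row("d_TD",  "decay", "1/day", "tissue repair (TD decay)"),
    row("n", "structural", "dimensionless", "global Hill coefficient", sampled = FALSE),
    row("tg_prolif_mode", "structural", "flag",
        "0 = constant Treg source term (default); 1 = Treg-proportional variant",
        sampled = FALSE)
  )
})

#' Parameter schema of the network model
#'
#' One row per model parameter: key, group (`cell_rate`, `td_rate`,
#' `secretion`, `half_sat`, `decay`, `structural`), unit, description and
#' whether the parameter is subject to global sensitivity sampling.
#'
#' @return A data frame with columns `key`, `group`, `unit`, `description`,
#'   `sampled`.
#' @export
param_schema <- function() PARAM_SCHEMA

#' Synthetic reference parameter table
#'
#' The package's reference baseline for all simulations and experiment
#' suites. The values are synthetic: they were calibrated once, against the
#' qualitative regime structure the model is built to exhibit (an acute M1
#' peak around two weeks of exposure that resolves by about two months, an
#' M1/M2 dominance switch between high and low smoke doses, a COPD dose
#' threshold at smoking intensity S of about 1, persistence of disease after
#' late smoking cessation, and functioning loop-breaking/activation
#' behaviour), not transcribed from any published table. See the methods
#' vignette for the calibration rationale.
#'
#' @return A `copd_params` object: named numeric vector over all schema keys.
#' @seealso [param_schema()], [load_params()], [apply_intervention()]
#' @export
reference_params <- function() {
  p <- c(
    # cell production / differentiation rates
    k1 = 0.016625, k2 = 0.00998, k3 = 0.1575, k4 = 0.039, k5 = 0.015091, k6 = 0.02,
    k7 = 1.1e-3, k8 = 1.4e-3, k9 = 1.7e-3, k10 = 1.5e-3, k11 = 0.0201,
    # tissue-damage rates
    k12 = 1.108e-4, k13 = 0.0115, k14 = 0.0065, k15 = 9e-4,
    # self-proliferation and Treg source
    kp1 = 0.01, kp2 = 0.01, kp8 = 0.022, kp17 = 0.022, kgp = 0.0072,
    # cytokine secretion
    kI4_T2 = 25, kI4_TD = 4, kI6_M1 = 300, kI6_TD = 5.6,
    kI10_M2 = 110, kI10_Tg = 609, kI12_M1 = 45,
    kI17_T17 = 146, kI21_T17 = 109, kIa_M1 = 151,
    kIg_T1 = 104, kIg_T8 = 62.5, kIb_M2 = 60,
    # half-saturation constants
    K1 = 8, K2 = 5, K3 = 5, K4 = 10, K5 = 10, K6 = 1.5, K7 = 12,
    K8 = 10, K9 = 10, K10 = 12, K11 = 12, K12 = 12,
    K_TD_Ig = 6, K_TD_I17 = 6, K_TD_I10 = 12, K_TD_Ib = 6,
    KT1 = 1, KT2 = 0.4, KT8 = 1,
    KT1_10 = 12, KT2_10 = 20, KT8_10 = 12, KT17_10 = 12,
    KT1_I10p = 12, KT2_I10p = 20, KT8_I10p = 30, KT17_I10p = 30,
    K_T17_I6 = 7, K_Tg = 2.5, K_Tg_I6 = 5.8, K_pTg_I10 = 4,
    K_M1_I10 = 15, K_M2_I10 = 20, K_T1_I10 = 12, K_T2_I10 = 20,
    K_T8_I10 = 12, K_T17_I10 = 12, K_I4_I10 = 12, K_I6_I10 = 12,
    K_I10_I10 = 10,
    # decay rates
    d_M1 = 0.21, d_M2 = 0.2, d_DC = 0.3,
    d_T1 = 0.03, d_T2 = 0.03, d_T8 = 0.03, d_T17 = 0.03, d_Tg = 0.15,
    d_I4 = 2, d_I6 = 2, d_I10 = 1, d_I12 = 2, d_I17 = 2, d_I21 = 2,
    d_Ia = 2, d_Ig = 2, d_Ib = 2, d_TD = 2.9e-3,
    # structural
    n = 2, tg_prolif_mode = 0
  )
  as_copd_params(p)
}

#' Coerce and validate a parameter table
#'
#' @param p Named numeric vector covering exactly the schema keys (any order).
#' @return A validated `copd_params` object in schema key order.
#' @export
as_copd_params <- function(p) {
  keys <- PARAM_SCHEMA$key
  if (is.list(p)) p <- unlist(p)
  if (is.null(names(p))) stop("parameter table must be named", call. = FALSE)
  missing <- setdiff(keys, names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(p), keys)
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- p[keys]
  validate_params(p)
  structure(p, class = "copd_params")
}

#' @rdname as_copd_params
#' @export
validate_params <- function(p) {
  if (any(!is.finite(p))) {
    stop("non-finite parameter value(s): ",
         paste(names(p)[!is.finite(p)], collapse = ", "), call. = FALSE)
  }
  if (any(p < 0)) {
    stop("negative parameter value(s): ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  }
  ks <- PARAM_SCHEMA$key[PARAM_SCHEMA$group == "half_sat"]
  bad <- ks[p[ks] <= 0]
  if (length(bad)) {
    stop("half-saturation constant(s) must be > 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p[["n"]] <= 0) stop("Hill coefficient n must be > 0", call. = FALSE)
  if (!p[["tg_prolif_mode"]] %in% c(0, 1)) {
    stop("tg_prolif_mode must be 0 or 1", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.copd_params <- function(x, ...) {
  cat("<copd_params> ", length(x), " parameters\n", sep = "")
  sch <- param_schema()
  for (g in unique(sch$group)) {
    keys <- sch$key[sch$group == g]
    cat("  ", g, ": ", paste0(keys, "=", signif(unclass(x)[keys], 4), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read / write a parameter table as flat `key = value` text
#'
#' The on-disk format is one `key = value` pair per line (`#` comments and
#' blank lines ignored), mirroring the flat structure of the parameter
#' table. Unknown or missing keys are errors naming the offending keys, so a
#' file always round-trips losslessly through [save_params()] /
#' [load_params()].
#'
#' @param path File path.
#' @param p A `copd_params` table (for `save_params`).
#' @param header Optional comment line(s) written at the top of the file.
#' @return `load_params()` returns a validated `copd_params` object;
#'   `save_params()` returns `path` invisibly.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed line(s) in ", path, " (expected 'key = value')", call. = FALSE)
  }
  keys <- trimws(vapply(parts, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[[`, "", 2L))))
  if (anyNA(vals)) {
    stop("non-numeric value(s) for: ", paste(keys[is.na(vals)], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicated key(s): ", paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  as_copd_params(stats::setNames(vals, keys))
}

#' @rdname load_params
#' @export
save_params <- function(p, path, header = NULL) {
  p <- as_copd_params(p)
  sch <- param_schema()
  lines <- c(
    if (!is.null(header)) paste("#", header),
    paste0(sch$key, " = ", formatC(unclass(p)[sch$key], format = "g", digits = 17),
           "  # ", sch$unit)
  )
  writeLines(lines, path)
  invisible(path)
}
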