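# Right-hand sides of the 18-variable network model.
#
# Cells (M1, M2, DC, T1, T2, T8, T17, Tg): constant precursor pools (M0, D0,
# T0) are pre-folded into the production rates. Cytokines follow a generic
# secretion law: sum over source cells of rate * cell * hill_down(I10, K),
# with tissue damage an extra source for IL-4 and IL-6, minus first-order
# decay. TD integrates smoke-, M1-, CD8-, and cytokine-driven damage against
# first-order repair.

# (cytokine, source, rate key, IL-10-inhibition K key) edges; source "TD" is
# the tissue-damage fraction rather than a cell density. This table *is* the
# wiring of the cytokine layer: rhs_cytokines() is driven by it, so a
# corrected or extended source map is a data change, not a code change.
CYTOKINE_EDGES <- data.frame(
  cytokine = c("I4", "I4", "I6", "I6", "I10", "I10", "I12", "I17", "I21",
               "Ia", "Ig", "Ig", "Ib"),
  source   = c("T2", "TD", "M1", "TD", "M2", "Tg", "M1", "T17", "T17",
               "M1", "T1", "T8", "M2"),
  rate_key = c("kI4_T2", "kI4_TD", "kI6_M1", "kI6_TD", "kI10_M2", "kI10_Tg",
               "kI12_M1", "kI17_T17", "kI21_T17", "kIa_M1", "kIg_T1",
               "kIg_T8", "kIb_M2"),
  K_key    = c("K_T2_I10", "K_I4_I10", "K_M1_I10", "K_I6_I10", "K_I10_I10",
               "K_I10_I10", "K_M1_I10", "K_T17_I10", "K_T17_I10", "K_M1_I10",
               "K_T1_I10", "K_T8_I10", "K_M2_I10"),
  stringsAsFactors = FALSE
)

#' Cytokine source map
#'
#' The (cytokine, source cell) edges of the cytokine layer, with the rate
#' constant and IL-10 inhibition half-saturation key attached to each edge.
#' The right-hand side of the cytokine block is generated from this table.
#'
#' @return Data frame with columns `cytokine`, `source`, `rate_key`, `K_key`.
#' @export
cytokine_sources <- function() CYTOKINE_EDGES

#' Immune-cell derivatives
#'
#' Time derivatives of the eight cell densities (cells/ml/day). M1 is driven
#' by smoke, by an IFN-gamma/TNF-alpha cytokine drive sharing one saturating
#' denominator with IL-10 inhibition, and by tissue damage (the Loop-1 edge);
#' M2 by IL-4/IL-10; DC by smoke and damage; the T-cell subsets by their
#' polarising cytokines with IL-10-inhibited differentiation plus
#' IL-10-inhibited self-proliferation. The Treg source term `kgp` is a
#' constant (IL-10-inhibited) influx by default; set parameter
#' `tg_prolif_mode = 1` for the Treg-proportional variant.
#'
#' @param state Named 18-entry state vector (see [state_names()]).
#' @param params A `copd_params` table.
#' @param S Smoking intensity (dimensionless, >= 0).
#' @return Named numeric vector of the 8 cell derivatives.
#' @export
rhs_cells <- function(state, params, S) {
  y <- as.list(state)
  p <- as.list(params)
  if (S < 0) stop("smoking intensity S must be >= 0", call. = FALSE)
  n <- p$n
  hu2 <- function(x, K) { r <- (x / K)^n; r / (1 + r) }
  hd2 <- function(x, K) 1 / (1 + (x / K)^n)
  with(c(y, p), {
    dM1 <- k1 * S * hd2(I10, K1) +
      k2 * ((Ig / K2)^n + (Ia / K3)^n) /
        (1 + (Ig / K2)^n + (Ia / K3)^n + (I10 / K4)^n) +
      k3 * TD * hd2(I10, K5) - d_M1 * M1
    dM2 <- k4 * ((I4 / K6)^n + (I10 / K7)^n) /
      (1 + (I4 / K6)^n + (I10 / K7)^n) - d_M2 * M2
    dDC <- k5 * S * hd2(I10, K8) + k6 * TD * hd2(I10, K9) - d_DC * DC
    dT1 <- k7 * (I12 / KT1)^n / (1 + (I12 / KT1)^n + (I10 / KT1_10)^n) +
      kp1 * T1 * hd2(I10, KT1_I10p) - d_T1 * T1
    dT2 <- k8 * (I4 / KT2)^n / (1 + (I4 / KT2)^n + (I10 / KT2_10)^n) +
      kp2 * T2 * hd2(I10, KT2_I10p) - d_T2 * T2
    dT8 <- k9 * (I21 / KT8)^n / (1 + (I21 / KT8)^n + (I10 / KT8_10)^n) +
      kp8 * T8 * hd2(I10, KT8_I10p) - d_T8 * T8
    dT17 <- k10 * (Ib * I6 / K_T17_I6)^n /
      (1 + (Ib * I6 / K_T17_I6)^n + (I10 / KT17_10)^n) +
      kp17 * T17 * hd2(I10, KT17_I10p) - d_T17 * T17
    tg_src <- kgp * hd2(I10, K_pTg_I10)
    if (tg_prolif_mode == 1) tg_src <- tg_src * Tg
    dTg <- k11 * (Ib / K_Tg)^n / (1 + (Ib / K_Tg)^n + (I6 / K_Tg_I6)^n) +
      tg_src - d_Tg * Tg
    c(M1 = dM1, M2 = dM2, DC = dDC, T1 = dT1, T2 = dT2, T8 = dT8,
      T17 = dT17, Tg = dTg)
  })
}

#' Cytokine derivatives
#'
#' Time derivatives of the nine cytokine concentrations (pmol/L/day),
#' assembled from the edge table in [cytokine_sources()]: each cytokine is a
#' sum over its source cells of `rate * source * hill_down(I10, K)`, with TD
#' an additional source for IL-4 and IL-6 and IL-10 production inhibited by
#' IL-10 itself, minus first-order decay.
#'
#' @inheritParams rhs_cells
#' @param edges Cytokine source-edge table; defaults to the packaged map
#'   (see [cytokine_sources()]).
#' @return Named numeric vector of the 9 cytokine derivatives.
#' @export
rhs_cytokines <- function(state, params, edges = CYTOKINE_EDGES) {
  p <- unclass(params)
  n <- p[["n"]]
  I10 <- state[["I10"]]
  cyt <- state_names()[9:17]
  prod <- stats::setNames(numeric(9L), cyt)
  src_val <- state[edges$source]
  rate <- p[edges$rate_key]
  K <- p[edges$K_key]
  term <- rate * src_val / (1 + (I10 / K)^n)
  for (i in seq_len(nrow(edges))) {
    prod[[edges$cytokine[i]]] <- prod[[edges$cytokine[i]]] + term[[i]]
  }
  decay <- p[paste0("d_", cyt)] * state[cyt]
  prod - unname(decay)
}

#' Tissue-damage derivative
#'
#' Smoke-, M1-, and CD8-driven damage terms, each scaled by the remaining
#' intact fraction `(1 - TD)` and inhibited by IL-10; a combined
#' IFN-gamma/IL-17 damage term whose shared saturating denominator is
#' inhibited by both IL-10 and TGF-beta; and first-order repair `-d_TD * TD`.
#'
#' @inheritParams rhs_cells
#' @return The scalar dTD/dt (1/day).
#' @export
rhs_td <- function(state, params, S) {
  p <- as.list(params)
  y <- as.list(state)
  if (y$TD < 0 || y$TD > 1) stop("TD must lie in [0, 1]", call. = FALSE)
  if (S < 0) stop("smoking intensity S must be >= 0", call. = FALSE)
  n <- p$n
  hd2 <- function(x, K) 1 / (1 + (x / K)^n)
  with(c(y, p), {
    k12 * S * (1 - TD) * hd2(I10, K10) +
      k13 * M1 * (1 - TD) * hd2(I10, K11) +
      k14 * T8 * (1 - TD) * hd2(I10, K12) +
      k15 * ((Ig / K_TD_Ig)^n + (I17 / K_TD_I17)^n) /
        (1 + (Ig / K_TD_Ig)^n + (I17 / K_TD_I17)^n +
           (I10 / K_TD_I10)^n + (Ib / K_TD_Ib)^n) -
      d_TD * TD
  })
}

#' Full model right-hand side
#'
#' Concatenates [rhs_cells()], [rhs_cytokines()] and [rhs_td()] into the
#' 18-entry derivative vector, evaluating the smoking intensity from a
#' protocol at time `t`. A pure function of `(state, params, S)`.
#'
#' @inheritParams rhs_cells
#' @param protocol A [smoking_protocol()], or a single nonnegative number
#'   used as a constant intensity.
#' @param t Time in days (used to look up S in the protocol).
#' @return Named numeric vector of 18 derivatives in canonical state order.
#' @export
copd_rhs <- function(state, params, protocol, t = 0) {
  S <- if (inherits(protocol, "smoking_protocol")) {
    protocol_intensity(protocol, t)
  } else {
    protocol
  }
  validate_state(state)
  c(rhs_cells(state, params, S),
    rhs_cytokines(state, params),
    TD = rhs_td(state, params, S))
}

# Fast unchecked RHS used by the integrator: y and p are plain numeric
# vectors in canonical order; edges pre-resolved to integer indices.
make_rhs_fun <- function(params, edges = CYTOKINE_EDGES) {
  p <- unclass(as_copd_params(params))
  e_tgt <- match(edges$cytokine, state_names())
  e_src <- match(edges$source, state_names())
  e_rate <- unname(p[edges$rate_key])
  e_K <- unname(p[edges$K_key])
  d_cyt <- unname(p[paste0("d_", state_names()[9:17])])
  n <- p[["n"]]
  list2env(as.list(p), environment())
  function(t, y, S) {
    y[y < 0] <- 0
    M1 <- y[1L]; M2 <- y[2L]; DC <- y[3L]; T1 <- y[4L]; T2 <- y[5L]
    T8 <- y[6L]; T17 <- y[7L]; Tg <- y[8L]
    I4 <- y[9L]; I6 <- y[10L]; I10 <- y[11L]; I12 <- y[12L]; I17 <- y[13L]
    I21 <- y[14L]; Ia <- y[15L]; Ig <- y[16L]; Ib <- y[17L]; TD <- y[18L]
    i10n <- function(K) 1 / (1 + (I10 / K)^n)
    rIg <- (Ig / K2)^n; rIa <- (Ia / K3)^n
    dy <- numeric(18L)
    dy[1L] <- k1 * S * i10n(K1) +
      k2 * (rIg + rIa) / (1 + rIg + rIa + (I10 / K4)^n) +
      k3 * TD * i10n(K5) - d_M1 * M1
    r4 <- (I4 / K6)^n; r10 <- (I10 / K7)^n
    dy[2L] <- k4 * (r4 + r10) / (1 + r4 + r10) - d_M2 * M2
    dy[3L] <- k5 * S * i10n(K8) + k6 * TD * i10n(K9) - d_DC * DC
    r12 <- (I12 / KT1)^n
    dy[4L] <- k7 * r12 / (1 + r12 + (I10 / KT1_10)^n) +
      kp1 * T1 * i10n(KT1_I10p) - d_T1 * T1
    r4b <- (I4 / KT2)^n
    dy[5L] <- k8 * r4b / (1 + r4b + (I10 / KT2_10)^n) +
      kp2 * T2 * i10n(KT2_I10p) - d_T2 * T2
    r21 <- (I21 / KT8)^n
    dy[6L] <- k9 * r21 / (1 + r21 + (I10 / KT8_10)^n) +
      kp8 * T8 * i10n(KT8_I10p) - d_T8 * T8
    rb6 <- (Ib * I6 / K_T17_I6)^n
    dy[7L] <- k10 * rb6 / (1 + rb6 + (I10 / KT17_10)^n) +
      kp17 * T17 * i10n(KT17_I10p) - d_T17 * T17
    rb <- (Ib / K_Tg)^n
    tg_src <- kgp * i10n(K_pTg_I10)
    if (tg_prolif_mode == 1) tg_src <- tg_src * Tg
    dy[8L] <- k11 * rb / (1 + rb + (I6 / K_Tg_I6)^n) + tg_src - d_Tg * Tg
    prod <- e_rate * y[e_src] / (1 + (I10 / e_K)^n)
    for (i in seq_along(e_tgt)) dy[e_tgt[i]] <- dy[e_tgt[i]] + prod[i]
    dy[9:17] <- dy[9:17] - d_cyt * y[9:17]
    omTD <- 1 - TD
    rg <- (Ig / K_TD_Ig)^n; r17 <- (I17 / K_TD_I17)^n
    dy[18L] <- k12 * S * omTD * i10n(K10) +
      k13 * M1 * omTD * i10n(K11) +
      k14 * T8 * omTD * i10n(K12) +
      k15 * (rg + r17) /
        (1 + rg + r17 + (I10 / K_TD_I10)^n + (Ib / K_TD_Ib)^n) -
      d_TD * TD
    dy
  }
}
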