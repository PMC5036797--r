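# Independent oracles for the model core: a second, separately written
# transcription of the 18 right-hand sides (using the algebraically
# equivalent x^n/(K^n + x^n) Hill forms), and a fixed-step RK4 integrator
# built on it. Kept deliberately naive and independent of R/model.R.

oracle_rhs <- function(y, p, S) {
  e <- as.list(c(y, unclass(p)))
  with(e, {
    up <- function(x, K) x^n / (K^n + x^n)
    dn <- function(x, K) K^n / (K^n + x^n)

    # M1: smoke source, IFN-g/TNF-a drive with shared saturating denominator
    # carrying IL-10 inhibition, damage-driven recruitment, decay
    drive_num <- (Ig / K2)^n + (Ia / K3)^n
    dM1 <- k1 * S * dn(I10, K1) +
      k2 * drive_num / (1 + drive_num + (I10 / K4)^n) +
      k3 * TD * dn(I10, K5) - d_M1 * M1
    # M2: IL-4 or IL-10 drive (shared denominator, saturating)
    m2num <- (I4 / K6)^n + (I10 / K7)^n
    dM2 <- k4 * m2num / (1 + m2num) - d_M2 * M2
    # DC
    dDC <- k5 * S * dn(I10, K8) + k6 * TD * dn(I10, K9) - d_DC * DC
    # T cells: differentiation with IL-10 inhibition inside the denominator
    tcell <- function(kd, I_drv, Kd, K10d, kp, Kp, Tv, dT) {
      a <- (I_drv / Kd)^n
      kd * a / (1 + a + (I10 / K10d)^n) + kp * Tv * dn(I10, Kp) - dT * Tv
    }
    dT1 <- tcell(k7, I12, KT1, KT1_10, kp1, KT1_I10p, T1, d_T1)
    dT2 <- tcell(k8, I4, KT2, KT2_10, kp2, KT2_I10p, T2, d_T2)
    dT8 <- tcell(k9, I21, KT8, KT8_10, kp8, KT8_I10p, T8, d_T8)
    a17 <- (Ib * I6 / K_T17_I6)^n
    dT17 <- k10 * a17 / (1 + a17 + (I10 / KT17_10)^n) +
      kp17 * T17 * dn(I10, KT17_I10p) - d_T17 * T17
    ab <- (Ib / K_Tg)^n
    src <- kgp * dn(I10, K_pTg_I10)
    if (tg_prolif_mode == 1) src <- src * Tg
    dTg <- k11 * ab / (1 + ab + (I6 / K_Tg_I6)^n) + src - d_Tg * Tg

    # cytokines (source map written out by hand)
    dI4 <- kI4_T2 * T2 * dn(I10, K_T2_I10) + kI4_TD * TD * dn(I10, K_I4_I10) -
      d_I4 * I4
    dI6 <- kI6_M1 * M1 * dn(I10, K_M1_I10) + kI6_TD * TD * dn(I10, K_I6_I10) -
      d_I6 * I6
    dI10 <- (kI10_M2 * M2 + kI10_Tg * Tg) * dn(I10, K_I10_I10) - d_I10 * I10
    dI12 <- kI12_M1 * M1 * dn(I10, K_M1_I10) - d_I12 * I12
    dI17 <- kI17_T17 * T17 * dn(I10, K_T17_I10) - d_I17 * I17
    dI21 <- kI21_T17 * T17 * dn(I10, K_T17_I10) - d_I21 * I21
    dIa <- kIa_M1 * M1 * dn(I10, K_M1_I10) - d_Ia * Ia
    dIg <- kIg_T1 * T1 * dn(I10, K_T1_I10) + kIg_T8 * T8 * dn(I10, K_T8_I10) -
      d_Ig * Ig
    dIb <- kIb_M2 * M2 * dn(I10, K_M2_I10) - d_Ib * Ib

    # tissue damage
    cg <- (Ig / K_TD_Ig)^n
    c17 <- (I17 / K_TD_I17)^n
    dTD <- k12 * S * (1 - TD) * dn(I10, K10) +
      k13 * M1 * (1 - TD) * dn(I10, K11) +
      k14 * T8 * (1 - TD) * dn(I10, K12) +
      k15 * (cg + c17) /
        (1 + cg + c17 + (I10 / K_TD_I10)^n + (Ib / K_TD_Ib)^n) -
      d_TD * TD

    c(M1 = dM1, M2 = dM2, DC = dDC, T1 = dT1, T2 = dT2, T8 = dT8,
      T17 = dT17, Tg = dTg, I4 = dI4, I6 = dI6, I10 = dI10, I12 = dI12,
      I17 = dI17, I21 = dI21, Ia = dIa, Ig = dIg, Ib = dIb, TD = dTD)
  })
}

# classical RK4 with fixed step on the oracle RHS; constant S
oracle_rk4 <- function(y0, p, S, t_end, h) {
  nst <- ceiling(t_end / h)
  y <- unname(y0)
  f <- function(y) unname(oracle_rhs(stats::setNames(pmax(y, 0), state_names()), p, S))
  for (i in seq_len(nst)) {
    k1v <- f(y)
    k2v <- f(y + h / 2 * k1v)
    k3v <- f(y + h / 2 * k2v)
    k4v <- f(y + h * k3v)
    y <- y + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  }
  stats::setNames(pmax(y, 0), state_names())
}

# random strictly-positive state in physiological ranges
random_state <- function() {
  initial_state(
    M1 = runif(1, 0, 2), M2 = runif(1, 0, 2), DC = runif(1, 0, 2),
    T1 = runif(1, 0, 1), T2 = runif(1, 0, 1), T8 = runif(1, 0, 1),
    T17 = runif(1, 0, 1), Tg = runif(1, 0, 1),
    I4 = runif(1, 0, 10), I6 = runif(1, 0, 30), I10 = runif(1, 0, 30),
    I12 = runif(1, 0, 10), I17 = runif(1, 0, 20), I21 = runif(1, 0, 10),
    Ia = runif(1, 0, 30), Ig = runif(1, 0, 20), Ib = runif(1, 0, 10),
    TD = runif(1, 0, 1)
  )
}

# random valid table: log-uniform jitter of the reference values
random_params <- function(lo = 0.5, hi = 2) {
  p <- unclass(reference_params())
  sch <- param_schema()
  keys <- sch$key[sch$sampled]
  p[keys] <- p[keys] * exp(runif(length(keys), log(lo), log(hi)))
  as_copd_params(p)
}
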