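---
title: "An immune-network ODE model of smoke-induced COPD progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An immune-network ODE model of smoke-induced COPD progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`copdnet` implements a coarse-grained network model of the immune response
that cigarette smoke (CS) provokes in the lung, and of the progressive
tissue destruction that defines chronic obstructive pulmonary disease
(COPD). The network couples 18 dynamical variables:

* eight immune-cell densities — classically activated (inflammatory) `M1`
  and alternatively activated `M2` macrophages, mature dendritic cells
  `DC`, and the Th1 (`T1`), Th2 (`T2`), CD8+ (`T8`), Th17 (`T17`) and
  regulatory (`Tg`) T-cell populations;
* nine cytokine concentrations (pmol/L) — IL-4, IL-6, IL-10, IL-12, IL-17,
  IL-21, TNF-$\alpha$, IFN-$\gamma$, TGF-$\beta$ (`I4` ... `Ib`);
* the tissue-damage fraction `TD` = damaged / (normal + damaged) lung
  parenchyma, kept internally in $[0,1]$ and reported as a percentage.
  A steady `TD` above 30% is read as COPD.

Every regulatory input is a Hill function with global coefficient $n = 2$:
$h^+(x;K) = (x/K)^n / (1 + (x/K)^n)$ for activation and
$h^-(x;K) = 1/(1 + (x/K)^n)$ for inhibition (IL-10 inhibits nearly every
production process in the network). Cells follow

$$\frac{dM_1}{dt} = k_1 S\, h^-\!(I_{10}) +
  k_2 \frac{(I_\gamma/K_2)^2 + (I_\alpha/K_3)^2}
           {1 + (I_\gamma/K_2)^2 + (I_\alpha/K_3)^2 + (I_{10}/K_4)^2} +
  k_3 T_D\, h^-\!(I_{10}) - d_{M1} M_1$$

and analogous saturating laws (see `rhs_cells()`); constant precursor
pools (M0, D0, naive T cells) are pre-folded into the production rates.
Each T-cell subset is polarised by its canonical cytokine milieu (IL-12
for Th1, IL-4 for Th2, IL-21 for CD8+, the TGF-$\beta \times$IL-6 product
for Th17, TGF-$\beta$ opposed by IL-6 for Treg) and self-renews under
IL-10 control. Cytokines follow a generic secretion law — a sum over
source cells of $k_{i,j} C_j h^-(I_{10}; K_{C_j,I10})$, with damaged
tissue an extra source for IL-4 and IL-6 and IL-10 inhibiting its own
production — the wiring is data, exposed by `cytokine_sources()`, so a
corrected source map is a configuration change. Damage integrates
smoke-, M1- and CD8-driven destruction, each scaled by the intact
fraction $(1 - T_D)$ and inhibited by IL-10, plus a combined
IFN-$\gamma$/IL-17 term inhibited by IL-10 and TGF-$\beta$, against
first-order repair $-d_{TD} T_D$ (`rhs_td()`).

The smoking intensity $S(t)$ is piecewise constant
(`smoking_protocol()`); $S$ is dimensionless, defined as the ratio of the
CS dose to the minimal dose that causes COPD under the reference
parameters, so the COPD dose threshold sits at $S \approx 1$ by
construction.

Four positive feedback loops organise the dynamics: Loop 1
(M1 → TD → M1, edge `k3`), Loop 2 (IL-6 → Th17 → IL-17 → TD → IL-6, edge
`kI6_TD`), Loop 3 (M1 → IL-12 → Th1 → IFN-$\gamma$ → M1, edge
`kI12_M1`), and Loop 4 (IL-6 ⊣ Treg → IL-10 ⊣ Th17 → IL-17 → TD → IL-6,
edge `K_Tg_I6`). `intervention()` encodes breaking a loop on its edge
(rates to zero; `K_Tg_I6` to $10^4$ pmol/L for Loop 4) and single-loop
activation (`k3` = 1.9e6 cell/(ml day), `kI6_TD` = 22.0 pmol/(L day),
`K_Tg_I6` = 2.3 pmol/L, with the other loops broken).

## The synthetic reference table

The package's baseline parameter table, `reference_params()`, is
**synthetic**: it was not transcribed from a published table. It was
calibrated once, at design time, against the qualitative regime structure
the model is meant to exhibit, and then frozen:

* an acute inflammatory phase in which M1, TNF-$\alpha$ and IL-6 peak
  about two weeks into exposure and decline toward day 60 as IL-10
  (secreted mainly by M2 and Treg) catches up;
* a COPD dose threshold at $S = 1$ (definitional, enforced by rescaling
  the three smoke-coupled rates `k1`, `k5`, `k12`);
* low-grade chronic inflammation without COPD at $S = 0.7$
  (M2 and Treg dominant, steady TD below 5%);
* escalation to stable COPD at $S = 1.67$ (TD ≈ 57%, M1 over M2, late
  adaptive dominance through CD8+/Th17);
* bistability: quitting smoking early returns TD to baseline, quitting
  after a critical day (≈ 700 days under this table) leaves COPD
  self-sustained by Loops 1 and 2 and the slow T-cell memory;
* three susceptibility regimes in the M1-damage rate `k13` at repair rate
  `d_TD` = 3.4e-3/day — resistant below ≈ 2.1e-3, reversible up to
  ≈ 1.0e-2, severe beyond (cessation at day 2500 no longer reverses
  disease).

Cell densities are carried in normalized units of order 0.01–1
(≈ $10^5$–$10^6$ cells/ml); this scale is forced by the zero initial
conditions: with damage rates of order $10^{-2}$ ml/(cell day), any table
whose M1 transient reaches large absolute densities before IL-10 exists
would destroy the simulated lung in the first week. A consequence is that
several reported magnitudes from the literature this model echoes (the
`k13` regime boundaries, the Loop-1 sufficiency value) are not reproduced
numerically by the synthetic table, only structurally; the loop-activation
values above act as "very large"/"very strong" settings on our scale.
Passing tests therefore demonstrate the mechanism — regime structure,
loop necessity/sufficiency patterns, sensitivity ranking — not agreement
with any particular experimental quantification. Known quantitative
departures under the synthetic table: the critical cessation day is ≈ 700
rather than ≈ 920; breaking Loop 2 barely lowers steady damage (IL-6 here
is mostly macrophage-derived); Loop-2/Loop-4 activation alone reaches
TD of 7%/27% rather than full COPD; IFN-$\gamma$ and IL-17 knockouts are
milder than published; and the CD8-damage rate `k14` does not carry a
large PRCC. All are consequences of where this one hand-built table
places each damage channel relative to criticality.

Per-experiment repair rates follow the published contexts: the table
default `d_TD` = 2.9e-3/day is also the knockout/loop-screen value;
susceptibility sweeps use 3.4e-3/day. These are set explicitly by the
experiment functions, never globally.

## Numerics

* **Integrator.** `deSolve::ode(method = "lsoda")`, a stiff-capable
  variable-order multistep solver. Tolerances default to
  `rtol = 1e-8`, `atol = 1e-10` for single trajectories (state variables
  span several orders of magnitude); batch sensitivity runs use
  `1e-6`/`1e-8` with a per-interval step cap — halving the tolerances
  moves steady-state TD by well under 0.1% (tested).
* **Protocol discontinuities.** Integration restarts at every protocol
  breakpoint, so cessation steps are never smoothed across.
* **Nonnegativity.** The continuous flow cannot cross zero (every loss
  term vanishes with its own variable); numerical undershoots below the
  solver's resolution are clamped to zero after integration, larger
  negatives abort.
* **Steady state.** Read at t = 4000 days, the anchor used for all
  steady readouts; a run is flagged "not converged" when any variable
  moves more than 0.1% (relative) over the final 10% of the span. Slow
  parameter draws (small `d_TD`) are genuinely unconverged at 4000 days;
  they are included in sensitivity outcomes but counted in the
  `n_not_converged` attribute.
* **Peaks.** `peak_time()` refines the grid maximum with a local
  quadratic; flat windows resolve to the earliest time with a warning.
* **Thresholds.** `find_threshold()` is plain bisection with recorded
  evaluations; tolerances are 2 days for cessation-day searches and
  ~1% relative for parameter boundaries.
* **Sensitivity.** Latin hypercube sampling (via the `lhs` package) with
  one draw per equal-probability stratum over 10%–200% of baseline for
  every non-structural parameter (the Hill coefficient and variant
  switches are excluded; so would be any zero-baseline parameter, with a
  warning). PRCC follows the standard construction: average-rank
  transform, partialling by linear regression on all other parameters'
  ranks, t-test p-values with $n - 2 - q$ degrees of freedom. Some draws
  (self-renewal above decay) grow without bound; the solver returns a
  partial trajectory and the last attained TD — by then saturated near
  its asymptote — enters the outcome vector flagged as not converged.
  The headline analysis uses n = 2000 samples; package tests use reduced
  designs (n of a few tens over restricted parameter subsets) chosen to
  exercise the pipeline rather than to estimate all 91 coefficients.

## Design decisions

* `TD` is stored as a fraction in $[0,1]$ — the $(1-T_D)$ factors force
  the dimensionless reading — and converted to percent only for
  reporting; the COPD call is strictly `TD > 0.30`.
* The four half-saturation constants of the cytokine damage term carry
  explicit names (`K_TD_Ig`, `K_TD_I17`, `K_TD_I10`, `K_TD_Ib`), one per
  regulator, rather than ambiguous positional indices.
* The constant Treg source `kgp` enters as a constant influx (an
  IL-10-inhibited influx with no Treg factor); the Treg-proportional
  variant is available behind the structural switch `tg_prolif_mode = 1`.
* T-cell differentiation has no explicit DC factor (the constant
  DC/naive-T drive is folded into `k7`–`k10`), so a DC knockout acts only
  through the DC production terms; it is retained in the knockout
  manifest for completeness.
* Knockout scope is an explicit manifest (`knockout_manifest()`): zeroing
  an element's production/self-renewal rates forces its trajectory
  identically to zero, plus its element-specific action rates (`k13` for
  M1, `k14` for CD8+). Which rates constitute "all parameters of an
  element" is otherwise ambiguous for shared edges.
* IL-12 is secreted by M1 only; a dendritic-cell IL-12 channel would be a
  one-line addition to the cytokine source table but is not wired by
  default, keeping Loop 3 breakable on the single `kI12_M1` edge.
* Slow T-cell kinetics (decay 0.03/day with IL-10-gated self-renewal just
  below it) give the adaptive arm a months-scale memory; this produces
  the late CD8-dominated phase and the persistence of inflammation after
  late cessation.
* Smoker classification: resistant if chronic smoking never drives TD
  above 30%; otherwise severe if TD is still above 30% after cessation
  (default day 2500, read at day 6000), else reversible. "Returned to
  baseline" is operationalised as post-cessation TD below twice the
  never-smoked baseline; a reversible call that fails this stricter check
  is flagged provisional.
* The virtual-cohort generator draws log-uniform multiplicative
  perturbations (parameters span orders of magnitude; additive jitter
  would be scale-inconsistent), defaulting to the sensitivity range
  0.1–2.0×. No published inter-individual distribution exists; cohort
  outputs are labelled synthetic.

## Limitations

Neutrophils, proteases, reactive oxygen species and elastin fragments are
coarse-grained into the M1→TD and TD→M1 edges; there is no spatial
structure, no exacerbation/infection dynamics, and no aging. The
synthetic reference table reproduces the mechanism's regime structure but
not published numerical values (see above); analyses that need the latter
must substitute a transcribed experimental table via `load_params()`.
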