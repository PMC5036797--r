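#' State-vector layout of the network model
#'
#' The model tracks 18 dynamical variables in a fixed order: eight
#' immune-cell densities (cells/ml), nine cytokine concentrations (pmol/L)
#' and the tissue-damage fraction `TD` (dimensionless, in \eqn{[0, 1]};
#' reported externally as a percentage).
#'
#' Order: `M1`, `M2`, `DC`, `T1`, `T2`, `T8`, `T17`, `Tg`, `I4`, `I6`,
#' `I10`, `I12`, `I17`, `I21`, `Ia`, `Ig`, `Ib`, `TD`, where `M1`/`M2` are
#' classically/alternatively activated macrophages, `DC` mature dendritic
#' cells, `T1`/`T2`/`T8`/`T17`/`Tg` the Th1, Th2, CD8+, Th17 and regulatory
#' T-cell populations, and `I4` ... `Ib` the cytokines IL-4, IL-6, IL-10,
#' IL-12, IL-17, IL-21, TNF-alpha, IFN-gamma and TGF-beta.
#'
#' @return `state_names()` returns the 18 variable names in state order.
#' @export
state_names <- function() {
  c("M1", "M2", "DC", "T1", "T2", "T8", "T17", "Tg",
    "I4", "I6", "I10", "I12", "I17", "I21", "Ia", "Ig", "Ib",
    "TD")
}

#' Construct a model state vector
#'
#' The default is the resting lung used throughout: all activated cells,
#' secreted cytokines and tissue damage start at zero.
#'
#' @param ... Named variable values overriding the zero default; names must
#'   be a subset of [state_names()].
#' @return Named numeric vector of length 18 in canonical state order.
#' @examples
#' initial_state()               # resting lung
#' initial_state(TD = 0.1, M1 = 1e3)
#' @export
initial_state <- function(...) {
  y <- stats::setNames(numeric(18L), state_names())
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(y))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown state variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    y[names(over)] <- over
  }
  validate_state(y)
  y
}

validate_state <- function(y) {
  if (length(y) != 18L || !identical(names(y), state_names())) {
    stop("state must be a named numeric vector with the 18 canonical variables in order",
         call. = FALSE)
  }
  if (any(!is.finite(y))) stop("state contains non-finite values", call. = FALSE)
  if (any(y < 0)) stop("cell densities and cytokine concentrations must be >= 0", call. = FALSE)
  if (y[["TD"]] > 1) stop("tissue-damage fraction TD must lie in [0, 1]", call. = FALSE)
  invisible(y)
}

#' Classify a state as normal or COPD
#'
#' A tissue-damage fraction strictly larger than 30% is read as COPD;
#' anything up to and including 30% is normal.
#'
#' @param state A model state vector (see [initial_state()]) or a bare
#'   `TD` fraction in \eqn{[0, 1]}.
#' @return `"copd"` or `"normal"`.
#' @examples
#' classify_copd(initial_state())      # "normal"
#' classify_copd(0.32)                 # "copd"
#' @export
classify_copd <- function(state) {
  td <- if (length(state) == 1L && is.null(names(state))) state else state[["TD"]]
  if (!is.finite(td) || td < 0 || td > 1) {
    stop("TD must be a fraction in [0, 1]", call. = FALSE)
  }
  if (td > 0.30) "copd" else "normal"
}

#' Convert a tissue-damage fraction to the reported percentage scale
#' @param td TD fraction(s) in \eqn{[0, 1]}.
#' @return TD in percent.
#' @export
td_percent <- function(td) 100 * td
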