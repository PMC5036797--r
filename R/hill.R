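#' Hill regulation functions
#'
#' Saturating sigmoidal regulation terms used throughout the network model.
#' `hill_up()` is the increasing form \eqn{(x/K)^n / (1 + (x/K)^n)} used for
#' activating inputs; `hill_down()` is the decreasing form
#' \eqn{1 / (1 + (x/K)^n)} used for inhibitory inputs (mostly IL-10
#' suppression). Both map nonnegative inputs into \eqn{[0, 1]} and satisfy
#' `hill_up(x, K, n) + hill_down(x, K, n) == 1`.
#'
#' @param x Nonnegative input level (concentration or density). Vectorised.
#' @param K Positive half-saturation constant, in the units of `x`; at
#'   `x == K` either function returns 0.5.
#' @param n Positive Hill coefficient; the model default is 2, which gives
#'   enough nonlinearity for switch-like regulation.
#'
#' @return Numeric vector of regulation factors in \eqn{[0, 1]}.
#' @examples
#' hill_up(c(0, 1, 3), K = 1)   # 0, 0.5, 0.9
#' hill_down(c(0, 1, 3), K = 1) # 1, 0.5, 0.1
#' @export
hill_up <- function(x, K, n = 2) {
  check_hill_args(x, K, n)
  r <- (x / K)^n
  r / (1 + r)
}

#' @rdname hill_up
#' @export
hill_down <- function(x, K, n = 2) {
  check_hill_args(x, K, n)
  1 / (1 + (x / K)^n)
}

check_hill_args <- function(x, K, n) {
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("Hill half-saturation constant 'K' must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("Hill input 'x' must be nonnegative and finite", call. = FALSE)
  }
  if (any(n <= 0)) stop("Hill coefficient 'n' must be positive", call. = FALSE)
  invisible(TRUE)
}
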