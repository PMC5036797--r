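#' Piecewise-constant smoking protocols
#'
#' A smoking protocol is an ordered list of contiguous, non-overlapping
#' segments `(start_day, end_day, S)` covering the simulated span, with `S`
#' the dimensionless smoking intensity (the ratio of the cigarette-smoke
#' dose to the minimal dose required to cause COPD under the reference
#' parameters). The simulation engine restarts the integrator at every
#' segment boundary so discontinuities in S are never smoothed across.
#'
#' @param start_day,end_day Numeric vectors of segment bounds (days);
#'   segments must be contiguous (`end_day[i] == start_day[i + 1]`).
#' @param S Nonnegative intensity per segment.
#' @return A `smoking_protocol` object.
#' @examples
#' constant_smoking(1.67, t_end = 4000)
#' cessation_protocol(1.67, cessation_day = 400, t_end = 6000)
#' @export
smoking_protocol <- function(start_day, end_day, S) {
  stopifnot(length(start_day) == length(end_day), length(S) == length(start_day))
  if (any(!is.finite(c(start_day, end_day, S)))) {
    stop("protocol entries must be finite", call. = FALSE)
  }
  if (any(S < 0)) stop("smoking intensity S must be >= 0", call. = FALSE)
  if (any(end_day <= start_day)) stop("each segment needs end_day > start_day", call. = FALSE)
  o <- order(start_day)
  start_day <- start_day[o]; end_day <- end_day[o]; S <- S[o]
  if (length(start_day) > 1L &&
      any(abs(start_day[-1L] - end_day[-length(end_day)]) > 1e-9)) {
    stop("protocol segments must be contiguous and non-overlapping", call. = FALSE)
  }
  structure(list(start_day = start_day, end_day = end_day, S = S),
            class = "smoking_protocol")
}

#' @rdname smoking_protocol
#' @param t_end Protocol span end (days).
#' @export
constant_smoking <- function(S, t_end = 4000) {
  smoking_protocol(0, t_end, S)
}

#' @rdname smoking_protocol
#' @param cessation_day Day at which smoking stops (intensity drops to 0).
#' @export
cessation_protocol <- function(S, cessation_day, t_end = 6000) {
  if (cessation_day < 0 || cessation_day > t_end) {
    stop("cessation_day must lie in [0, t_end]", call. = FALSE)
  }
  if (cessation_day == 0) return(constant_smoking(0, t_end))
  if (cessation_day == t_end) return(constant_smoking(S, t_end))
  smoking_protocol(c(0, cessation_day), c(cessation_day, t_end), c(S, 0))
}

#' Evaluate a protocol's smoking intensity at time t
#'
#' Segment boundaries belong to the later segment (the protocol is
#' right-continuous), matching the integrator's restart-at-breakpoint
#' convention.
#'
#' @param protocol A [smoking_protocol()].
#' @param t Time(s) in days, within the protocol span.
#' @return Numeric vector of intensities.
#' @export
protocol_intensity <- function(protocol, t) {
  stopifnot(inherits(protocol, "smoking_protocol"))
  lo <- protocol$start_day[1L]; hi <- protocol$end_day[length(protocol$end_day)]
  if (any(t < lo | t > hi)) stop("time outside protocol span", call. = FALSE)
  idx <- findInterval(t, protocol$start_day)
  protocol$S[pmin(idx, length(protocol$S))]
}

#' @export
print.smoking_protocol <- function(x, ...) {
  cat("<smoking_protocol> ", length(x$S), " segment(s) over [",
      x$start_day[1L], ", ", x$end_day[length(x$end_day)], "] days\n", sep = "")
  for (i in seq_along(x$S)) {
    cat(sprintf("  [%8.1f, %8.1f) S = %g\n", x$start_day[i], x$end_day[i], x$S[i]))
  }
  invisible(x)
}

#' @export
format.smoking_protocol <- function(x, ...) {
  paste(sprintf("[%g,%g):S=%g", x$start_day, x$end_day, x$S), collapse = " ")
}
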