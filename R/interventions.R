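# In-silico interventions: element knockouts, positive-feedback-loop
# breaking and single-loop activation, expressed as declarative edits of a
# parameter table.

# Which parameter keys constitute "all parameters of the element" is an
# explicit manifest (shared edges make any implicit rule ambiguous).
# Zeroing an element's production/proliferation rates forces its trajectory
# identically to zero from the resting initial state; element-specific
# action rates (k13 for M1, k14 for CD8+ T) are zeroed as well.
KNOCKOUT_MANIFEST <- list(
  M1   = c("k1", "k2", "k3", "kI6_M1", "kI12_M1", "kIa_M1", "k13"),
  DC   = c("k5", "k6"),
  Th1  = c("k7", "kp1", "kIg_T1"),
  Th17 = c("k10", "kp17", "kI17_T17", "kI21_T17"),
  CD8T = c("k9", "kp8", "kIg_T8", "k14"),
  TNFa = c("kIa_M1"),
  IFNg = c("kIg_T1", "kIg_T8"),
  IL6  = c("kI6_M1", "kI6_TD"),
  IL17 = c("kI17_T17")
)

# Loop edges: the four positive feedback loops are broken on a single edge
# each; activation sets the loop's sufficiency value while breaking the
# other loops (Loop 3 has no sufficiency value: it cannot drive COPD alone).
LOOP_BREAK <- list(
  Loop1 = c(k3 = 0),          # break TD -> M1
  Loop2 = c(kI6_TD = 0),      # break TD -> IL-6
  Loop3 = c(kI12_M1 = 0),     # break M1 -> IL-12
  Loop4 = c(K_Tg_I6 = 1e4)    # break IL-6 -| Treg (inhibition made inert)
)
LOOP_ACTIVATE <- list(
  Loop1 = c(k3 = 1.9e6),      # cell/(ml day)
  Loop2 = c(kI6_TD = 22.0),   # pmol/(L day)
  Loop4 = c(K_Tg_I6 = 2.3)    # pmol/L
)

#' Knockout manifest and loop identifiers
#'
#' `knockout_manifest()` lists, per network element, the parameter keys that
#' are zeroed by its in-silico knockout. `loop_edges()` lists the edits that
#' break (and, for Loops 1/2/4, activate) each positive feedback loop:
#' Loop 1 is M1 -> TD -> M1; Loop 2 is IL-6 -> Th17 -> IL-17 -> TD -> IL-6;
#' Loop 3 is M1 -> IL-12 -> Th1 -> IFN-g -> M1; Loop 4 is
#' IL-6 -| Treg -> IL-10 -| Th17 -> IL-17 -> TD -> IL-6.
#'
#' @return Named lists of parameter edits.
#' @export
knockout_manifest <- function() KNOCKOUT_MANIFEST

#' @rdname knockout_manifest
#' @export
loop_edges <- function() list(break_ = LOOP_BREAK, activate = LOOP_ACTIVATE)

#' Declare an intervention
#'
#' @param kind One of `"knockout"`, `"loop_break"`, `"loop_activate"`,
#'   `"cessation"`.
#' @param target Element name (see [knockout_manifest()]) for knockouts;
#'   `"Loop1"`..`"Loop4"` for loop interventions (`"Loop3"` has no
#'   activation); ignored for cessation.
#' @param cessation_day Day smoking stops (cessation kind only).
#' @return An `intervention` object with the parameter modifications it
#'   implies.
#' @examples
#' intervention("knockout", "IL6")
#' intervention("loop_activate", "Loop1")
#' @export
intervention <- function(kind = c("knockout", "loop_break", "loop_activate",
                                  "cessation"),
                         target = NULL, cessation_day = NULL) {
  kind <- match.arg(kind)
  mods <- switch(kind,
    knockout = {
      if (is.null(target) || !target %in% names(KNOCKOUT_MANIFEST)) {
        stop("unknown element '", target, "'; valid: ",
             paste(names(KNOCKOUT_MANIFEST), collapse = ", "), call. = FALSE)
      }
      stats::setNames(numeric(length(KNOCKOUT_MANIFEST[[target]])),
                      KNOCKOUT_MANIFEST[[target]])
    },
    loop_break = {
      if (is.null(target) || !target %in% names(LOOP_BREAK)) {
        stop("unknown loop '", target, "'; valid: ",
             paste(names(LOOP_BREAK), collapse = ", "), call. = FALSE)
      }
      LOOP_BREAK[[target]]
    },
    loop_activate = {
      if (is.null(target) || !target %in% names(LOOP_ACTIVATE)) {
        stop("unknown loop '", target, "'; activatable: ",
             paste(names(LOOP_ACTIVATE), collapse = ", "), call. = FALSE)
      }
      other <- setdiff(names(LOOP_BREAK), target)
      c(LOOP_ACTIVATE[[target]], do.call(c, unname(LOOP_BREAK[other])))
    },
    cessation = {
      if (is.null(cessation_day) || cessation_day < 0) {
        stop("cessation requires cessation_day >= 0", call. = FALSE)
      }
      stats::setNames(numeric(0), character(0))
    }
  )
  structure(list(kind = kind, target = target, modifications = mods,
                 cessation_day = cessation_day),
            class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat("<intervention> ", x$kind,
      if (!is.null(x$target)) paste0(" [", x$target, "]"), "\n", sep = "")
  if (length(x$modifications)) {
    cat("  ", paste0(names(x$modifications), " -> ", x$modifications,
                     collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$cessation_day)) cat("  cessation at day", x$cessation_day, "\n")
  invisible(x)
}

#' Apply or revert an intervention on a parameter table
#'
#' `apply_intervention()` returns a new validated table with the
#' intervention's modifications applied; the previous values of the touched
#' keys are stored so that `revert_intervention()` restores a table equal to
#' the original. A cessation intervention does not modify the table (it acts
#' through the smoking protocol; see [run_cessation()]).
#'
#' @param params A `copd_params` table.
#' @param intv An [intervention()].
#' @return A modified (resp. restored) `copd_params` table.
#' @export
apply_intervention <- function(params, intv) {
  stopifnot(inherits(intv, "intervention"))
  p <- unclass(as_copd_params(params))
  mods <- intv$modifications
  bad <- setdiff(names(mods), names(p))
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  prev <- p[names(mods)]
  p[names(mods)] <- mods
  out <- as_copd_params(p)
  attr(out, "previous") <- prev
  attr(out, "intervention") <- intv
  out
}

#' @rdname apply_intervention
#' @export
revert_intervention <- function(params) {
  prev <- attr(params, "previous")
  if (is.null(prev)) stop("no intervention recorded on this table", call. = FALSE)
  p <- unclass(params)
  p[names(prev)] <- prev
  as_copd_params(p)
}
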