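#' Bundle the four RUSH conditions on one time grid
#'
#' Container for a retention-using-selective-hooks experiment: the biotin
#' control (reporter released before imaging; flat), the avidin control
#' (full re-accumulation; the 0%-inhibition reference), the continuous drug
#' treatment, and the discontinuous treatment (drug washed out, avidin
#' added) that probes reversibility.
#'
#' @param timepoints Strictly increasing time grid in hours (>= 3 points).
#' @param biotin,avidin,continuous,discontinuous Intensity series on that
#'   grid, a.u.
#' @param normalized Whether the series have been normalized to a control
#'   via [normalize_rush()].
#' @return An object of class `rush_set`.
#' @export
rush_set <- function(timepoints, biotin, avidin, continuous, discontinuous,
                     normalized = FALSE) {
  n <- length(timepoints)
  stopifnot(n >= 3L, all(diff(timepoints) > 0),
            length(biotin) == n, length(avidin) == n,
            length(continuous) == n, length(discontinuous) == n)
  vals <- c(biotin, avidin, continuous, discontinuous)
  if (any(!is.finite(vals))) stop("series values must be finite")
  structure(list(timepoints = timepoints, biotin = biotin, avidin = avidin,
                 continuous = continuous, discontinuous = discontinuous,
                 normalized = isTRUE(normalized)),
            class = "rush_set")
}

#' @export
print.rush_set <- function(x, ...) {
  cat(sprintf("<rush_set> %d timepoints over %.3g h (%s)\n",
              length(x$timepoints), diff(range(x$timepoints)),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Normalize a RUSH set to an untreated control series
#'
#' Divides every condition pointwise by the control value at the same
#' timepoint, removing shared acquisition drift.
#'
#' @param set A [rush_set()].
#' @param ctr Control series on the same grid; all values must be positive.
#' @return The normalized `rush_set`.
#' @export
normalize_rush <- function(set, ctr) {
  stopifnot(inherits(set, "rush_set"), length(ctr) == length(set$timepoints))
  if (any(ctr <= 0)) stop("control series must be positive at every timepoint")
  rush_set(set$timepoints,
           biotin = set$biotin / ctr,
           avidin = set$avidin / ctr,
           continuous = set$continuous / ctr,
           discontinuous = set$discontinuous / ctr,
           normalized = TRUE)
}

ols_slope <- function(t, v) {
  tc <- t - mean(t)
  sum(tc * v) / sum(tc^2)
}

#' Protein-synthesis inhibition percentage from RUSH slopes
#'
#' Ordinary-least-squares slopes over the full acquisition window; the
#' avidin control slope defines 0% inhibition and the statistic is the
#' complementary slope ratio
#' `100 * (1 - slope(continuous) / slope(avidin))`. Negative values (faster
#' accumulation than the control) are reported as-is.
#'
#' @param set A [rush_set()] (normalized; a warning is raised otherwise).
#' @param tol Absolute tolerance below which the avidin slope counts as
#'   zero (failed assay).
#' @return Inhibition percentage.
#' @export
inhibition_percent <- function(set, tol = sqrt(.Machine$double.eps)) {
  stopifnot(inherits(set, "rush_set"))
  if (!set$normalized) {
    warning("rush_set is not normalized to a control; interpreting raw series")
  }
  s_av <- ols_slope(set$timepoints, set$avidin)
  if (s_av <= tol) stop("avidin control slope is not positive: assay failed")
  100 * (1 - ols_slope(set$timepoints, set$continuous) / s_av)
}

#' Reversibility percentage from RUSH curve areas
#'
#' Trapezoid areas on the shared grid: the maximum achievable effect is the
#' area between the avidin and biotin control curves, and reversibility is
#' the area recovered between the continuous and discontinuous treatments,
#' `100 * area(discontinuous - continuous) / area(avidin - biotin)`.
#'
#' @param set A [rush_set()] (normalized; a warning is raised otherwise).
#' @param tol Absolute tolerance below which the maximum-effect area counts
#'   as zero.
#' @return Reversibility percentage.
#' @export
reversibility_percent <- function(set, tol = sqrt(.Machine$double.eps)) {
  stopifnot(inherits(set, "rush_set"))
  if (!set$normalized) {
    warning("rush_set is not normalized to a control; interpreting raw series")
  }
  max_effect <- trapz(set$timepoints, set$avidin - set$biotin)
  if (max_effect <= tol) stop("maximum-effect area is not positive: assay failed")
  100 * trapz(set$timepoints, set$discontinuous - set$continuous) / max_effect
}
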