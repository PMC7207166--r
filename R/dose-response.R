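#' Classification thresholds for healthy / pyknotic / dead calling
#'
#' @param pi_threshold PI intensity at or above which a cell is dead (a.u.).
#' @param hoechst_high_threshold Hoechst intensity at or above which a
#'   PI-negative cell counts as Hoechst-high (a.u.).
#' @param condensed_area_threshold Nuclear area at or below which a nucleus
#'   counts as condensed (px^2).
#' @return An object of class `class_rule`.
#' @seealso [classify_cells()], [derive_class_rule()]
#' @export
class_rule <- function(pi_threshold, hoechst_high_threshold,
                       condensed_area_threshold) {
  stopifnot(pi_threshold > 0, hoechst_high_threshold > 0,
            condensed_area_threshold > 0)
  structure(list(pi_threshold = pi_threshold,
                 hoechst_high_threshold = hoechst_high_threshold,
                 condensed_area_threshold = condensed_area_threshold),
            class = "class_rule")
}

#' Derive a classification rule from control-well cells
#'
#' Default cut-offs taken from the plate's untreated controls:
#' Hoechst-high above control median + 2 MAD, condensed below 0.6 x the
#' control median area, and PI-positive above control median + 6 MAD of the
#' PI channel (controls are PI-negative, so this flags clear outliers).
#'
#' @param control_cells Data frame from [measure_cells()] for control wells.
#' @param hoechst_col,pi_col,area_col Column names.
#' @return A [class_rule()].
#' @export
derive_class_rule <- function(control_cells,
                              hoechst_col = "nuc_mean_dna",
                              pi_col = "nuc_mean_pi",
                              area_col = "nuclear_area") {
  stopifnot(nrow(control_cells) >= 3L)
  h <- control_cells[[hoechst_col]]
  p <- control_cells[[pi_col]]
  a <- control_cells[[area_col]]
  class_rule(pi_threshold = median(p) + 6 * mad(p) + 1,
             hoechst_high_threshold = median(h) + 2 * mad(h),
             condensed_area_threshold = 0.6 * median(a))
}

#' Classify cells as healthy, pyknotic or dead
#'
#' Applies the viability partition used before dose-response fitting:
#' dead if PI at/above threshold (takes precedence); else pyknotic if the
#' nucleus is condensed (small area) AND Hoechst-high; else healthy. Every
#' cell receives exactly one label.
#'
#' @param cells Data frame from [measure_cells()].
#' @param rule A [class_rule()].
#' @param hoechst_col,pi_col,area_col Column names of the Hoechst and PI
#'   intensities and the nuclear area.
#' @return `cells` with an added factor column `class` with levels
#'   `healthy`, `pyknotic`, `dead`.
#' @export
classify_cells <- function(cells, rule,
                           hoechst_col = "nuc_mean_dna",
                           pi_col = "nuc_mean_pi",
                           area_col = "nuclear_area") {
  stopifnot(inherits(rule, "class_rule"))
  for (col in c(hoechst_col, pi_col, area_col)) {
    if (!col %in% names(cells)) stop("missing required column: ", col)
  }
  dead <- cells[[pi_col]] >= rule$pi_threshold
  pyk <- !dead &
    cells[[area_col]] <= rule$condensed_area_threshold &
    cells[[hoechst_col]] >= rule$hoechst_high_threshold
  cls <- rep("healthy", nrow(cells))
  cls[pyk] <- "pyknotic"
  cls[dead] <- "dead"
  cells$class <- factor(cls, levels = c("healthy", "pyknotic", "dead"))
  cells
}

#' Fit a four-parameter log-logistic dose-response model
#'
#' Least-squares fit of the healthy fraction against dose under
#' `y(x) = c + (d - c) / (1 + (x/e)^b)`, with multi-start over the slope
#' `b` in `{0.5, 1, 2, 4}` and box constraints `c >= 0`,
#' `d <= 1.05 * max(fraction)`. The model is fitted on the dose scale, where
#' `y(0) = d` is well defined for `b > 0`; users with a strict log-dose grid
#' can pre-offset zero doses via `zero_dose_offset`.
#'
#' @param dose Doses in micromolar (>= 0).
#' @param healthy Healthy-cell counts per well (or healthy fractions when
#'   `total` is `NULL` and all values lie in `[0, 1]`).
#' @param total Total cells per well; when given, fractions are
#'   `healthy / total`.
#' @param starts_b Slope values used as starting points.
#' @param zero_dose_offset Optional replacement dose for `dose == 0` wells
#'   (e.g. smallest positive dose / 10); `NULL` keeps zero doses as-is.
#' @return An object of class `fourpl`: coefficients `b`, `c`, `d`, `e`,
#'   residual sum of squares `rss`, logical `converged`, and the fitted
#'   data. Supports `print()`, `coef()`, `predict()`, `residuals()`,
#'   `summary()` and `plot()`; pass to [ic60()] for the IC60.
#' @examples
#' plate <- make_dose_response(b = 1.2, c = 0.05, d = 0.95, e = 2,
#'                             doses = 2^(-3:4), n_cells_per_well = 1000)
#' fit <- fit_4pl(plate$dose_uM, plate$healthy,
#'                total = plate$healthy + plate$pyknotic + plate$dead)
#' coef(fit)
#' @export
fit_4pl <- function(dose, healthy, total = NULL,
                    starts_b = c(0.5, 1, 2, 4), zero_dose_offset = NULL) {
  stopifnot(length(dose) == length(healthy), all(dose >= 0), all(healthy >= 0))
  if (length(unique(dose)) < 4L) stop("need >= 4 distinct doses")
  if (!any(dose > 0)) stop("need at least one positive dose")
  frac <- if (is.null(total)) {
    if (any(healthy > 1)) stop("`healthy` looks like counts: supply `total`")
    healthy
  } else {
    total <- rep_len(total, length(healthy))
    stopifnot(all(total > 0))
    healthy / total
  }
  if (!is.null(zero_dose_offset)) dose[dose == 0] <- zero_dose_offset
  dat <- data.frame(dose = dose, frac = frac)
  cl <- match.call()
  if (sd(frac) < 1e-9) {
    return(new_fourpl(c(b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_),
                      rss = NA_real_, converged = FALSE, data = dat, call = cl))
  }
  max_frac <- max(frac)
  pos <- dose > 0
  e0_default <- exp(mean(log(dose[pos])))
  # dose nearest the half response as an inflection guess
  mid <- (min(frac) + max(frac)) / 2
  e0 <- dose[pos][which.min(abs(frac[pos] - mid))]
  if (!is.finite(e0) || e0 <= 0) e0 <- e0_default
  lower <- c(b = 0.05, c = 0, d = 0, e = min(dose[pos]) / 1000)
  upper <- c(b = 50, c = 1.05 * max_frac, d = 1.05 * max_frac,
             e = max(dose) * 1000)
  best <- NULL
  for (b0 in starts_b) {
    fit <- tryCatch(
      minpack.lm::nlsLM(frac ~ c + (d - c) / (1 + (dose / e)^b),
                        data = dat,
                        start = list(b = b0, c = max(min(frac), 0),
                                     d = min(max(frac), upper[["d"]]), e = e0),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(new_fourpl(c(b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_),
                      rss = NA_real_, converged = FALSE, data = dat, call = cl))
  }
  cf <- coef(best$fit)[c("b", "c", "d", "e")]
  converged <- is.finite(best$rss) && (cf[["d"]] - cf[["c"]]) > 1e-6
  new_fourpl(cf, rss = best$rss, converged = converged, data = dat, call = cl)
}

new_fourpl <- function(coefficients, rss, converged, data, call) {
  structure(list(coefficients = coefficients, rss = rss,
                 converged = converged, data = data, call = call),
            class = "fourpl")
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' @export
print.fourpl <- function(x, ...) {
  cat("Four-parameter log-logistic dose-response fit\n")
  if (!x$converged) {
    cat("  NOT converged (no usable dose effect)\n")
  } else {
    cf <- x$coefficients
    cat(sprintf("  b = %.4g, c = %.4g, d = %.4g, e = %.4g uM\n",
                cf[["b"]], cf[["c"]], cf[["d"]], cf[["e"]]))
    cat(sprintf("  RSS = %.4g over %d wells\n", x$rss, nrow(x$data)))
  }
  invisible(x)
}

#' @export
predict.fourpl <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  x <- if (is.null(newdata)) object$data$dose else {
    if (is.data.frame(newdata)) newdata$dose else newdata
  }
  cf <- object$coefficients
  cf[["c"]] + (cf[["d"]] - cf[["c"]]) / (1 + (x / cf[["e"]])^cf[["b"]])
}

#' @export
residuals.fourpl <- function(object, ...) {
  object$data$frac - predict(object)
}

#' @export
summary.fourpl <- function(object, ...) {
  out <- list(coefficients = object$coefficients, rss = object$rss,
              converged = object$converged, n = nrow(object$data),
              ic60 = tryCatch(ic60(object), error = function(e) NA_real_))
  class(out) <- "summary.fourpl"
  out
}

#' @export
print.summary.fourpl <- function(x, ...) {
  cat("4PL fit:", if (x$converged) "converged" else "NOT converged",
      sprintf("(n = %d wells)\n", x$n))
  if (x$converged) {
    print(round(x$coefficients, 5))
    cat(sprintf("RSS = %.4g, IC60 = %.4g uM\n", x$rss, x$ic60))
  }
  invisible(x)
}

#' @export
plot.fourpl <- function(x, ...) {
  if (!x$converged) stop("nothing to plot: fit not converged")
  d <- x$data
  pos <- d$dose > 0
  graphics::plot(d$dose[pos], d$frac[pos], log = "x",
                 xlab = "dose (uM)", ylab = "healthy fraction", ...)
  xs <- exp(seq(log(min(d$dose[pos])), log(max(d$dose[pos])), length.out = 200))
  graphics::lines(xs, predict(x, xs))
  ic <- tryCatch(ic60(x), error = function(e) NA_real_)
  if (is.finite(ic)) graphics::abline(v = ic, lty = 2)
  invisible(x)
}

#' IC60 from a fitted 4PL model
#'
#' The IC60 is the dose at which 40% of the cell population remains healthy,
#' obtained in closed form by inverting the log-logistic curve:
#' `x = e * ((d - c) / (0.4 - c) - 1)^(1/b)`. Defined only when the target
#' fraction lies strictly between the asymptotes.
#'
#' @param fit A converged [fit_4pl()] object.
#' @param target_fraction Healthy fraction defining the endpoint (0.4 for
#'   the IC60).
#' @return Dose in micromolar.
#' @examples
#' # 1 / (1 + x) = 0.4  =>  x = 1.5
#' f <- structure(list(coefficients = c(b = 1, c = 0, d = 1, e = 1),
#'                     converged = TRUE), class = "fourpl")
#' ic60(f)
#' @export
ic60 <- function(fit, target_fraction = 0.4) {
  stopifnot(inherits(fit, "fourpl"))
  if (!fit$converged) stop("fit did not converge: IC60 undefined")
  cf <- fit$coefficients
  if (!(target_fraction > cf[["c"]] && target_fraction < cf[["d"]])) {
    stop(sprintf("target fraction %.2f outside the fitted asymptotes (%.3f, %.3f): IC60 undefined",
                 target_fraction, cf[["c"]], cf[["d"]]))
  }
  cf[["e"]] * ((cf[["d"]] - cf[["c"]]) / (target_fraction - cf[["c"]]) - 1)^(1 / cf[["b"]])
}
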