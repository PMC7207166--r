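#' Simulate single-cell HMGB1 nuclear-intensity tracks
#'
#' Emulates time-lapse imaging of nuclear HMGB1-GFP during immunogenic cell
#' death: each cell starts at its own baseline intensity and loses a fixed
#' fraction of nuclear signal per imaging interval (multiplicative decay),
#' with optional Gaussian measurement noise.
#'
#' @param n_cells Number of tracked cells.
#' @param n_timepoints Number of frames (>= 2), one per hour.
#' @param decay_per_interval Fraction of nuclear intensity lost per interval,
#'   in `[0, 1]`.
#' @param noise_sd Gaussian noise sd in intensity units.
#' @param seed Integer seed.
#' @param i0_mean,i0_sd Distribution of per-cell starting intensity (a.u.).
#' @param dt_hours Imaging interval in hours.
#' @return A long data frame (`subject_id`, `t_hours`, `value`) with the
#'   generating parameters attached as attributes `decay_per_interval` and
#'   `i0` (per-cell baselines).
#' @seealso [hmgb1_release()]
#' @export
make_hmgb1_tracks <- function(n_cells, n_timepoints, decay_per_interval,
                              noise_sd = 0, seed = 1L,
                              i0_mean = 1000, i0_sd = 100, dt_hours = 1) {
  stopifnot(n_cells >= 1L, n_timepoints >= 2L, noise_sd >= 0)
  stop_if_not_scalar_prob(decay_per_interval, "decay_per_interval")
  with_seed(seed, {
    i0 <- pmax(1, rnorm(n_cells, i0_mean, i0_sd))
    t_hours <- (seq_len(n_timepoints) - 1L) * dt_hours
    out <- do.call(rbind, lapply(seq_len(n_cells), function(k) {
      v <- i0[k] * (1 - decay_per_interval)^(seq_len(n_timepoints) - 1L)
      if (noise_sd > 0) v <- v + rnorm(n_timepoints, 0, noise_sd)
      data.frame(subject_id = sprintf("cell_%03d", k),
                 t_hours = t_hours, value = v)
    }))
    attr(out, "decay_per_interval") <- decay_per_interval
    attr(out, "i0") <- i0
    out
  })
}

#' Simulate a four-condition RUSH retention experiment
#'
#' Emulates GFP-reporter accumulation in the retention-using-selective-hooks
#' secretion assay under the four canonical conditions: biotin control (hook
#' released before imaging, flat baseline), avidin control (biotin scavenged,
#' reporter re-accumulates linearly at rate `rate`), continuous drug
#' treatment (accumulation slowed to `rate * (1 - planted_inhibition)`), and
#' discontinuous treatment where the drug is washed out (accumulation at
#' `rate * (1 - planted_inhibition * (1 - planted_reversibility))`).
#'
#' @param timepoints Uniform time grid in hours (>= 3 points); non-uniform
#'   grids are refused.
#' @param rate Accumulation rate of the avidin control, a.u. per hour.
#' @param baseline Common starting intensity, a.u.
#' @param planted_inhibition,planted_reversibility Fractions in `[0, 1]`.
#' @param noise_sd Gaussian noise sd, a.u.
#' @param seed Integer seed.
#' @return A [rush_set()] with attribute `truth` holding the planted values.
#' @export
make_rush_curves <- function(timepoints = 0:24, rate = 50, baseline = 100,
                             planted_inhibition = 0, planted_reversibility = 0,
                             noise_sd = 0, seed = 1L) {
  stopifnot(length(timepoints) >= 3L, noise_sd >= 0, rate > 0)
  dt <- diff(timepoints)
  if (any(dt <= 0) || max(abs(dt - dt[1L])) > 1e-9 * max(abs(dt))) {
    stop("timepoints must form a strictly increasing uniform grid")
  }
  stop_if_not_scalar_prob(planted_inhibition, "planted_inhibition")
  stop_if_not_scalar_prob(planted_reversibility, "planted_reversibility")
  f <- planted_inhibition
  r <- planted_reversibility
  with_seed(seed, {
    t <- timepoints - timepoints[1L]
    mk <- function(slope) {
      v <- baseline + slope * t
      if (noise_sd > 0) v <- v + rnorm(length(t), 0, noise_sd)
      v
    }
    out <- rush_set(timepoints,
                    biotin = mk(0),
                    avidin = mk(rate),
                    continuous = mk(rate * (1 - f)),
                    discontinuous = mk(rate * (1 - f * (1 - r))))
    attr(out, "truth") <- list(rate = rate, baseline = baseline,
                               planted_inhibition = f,
                               planted_reversibility = r)
    out
  })
}

#' Simulate a dose-response plate of healthy-cell counts
#'
#' Draws per-well healthy-cell counts around a four-parameter log-logistic
#' viability curve `y(x) = c + (d - c) / (1 + (x/e)^b)` (healthy fraction vs
#' dose), with Gaussian noise on the fraction scale. The generating
#' parameters and the closed-form true IC60 (dose at healthy fraction 0.4)
#' are attached as attributes.
#'
#' @param b,c,d,e 4PL parameters: slope, lower asymptote, upper asymptote,
#'   inflection dose (micromolar); requires `e > 0` and `d > c`.
#' @param doses Strictly increasing positive doses in micromolar.
#' @param n_cells_per_well Cells seeded per well; counts are
#'   `round(n * fraction)`.
#' @param noise_sd Gaussian noise sd on the healthy fraction.
#' @param replicates Wells per dose.
#' @param seed Integer seed.
#' @return Data frame (`well`, `dose_uM`, `healthy`, `pyknotic`, `dead`) with
#'   attributes `params` and `true_ic60`.
#' @seealso [fit_4pl()], [ic60()]
#' @export
make_dose_response <- function(b, c, d, e, doses, n_cells_per_well = 500L,
                               noise_sd = 0, replicates = 1L, seed = 1L) {
  if (e <= 0) stop("inflection dose e must be > 0")
  stopifnot(d > c, all(doses > 0), all(diff(doses) > 0),
            n_cells_per_well >= 1L, noise_sd >= 0, replicates >= 1L)
  true_ic60 <- if (0.4 > c && 0.4 < d) e * ((d - c) / (0.4 - c) - 1)^(1 / b) else NA_real_
  with_seed(seed, {
    rows <- expand.grid(rep = seq_len(replicates), dose_uM = doses)
    frac <- c + (d - c) / (1 + (rows$dose_uM / e)^b)
    if (noise_sd > 0) frac <- frac + rnorm(nrow(rows), 0, noise_sd)
    frac <- pmin(pmax(frac, 0), 1)
    healthy <- round(n_cells_per_well * frac)
    rest <- n_cells_per_well - healthy
    dead <- round(0.7 * rest)
    out <- data.frame(well = sprintf("W%03d", seq_len(nrow(rows))),
                      dose_uM = rows$dose_uM,
                      healthy = healthy,
                      pyknotic = rest - dead,
                      dead = dead)
    attr(out, "params") <- c(b = b, c = c, d = d, e = e)
    attr(out, "true_ic60") <- true_ic60
    attr(out, "n_cells_per_well") <- n_cells_per_well
    out
  })
}

#' Simulate a compound screening table with a planted class shift
#'
#' Background compounds get standard-normal ICD prediction scores; a chosen
#' annotated subset is shifted upward by `planted_shift` standard deviations,
#' emulating a functional class enriched in predicted immunogenicity. IC50s
#' are log-uniform over 0.01-100 micromolar.
#'
#' @param n_compounds Total compounds (population).
#' @param n_annotated Size of the annotated class (`0 <=` and
#'   `<= n_compounds`); class members are a random subset.
#' @param planted_shift Mean shift of the class, in sd units.
#' @param seed Integer seed.
#' @param class_label Annotation label given to the class members.
#' @return Data frame (`compound_id`, `icd_score`, `ic50_uM`, `annotation`,
#'   `clinical_flag`) with attribute `annotated_ids`.
#' @seealso [ks_enrichment()]
#' @export
make_compound_table <- function(n_compounds, n_annotated, planted_shift = 0,
                                seed = 1L, class_label = "annotated") {
  stopifnot(n_compounds >= 1L, n_annotated >= 0L, n_annotated <= n_compounds)
  with_seed(seed, {
    score <- rnorm(n_compounds)
    ann <- rep("", n_compounds)
    idx <- integer(0)
    if (n_annotated > 0L) {
      idx <- sort(sample.int(n_compounds, n_annotated))
      score[idx] <- score[idx] + planted_shift
      ann[idx] <- class_label
    }
    out <- data.frame(compound_id = sprintf("C%05d", seq_len(n_compounds)),
                      icd_score = score,
                      ic50_uM = 10^runif(n_compounds, -2, 2),
                      annotation = ann,
                      clinical_flag = TRUE)
    attr(out, "annotated_ids") <- out$compound_id[idx]
    out
  })
}
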