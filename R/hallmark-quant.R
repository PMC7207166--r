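#' A named assay statistic with provenance
#'
#' Light container recording the statistic together with the anchors
#' (control identifiers) that define its scale and the number of
#' cells/wells it summarizes.
#'
#' @param assay Assay name.
#' @param value Statistic value.
#' @param units Units string (e.g. `"%"`).
#' @param anchors Named list or character vector of control identifiers.
#' @param n Number of cells/wells/tracks contributing.
#' @return An object of class `assay_result`.
#' @export
assay_result <- function(assay, value, units = "", anchors = NULL, n = NA_integer_) {
  structure(list(assay = assay, value = value, units = units,
                 anchors = anchors, n = n),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("<assay_result> %s: %.4g %s (n = %s)\n",
              x$assay, x$value, x$units, format(x$n)))
  if (!is.null(x$anchors)) {
    cat("  anchors:", paste(names(x$anchors), unlist(x$anchors),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Anchored inhibition percentage
#'
#' Ranges a condition's mean intensity between two anchors: untreated
#' control cells (0% inhibition) and blank cells never exposed to the label
#' (100% inhibition), the scheme used for EU (transcription) and AHA
#' (translation) incorporation readouts:
#' `100 * (mean(ctr) - mean(values)) / (mean(ctr) - mean(blank))`.
#' The result is not clipped by default, so over-range conditions remain
#' visible.
#'
#' @param values Per-cell intensities of the condition.
#' @param ctr_values Per-cell intensities of the untreated control.
#' @param blank_values Per-cell intensities of the unlabelled blank.
#' @param clip Clip the result to `[0, 100]`.
#' @param tol Relative tolerance below which the anchor separation is
#'   considered degenerate.
#' @return Inhibition percentage (numeric scalar).
#' @examples
#' anchored_inhibition(rep(600, 5), rep(1000, 5), rep(200, 5))  # 50
#' @export
anchored_inhibition <- function(values, ctr_values, blank_values,
                                clip = FALSE, tol = 1e-8) {
  stopifnot(length(values) >= 1L, length(ctr_values) >= 1L,
            length(blank_values) >= 1L)
  m_ctr <- mean(ctr_values)
  m_blk <- mean(blank_values)
  denom <- m_ctr - m_blk
  scale <- max(abs(m_ctr), abs(m_blk), 1)
  if (abs(denom) < tol * scale) {
    stop("degenerate anchors: control and blank means coincide")
  }
  out <- 100 * (m_ctr - mean(values)) / denom
  if (clip) out <- min(max(out, 0), 100)
  out
}

#' Top-hat dot area of CALR-GFP puncta over time
#'
#' Per timepoint, applies a white top-hat filter (disk structuring element)
#' to both treated and control fields, thresholds the filtered image, and
#' sums the area of surviving "high" pixels within the cytoplasmic mask.
#' The treated area is divided by the control area at the same timepoint and
#' the normalized series is summarized by its trapezoid area under the curve
#' (AUC). Timepoints whose control area is zero are flagged and excluded
#' from the AUC.
#'
#' @param treated,control Lists (one element per timepoint) of
#'   `list(image = <matrix>, mask = <logical/label matrix or NULL>)`; a
#'   `NULL` mask means the whole field.
#' @param timepoints Shared acquisition times in hours.
#' @param tophat_radius Disk radius of the structuring element, px.
#' @param high_threshold Threshold on the top-hat image; default is the
#'   control field's top-hat mean + 3 sd (within its mask) at each timepoint.
#' @return List with `series` (data frame: `t_hours`, `area_treated`,
#'   `area_control`, `ratio`, `flagged`), `auc`, and the thresholds used.
#' @export
calr_dot_area <- function(treated, control, timepoints,
                          tophat_radius = 5, high_threshold = NULL) {
  stopifnot(length(treated) == length(timepoints),
            length(control) == length(timepoints),
            tophat_radius >= 1)
  brush <- EBImage::makeBrush(2L * as.integer(tophat_radius) + 1L, "disc")
  tophat <- function(img) {
    as.matrix(EBImage::whiteTopHat(EBImage::Image(img / 65535), brush)) * 65535
  }
  n <- length(timepoints)
  area_t <- area_c <- thr <- numeric(n)
  for (i in seq_len(n)) {
    th_t <- tophat(treated[[i]]$image)
    th_c <- tophat(control[[i]]$image)
    mt <- treated[[i]]$mask
    mc <- control[[i]]$mask
    in_t <- if (is.null(mt)) rep(TRUE, length(th_t)) else mt > 0
    in_c <- if (is.null(mc)) rep(TRUE, length(th_c)) else mc > 0
    thr[i] <- if (is.null(high_threshold)) {
      mean(th_c[in_c]) + 3 * sd(th_c[in_c])
    } else {
      high_threshold
    }
    area_t[i] <- sum(th_t > thr[i] & in_t)
    area_c[i] <- sum(th_c > thr[i] & in_c)
  }
  flagged <- area_c == 0
  ratio <- ifelse(flagged, NA_real_, area_t / area_c)
  keep <- !flagged
  auc <- if (sum(keep) >= 2L) trapz(timepoints[keep], ratio[keep]) else NA_real_
  list(series = data.frame(t_hours = timepoints, area_treated = area_t,
                           area_control = area_c, ratio = ratio,
                           flagged = flagged),
       auc = auc, threshold = thr)
}

#' HMGB1 nuclear release speed from single-cell tracks
#'
#' Each track is normalized to its first timepoint; the release speed over
#' an interval is the consecutive difference of the normalized intensity,
#' the per-cell speed is the mean of its interval differences (which
#' telescopes to `(last - first) / (n - 1)`), and the assay statistic is the
#' mean per-cell speed. Release therefore comes out negative (intensity
#' loss). Tracks whose first value is not positive cannot be normalized and
#' are dropped with a count.
#'
#' @param tracks Long data frame with columns `subject_id`, `t_hours`,
#'   `value` (e.g. from [make_hmgb1_tracks()]).
#' @return List with `statistic` (mean speed per interval), `per_cell`
#'   (data frame `subject_id`, `speed`), `normalized` (long data frame),
#'   and `n_dropped`.
#' @export
hmgb1_release <- function(tracks) {
  stopifnot(all(c("subject_id", "t_hours", "value") %in% names(tracks)))
  tracks <- tracks[order(tracks$subject_id, tracks$t_hours), ]
  by_cell <- split(tracks, tracks$subject_id)
  dropped <- 0L
  per_cell <- list()
  norm <- list()
  for (id in names(by_cell)) {
    tr <- by_cell[[id]]
    if (nrow(tr) < 2L) stop("track ", id, " has fewer than 2 timepoints")
    if (tr$value[1L] <= 0) { dropped <- dropped + 1L; next }
    v <- tr$value / tr$value[1L]
    per_cell[[id]] <- mean(diff(v))
    norm[[id]] <- data.frame(subject_id = id, t_hours = tr$t_hours, value = v)
  }
  if (length(per_cell) == 0L) stop("no usable tracks (all first values <= 0)")
  pc <- data.frame(subject_id = names(per_cell),
                   speed = unlist(per_cell, use.names = FALSE))
  list(statistic = mean(pc$speed), per_cell = pc,
       normalized = do.call(rbind, norm), n_dropped = dropped)
}

#' Fraction of positive cells from a control-anchored threshold
#'
#' Sets the calling threshold between the intensity distributions of a
#' negative and a positive control by exhaustive 1-D search: candidate cuts
#' are the midpoints between consecutive sorted pooled control values, and
#' the cut minimizing the total number of misclassified control cells is
#' chosen (on ties, the midpoint of the two control medians). The returned
#' fraction is the share of test values beyond the threshold in the stated
#' direction. Used for MX1-GFP pathway activation (direction `"above"`,
#' IFN-treated positive control) and for quinacrine-negative calling
#' (direction `"below"`, where ATP loss lowers staining).
#'
#' @param values Test-cell intensities.
#' @param neg_ctrl_values,pos_ctrl_values Control intensity distributions.
#' @param direction `"above"` or `"below"`: side of the threshold on which
#'   test cells count as positive (the positive control is expected there).
#' @return List with `fraction`, `threshold`, and `control_error` (the
#'   misclassified share of control cells at the chosen threshold).
#' @export
positive_fraction <- function(values, neg_ctrl_values, pos_ctrl_values,
                              direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(length(values) >= 1L, length(neg_ctrl_values) >= 1L,
            length(pos_ctrl_values) >= 1L)
  pooled <- sort(unique(c(neg_ctrl_values, pos_ctrl_values)))
  if (length(pooled) < 2L) stop("controls are identical: no threshold separates them")
  # the two control distributions must actually differ, otherwise any
  # threshold separates them no better than chance
  sep_p <- suppressWarnings(ks.test(neg_ctrl_values, pos_ctrl_values,
                                    exact = FALSE)$p.value)
  if (sep_p > 0.01) {
    stop("controls overlap completely: no threshold separates better than chance")
  }
  cand <- (utils::head(pooled, -1L) + utils::tail(pooled, -1L)) / 2
  is_pos_side <- function(x, t) if (direction == "above") x > t else x < t
  err <- vapply(cand, function(t) {
    sum(!is_pos_side(pos_ctrl_values, t)) + sum(is_pos_side(neg_ctrl_values, t))
  }, numeric(1L))
  n_ctrl <- length(neg_ctrl_values) + length(pos_ctrl_values)
  best <- min(err)
  hits <- which(err == best)
  threshold <- if (length(hits) == 1L) {
    cand[hits]
  } else {
    (median(neg_ctrl_values) + median(pos_ctrl_values)) / 2
  }
  list(fraction = mean(is_pos_side(values, threshold)),
       threshold = threshold,
       control_error = best / n_ctrl)
}

#' Surface overlap coefficient of two channels
#'
#' Binarizes each channel (per-channel Otsu by default, explicit thresholds
#' or ready-made logical masks accepted) and returns
#' `|A intersect B| / |A union B|`, a symmetric overlap measure in `[0, 1]`
#' used to score fibrillarin/nucleolin colocalization (nucleolar integrity).
#'
#' @param a,b Intensity matrices or logical masks of identical dimensions.
#' @param threshold_a,threshold_b Optional explicit binarization thresholds;
#'   ignored when the input is already logical.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[1:5, ] <- TRUE
#' soc(m, m)  # 1
#' @export
soc <- function(a, b, threshold_a = NULL, threshold_b = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  ma <- binarize_channel(a, threshold_a)
  mb <- binarize_channel(b, threshold_b)
  un <- sum(ma | mb)
  if (un == 0L) stop("both masks are empty: SOC undefined")
  sum(ma & mb) / un
}

binarize_channel <- function(x, threshold) {
  if (is.logical(x)) return(x)
  if (!is.null(threshold)) return(x > threshold)
  rng <- range(x)
  if (diff(rng) <= 0) return(matrix(FALSE, nrow(x), ncol(x)))
  norm <- (x - rng[1L]) / diff(rng)
  norm > EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
}

#' Rank wells between control and maximal SOC loss
#'
#' Converts per-well SOC values to inhibition percentages anchored at the
#' control well (0% inhibition) and the dataset's lowest SOC (100%):
#' `100 * (SOC(ctr) - SOC(w)) / (SOC(ctr) - min SOC)`.
#'
#' @param soc_by_well Named numeric vector of per-well SOC values.
#' @param ctr_well Name of the control well.
#' @return Named vector of inhibition percentages.
#' @export
soc_rank <- function(soc_by_well, ctr_well) {
  stopifnot(!is.null(names(soc_by_well)))
  if (!ctr_well %in% names(soc_by_well)) stop("control well not present")
  if (length(unique(soc_by_well)) < 2L) stop("need at least 2 distinct SOC values")
  s_ctr <- soc_by_well[[ctr_well]]
  s_min <- min(soc_by_well)
  if (s_ctr <= s_min) stop("degenerate ranking: control SOC equals the dataset minimum")
  100 * (s_ctr - soc_by_well) / (s_ctr - s_min)
}

#' Cytoplasmic coefficient-of-variation translocation score
#'
#' Mean over cells of the cytoplasmic CV (population sd / mean) of a
#' channel; peripheral redistribution of CALR-RFP raises the CV while
#' uniform cytoplasmic staining keeps it near zero. Scale-invariant by
#' construction.
#'
#' @param cell_records Data frame from [measure_cells()] including
#'   `cyto_cv_<channel>`.
#' @param channel Channel role whose CV column is summarized.
#' @return An [assay_result()] with the mean CV.
#' @export
cv_translocation <- function(cell_records, channel = "signal") {
  col <- paste0("cyto_cv_", channel)
  if (!col %in% names(cell_records)) stop("no cytoplasmic CV column: ", col)
  cv <- cell_records[[col]]
  cv <- cv[is.finite(cv)]
  if (length(cv) == 0L) stop("no cells with cytoplasmic measurements")
  assay_result("cv_translocation", mean(cv), units = "",
               n = length(cv))
}
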