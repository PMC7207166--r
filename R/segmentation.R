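#' Segment nuclei from the DNA-stain channel
#'
#' Two-step scheme: Gaussian smoothing followed by an Otsu threshold yields a
#' foreground mask, and a distance-transform watershed splits touching
#' nuclei. Objects outside the `[min_area, max_area]` window (debris, clumps)
#' and objects touching the image border (partial cells that would bias
#' intensity statistics) are discarded; surviving labels are renumbered
#' 1..K.
#'
#' @param field A [field_image()] with a `dna` channel.
#' @param min_area,max_area Retained object area window in px^2.
#' @param smooth_sd Gaussian smoothing sd in px before thresholding.
#' @param watershed_tolerance Minimum distance-transform depth (px) between
#'   two catchment basins for them to stay separate objects; larger values
#'   merge more aggressively.
#' @param discard_border Drop objects touching the image border.
#' @return Integer label matrix (0 = background) of class `label_mask`, with
#'   attribute `n_objects`.
#' @examples
#' sf <- make_field(field_spec(n_cells = 8, seed = 7))
#' nuc <- segment_nuclei(sf$field, min_area = 50)
#' attr(nuc, "n_objects")
#' @export
segment_nuclei <- function(field, min_area = 50, max_area = Inf,
                           smooth_sd = 2, watershed_tolerance = 1,
                           discard_border = TRUE) {
  stopifnot(inherits(field, "field_image"))
  dna <- field$channels$dna
  if (is.null(dna)) stop("field has no 'dna' channel")
  sm <- as.matrix(EBImage::gblur(EBImage::Image(dna), sigma = smooth_sd))
  rng <- range(sm)
  if (diff(rng) < .Machine$double.eps * max(abs(rng), 1)) {
    return(empty_label_mask(dim(dna)))
  }
  norm <- (sm - rng[1L]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > th
  dm <- EBImage::distmap(EBImage::Image(bw))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance,
                                               ext = 1L))
  lab <- matrix(as.integer(lab), nrow = nrow(bw), ncol = ncol(bw))
  k <- max(lab)
  if (k > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = k)
    drop <- which(areas < min_area | areas > max_area)
    if (discard_border) {
      edge <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
      drop <- union(drop, edge[edge > 0L])
    }
    if (length(drop) > 0L) lab[lab %in% drop] <- 0L
  }
  relabel_mask(lab)
}

empty_label_mask <- function(d) {
  structure(matrix(0L, d[1L], d[2L]), n_objects = 0L, class = "label_mask")
}

# Renumber positive labels to contiguous 1..K, preserving order.
relabel_mask <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) > 0L) {
    map <- integer(max(u))
    map[u] <- seq_along(u)
    pos <- lab > 0L
    lab[pos] <- map[lab[pos]]
  }
  structure(lab, n_objects = length(u), class = "label_mask")
}

#' Derive cytoplasmic ring ROIs around segmented nuclei
#'
#' Each cytoplasmic ROI is an annulus of `ring_width` pixels around its
#' nucleus, excluding all nuclear pixels; where rings of neighbouring cells
#' would overlap, each pixel is claimed by the nucleus it is nearest to
#' (Euclidean distance to the nucleus boundary; the lower label wins exact
#' ties), so the resulting ROIs partition the ring region.
#'
#' @param nuclei A nuclear `label_mask` from [segment_nuclei()].
#' @param ring_width Ring width in px (> 0).
#' @return A `label_mask` of cytoplasmic ROIs sharing the nuclear labels.
#' @export
segment_cytoplasm <- function(nuclei, ring_width = 8) {
  stopifnot(inherits(nuclei, "label_mask"))
  if (ring_width <= 0) stop("ring_width must be > 0")
  k <- attr(nuclei, "n_objects")
  if (k == 0L) return(empty_label_mask(dim(nuclei)))
  any_nuc <- nuclei > 0L
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(ring_width)) + 1L, "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(any_nuc * 1), brush)) > 0
  ring <- dil & !any_nuc
  best_d <- matrix(Inf, nrow(nuclei), ncol(nuclei))
  best_k <- matrix(0L, nrow(nuclei), ncol(nuclei))
  for (j in seq_len(k)) {
    # distance of every pixel to nucleus j (its pixels are the zeros)
    dj <- EBImage::imageData(EBImage::distmap(EBImage::Image((nuclei != j) * 1)))
    upd <- ring & (dj < best_d)         # strict: lower label keeps exact ties
    best_d[upd] <- dj[upd]
    best_k[upd] <- j
  }
  best_k[!ring] <- 0L
  structure(matrix(as.integer(best_k), nrow(nuclei), ncol(nuclei)),
            n_objects = length(unique(best_k[best_k > 0L])),
            class = "label_mask")
}

#' Measure per-cell morphology and intensities
#'
#' Produces one record per nuclear label: nuclear area, arithmetic-mean
#' intensity per channel over the nuclear mask and (when given) the
#' cytoplasmic mask, and the cytoplasmic coefficient of variation
#' (population standard deviation / mean) per channel. Cells whose
#' cytoplasmic ROI has zero area keep their record with the cytoplasmic
#' fields set to `NA`.
#'
#' @param field A [field_image()].
#' @param nuclei Nuclear `label_mask` aligned to the field.
#' @param cytoplasm Optional cytoplasmic `label_mask` sharing the labels.
#' @return Data frame with columns `cell_id`, `nuclear_area`,
#'   `nuc_mean_<role>`, and when `cytoplasm` is given also `cyto_area`,
#'   `cyto_mean_<role>`, `cyto_cv_<role>`.
#' @export
measure_cells <- function(field, nuclei, cytoplasm = NULL) {
  stopifnot(inherits(field, "field_image"), inherits(nuclei, "label_mask"))
  if (!all(dim(nuclei) == dim(field$channels[[1L]]))) {
    stop("masks must be aligned to the field")
  }
  k <- attr(nuclei, "n_objects")
  out <- data.frame(cell_id = seq_len(k),
                    nuclear_area = tabulate(nuclei[nuclei > 0L], nbins = k))
  for (role in names(field$channels)) {
    out[[paste0("nuc_mean_", role)]] <-
      label_means(nuclei, field$channels[[role]], k)
  }
  if (!is.null(cytoplasm)) {
    stopifnot(inherits(cytoplasm, "label_mask"),
              all(dim(cytoplasm) == dim(nuclei)))
    cyt_area <- tabulate(cytoplasm[cytoplasm > 0L], nbins = k)
    out$cyto_area <- cyt_area
    for (role in names(field$channels)) {
      ch <- field$channels[[role]]
      m <- label_means(cytoplasm, ch, k)
      m2 <- label_means(cytoplasm, ch^2, k)
      psd <- sqrt(pmax(m2 - m^2, 0))    # population sd
      cv <- ifelse(m > 0, psd / m, NA_real_)
      miss <- cyt_area == 0L
      m[miss] <- NA_real_; cv[miss] <- NA_real_
      out[[paste0("cyto_mean_", role)]] <- m
      out[[paste0("cyto_cv_", role)]] <- cv
    }
  }
  out
}
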