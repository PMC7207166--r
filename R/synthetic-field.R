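#' Specify a synthetic fluorescence field
#'
#' Describes one multi-channel 2-D field for [make_field()]: nuclei rendered
#' as filled ellipses on a DNA-stain channel, a nuclear signal channel
#' carrying a planted inhibition fraction (emulating EU/AHA click-labelling
#' intensity), an optional punctate channel with dots planted in a
#' perinuclear annulus (emulating calreticulin-GFP puncta), and an optional
#' PI channel marking a planted dead-cell subset.
#'
#' @param width,height Field size in pixels.
#' @param n_cells Number of nuclei to place (>= 0).
#' @param nucleus_radius Mean nuclear semi-axis in pixels.
#' @param nucleus_radius_sd Standard deviation of the semi-axes.
#' @param channels Named list mapping a channel role (any of `"dna"`,
#'   `"signal"`, `"dots"`, `"pi"`) to a list/vector with elements
#'   `background`, `level` and `noise_sd`, all in arbitrary intensity units.
#' @param planted_inhibition Fraction in `[0, 1]` by which the per-cell level
#'   of the `signal` channel is reduced; the ground truth that downstream
#'   anchored-inhibition statistics must recover.
#' @param planted_dots List/vector with `count`, `radius` (px) and
#'   `amplitude` (a.u.) for the `dots` channel; `count = 0` plants none.
#' @param pi_positive_fraction Fraction of cells rendered PI-positive on the
#'   `pi` channel (dead-cell emulation).
#' @param touching_pairs Number of nucleus pairs deliberately placed so that
#'   they overlap (about 20% of a radius), to exercise watershed splitting.
#' @param seed Integer seed; identical spec + seed give bit-identical fields.
#' @return An object of class `field_spec`.
#' @seealso [make_field()]
#' @export
field_spec <- function(width = 256L, height = 256L, n_cells = 20L,
                       nucleus_radius = 9, nucleus_radius_sd = 1,
                       channels = list(
                         dna    = c(background = 100, level = 2000, noise_sd = 20),
                         signal = c(background = 100, level = 1500, noise_sd = 20)
                       ),
                       planted_inhibition = 0,
                       planted_dots = c(count = 0, radius = 3, amplitude = 3000),
                       pi_positive_fraction = 0,
                       touching_pairs = 0L,
                       seed = 1L) {
  stopifnot(width >= 16L, height >= 16L, n_cells >= 0L,
            nucleus_radius > 0, nucleus_radius_sd >= 0,
            touching_pairs >= 0L, 2L * touching_pairs <= max(n_cells, 0L))
  stop_if_not_scalar_prob(planted_inhibition, "planted_inhibition")
  stop_if_not_scalar_prob(pi_positive_fraction, "pi_positive_fraction")
  if (is.null(names(channels)) ||
      !all(names(channels) %in% c("dna", "signal", "dots", "pi"))) {
    stop("channel roles must be among 'dna', 'signal', 'dots', 'pi'")
  }
  channels <- lapply(channels, function(ch) {
    ch <- as.list(ch)
    stopifnot(all(c("background", "level", "noise_sd") %in% names(ch)))
    if (ch$noise_sd < 0) stop("noise_sd must be >= 0")
    ch
  })
  pd <- as.list(planted_dots)
  stopifnot(all(c("count", "radius", "amplitude") %in% names(pd)),
            pd$count >= 0, pd$radius > 0)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_cells = as.integer(n_cells),
         nucleus_radius = nucleus_radius, nucleus_radius_sd = nucleus_radius_sd,
         channels = channels, planted_inhibition = planted_inhibition,
         planted_dots = pd, pi_positive_fraction = pi_positive_fraction,
         touching_pairs = as.integer(touching_pairs), seed = as.integer(seed)),
    class = "field_spec")
}

#' Construct a multi-channel field image
#'
#' Container for one imaged field: a named list of equally sized intensity
#' matrices (one per channel role) plus acquisition identifiers.
#'
#' @param channels Named list of numeric matrices with identical dimensions
#'   and non-negative intensities.
#' @param pixel_size Optional pixel size in micrometres.
#' @param well,site,timepoint Acquisition identifiers.
#' @return An object of class `field_image`.
#' @export
field_image <- function(channels, pixel_size = NULL, well = NA_character_,
                        site = 1L, timepoint = NA_real_) {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) stop("all channels must share dimensions")
  if (any(vapply(channels, function(m) any(m < 0), logical(1L)))) {
    stop("intensities must be >= 0")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 well = well, site = site, timepoint = timepoint),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<field_image> %d x %d px, channels: %s (well %s, site %s, t %s)\n",
              d[1L], d[2L], paste(names(x$channels), collapse = ", "),
              x$well, x$site, x$timepoint))
  invisible(x)
}

# Place ellipse centres by rejection sampling so nuclei stay disjoint
# (and inside a border margin); bounded retries guard against overcrowding.
place_nuclei <- function(spec) {
  n <- spec$n_cells
  if (n == 0L) {
    return(data.frame(cx = numeric(0), cy = numeric(0), rx = numeric(0),
                      ry = numeric(0), theta = numeric(0)))
  }
  rx <- pmax(2, rnorm(n, spec$nucleus_radius, spec$nucleus_radius_sd))
  ry <- pmax(2, rnorm(n, spec$nucleus_radius, spec$nucleus_radius_sd))
  theta <- runif(n, 0, pi)
  margin <- max(rx, ry) + 3
  if (2 * margin >= min(spec$width, spec$height)) {
    stop("field too small for the requested nucleus size")
  }
  cx <- numeric(n); cy <- numeric(n)
  gap <- 3            # clearance between disjoint nuclei, px
  max_tries <- 300L * n
  tries <- 0L
  i <- 1L
  n_paired <- 2L * spec$touching_pairs
  while (i <= n) {
    if (tries >= max_tries) {
      stop(sprintf("overcrowded field: could not place nucleus %d of %d after %d tries",
                   i, n, max_tries))
    }
    tries <- tries + 1L
    if (i > 1L && i <= n_paired && i %% 2L == 0L) {
      # second member of a touching pair: ~20% overlap with its partner
      ang <- runif(1, 0, 2 * pi)
      sep <- 0.9 * (max(rx[i - 1L], ry[i - 1L]) + max(rx[i], ry[i]))
      x <- cx[i - 1L] + sep * cos(ang)
      y <- cy[i - 1L] + sep * sin(ang)
      if (x < margin || x > spec$width - margin ||
          y < margin || y > spec$height - margin) next
      js <- seq_len(i - 2L)
    } else {
      x <- runif(1, margin, spec$width - margin)
      y <- runif(1, margin, spec$height - margin)
      js <- seq_len(i - 1L)
    }
    rmax_i <- max(rx[i], ry[i])
    ok <- TRUE
    for (j in js) {
      mind <- rmax_i + max(rx[j], ry[j]) + gap
      if ((x - cx[j])^2 + (y - cy[j])^2 < mind^2) { ok <- FALSE; break }
    }
    if (!ok) next
    cx[i] <- x; cy[i] <- y
    i <- i + 1L
  }
  data.frame(cx = cx, cy = cy, rx = rx, ry = ry, theta = theta)
}

# Rasterise ellipses into a label matrix; earlier (lower) labels keep
# contested pixels, so overlapping pairs stay two objects with a clean seam.
rasterize_nuclei <- function(geom, width, height) {
  mask <- matrix(0L, nrow = width, ncol = height)
  if (nrow(geom) == 0L) return(mask)
  for (k in seq_len(nrow(geom))) {
    g <- geom[k, ]
    rmax <- ceiling(max(g$rx, g$ry))
    xs <- max(1L, floor(g$cx - rmax)):min(width, ceiling(g$cx + rmax))
    ys <- max(1L, floor(g$cy - rmax)):min(height, ceiling(g$cy + rmax))
    dx <- outer(xs - g$cx, rep(1, length(ys)))
    dy <- outer(rep(1, length(xs)), ys - g$cy)
    u <- dx * cos(g$theta) + dy * sin(g$theta)
    v <- -dx * sin(g$theta) + dy * cos(g$theta)
    inside <- (u / g$rx)^2 + (v / g$ry)^2 <= 1
    sub <- mask[xs, ys]
    sub[inside & sub == 0L] <- k
    mask[xs, ys] <- sub
  }
  mask
}

# Stamp disks of given radius/amplitude at (cx, cy) onto `img`.
stamp_disks <- function(img, cx, cy, radius, amplitude) {
  w <- nrow(img); h <- ncol(img)
  for (k in seq_along(cx)) {
    xs <- max(1L, floor(cx[k] - radius)):min(w, ceiling(cx[k] + radius))
    ys <- max(1L, floor(cy[k] - radius)):min(h, ceiling(cy[k] + radius))
    dx <- outer(xs - cx[k], rep(1, length(ys)))
    dy <- outer(rep(1, length(xs)), ys - cy[k])
    inside <- dx^2 + dy^2 <= radius^2
    sub <- img[xs, ys]
    sub[inside] <- sub[inside] + amplitude
    img[xs, ys] <- sub
  }
  img
}

#' Generate a synthetic field with known ground truth
#'
#' Renders the field described by a [field_spec()]: nuclei as filled ellipses
#' with Gaussian edge blur (sd 1 px) on the DNA channel, a sharp nuclear
#' signal channel attenuated by the planted inhibition fraction, optional
#' perinuclear dots and PI staining, plus Gaussian read noise, quantized to
#' the 16-bit unsigned range. The true label mask and a per-cell truth table
#' are returned alongside, so every downstream measurement has an oracle.
#'
#' @param spec A [field_spec()].
#' @return A list of class `synthetic_field` with elements `field`
#'   (a [field_image()]), `mask` (integer label matrix, 0 = background),
#'   `truth` (data frame: `cell_id`, geometry, `pi_positive`, per-channel
#'   expected mean `expected_<role>` and realized within-mask mean
#'   `mean_<role>`), and `spec`.
#' @examples
#' sf <- make_field(field_spec(n_cells = 5, seed = 42))
#' nrow(sf$truth)
#' @export
make_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(spec$seed, {
    geom <- place_nuclei(spec)
    mask <- rasterize_nuclei(geom, spec$width, spec$height)
    n <- spec$n_cells
    pi_pos <- rep(FALSE, n)
    if (n > 0L && spec$pi_positive_fraction > 0) {
      n_pos <- round(spec$pi_positive_fraction * n)
      if (n_pos > 0L) pi_pos[sample.int(n, n_pos)] <- TRUE
    }
    nuc <- mask > 0L
    channels <- list()
    expected <- list()
    for (role in names(spec$channels)) {
      ch <- spec$channels[[role]]
      img <- matrix(0, spec$width, spec$height)
      if (role == "dna") {
        img[nuc] <- ch$level
        img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 1))
        exp_mean <- ch$background + ch$level
      } else if (role == "signal") {
        lv <- ch$level * (1 - spec$planted_inhibition)
        img[nuc] <- lv
        exp_mean <- ch$background + lv
      } else if (role == "pi") {
        if (any(pi_pos)) img[mask %in% which(pi_pos)] <- ch$level
        exp_mean <- ch$background + ifelse(pi_pos, ch$level, 0)
      } else if (role == "dots") {
        pd <- spec$planted_dots
        if (pd$count > 0L && n > 0L) {
          for (k in seq_len(n)) {
            rr <- max(geom$rx[k], geom$ry[k])
            ang <- runif(pd$count, 0, 2 * pi)
            rad <- runif(pd$count, rr + pd$radius + 1, rr + pd$radius + 5)
            img <- stamp_disks(img, geom$cx[k] + rad * cos(ang),
                               geom$cy[k] + rad * sin(ang),
                               pd$radius, pd$amplitude)
          }
        }
        exp_mean <- rep(NA_real_, max(n, 0L))
      }
      img <- img + ch$background
      if (ch$noise_sd > 0) {
        img <- img + matrix(rnorm(length(img), 0, ch$noise_sd),
                            spec$width, spec$height)
      }
      channels[[role]] <- quantize_u16(img)
      expected[[role]] <- if (length(exp_mean) == 1L) rep(exp_mean, n) else exp_mean
    }
    truth <- data.frame(cell_id = seq_len(n),
                        cx = geom$cx, cy = geom$cy,
                        rx = geom$rx, ry = geom$ry, theta = geom$theta,
                        area_px = tabulate(mask[mask > 0L], nbins = n),
                        pi_positive = pi_pos)
    for (role in names(channels)) {
      truth[[paste0("expected_", role)]] <- expected[[role]]
      truth[[paste0("mean_", role)]] <- label_means(mask, channels[[role]], n)
    }
    structure(list(field = field_image(channels),
                   mask = mask, truth = truth, spec = spec),
              class = "synthetic_field")
  })
}

#' Write a field's channels to TIFF plus its truth table and spec
#'
#' One 16-bit single-plane TIFF per channel, named
#' `{plate}_{well}_{site}_{t}_{channel}.tif`, with the truth table as CSV and
#' the spec as YAML next to them.
#'
#' @param sf A `synthetic_field` from [make_field()].
#' @param dir Output directory (created if needed).
#' @param plate,well,site,timepoint Identifiers used in the filename pattern.
#' @return Invisibly, the vector of files written.
#' @export
write_field_tiffs <- function(sf, dir, plate = "P1", well = "A01",
                              site = 1L, timepoint = 0L) {
  stopifnot(inherits(sf, "synthetic_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("%s_%s_%d_%d", plate, well, site, timepoint)
  files <- character(0)
  for (role in names(sf$field$channels)) {
    f <- file.path(dir, sprintf("%s_%s.tif", stem, role))
    EBImage::writeImage(EBImage::Image(sf$field$channels[[role]] / 65535),
                        f, type = "tiff", bits.per.sample = 16L)
    files <- c(files, f)
  }
  truth_f <- file.path(dir, sprintf("%s_truth.csv", stem))
  write.csv(sf$truth, truth_f, row.names = FALSE)
  spec_f <- file.path(dir, sprintf("%s_spec.yaml", stem))
  sp <- sf$spec
  class(sp) <- NULL
  yaml::write_yaml(sp, spec_f)
  invisible(c(files, truth_f, spec_f))
}

#' Read a field written by [write_field_tiffs()]
#'
#' @param dir Directory containing the TIFFs.
#' @param plate,well,site,timepoint Identifiers of the field.
#' @return A [field_image()] with intensities restored to the 16-bit scale.
#' @export
read_field_tiffs <- function(dir, plate = "P1", well = "A01",
                             site = 1L, timepoint = 0L) {
  stem <- sprintf("%s_%s_%d_%d", plate, well, site, timepoint)
  files <- list.files(dir, pattern = paste0("^", stem, "_[a-z]+\\.tif$"),
                      full.names = TRUE)
  if (length(files) == 0L) stop("no channel TIFFs found for ", stem)
  roles <- sub("\\.tif$", "", sub(paste0("^", stem, "_"), "", basename(files)))
  channels <- lapply(files, function(f) {
    d <- EBImage::imageData(EBImage::readImage(f))
    matrix(round(d * 65535), nrow(d), ncol(d))
  })
  names(channels) <- roles
  field_image(channels, well = well, site = site, timepoint = timepoint)
}
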