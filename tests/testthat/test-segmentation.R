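test_that("segment_nuclei recovers planted nuclei and rejects bad input", {
  blank <- field_image(list(dna = matrix(100, 64, 64)))
  expect_equal(attr(segment_nuclei(blank), "n_objects"), 0L)

  expect_error(segment_nuclei(field_image(list(signal = matrix(1, 8, 8)))),
               "dna")

  sf <- small_field(n_cells = 10L, seed = 11L)
  nuc <- segment_nuclei(sf$field)
  expect_equal(attr(nuc, "n_objects"), 10L)
  # each truth object covered >= 95% by exactly one segmented label
  for (k in 1:10) {
    tm <- sf$mask == k
    labs <- nuc[tm]
    lab <- as.integer(names(which.max(table(labs[labs > 0L]))))
    expect_gte(sum(nuc == lab & tm) / sum(tm), 0.95)
  }
  # labels are contiguous 1..K
  expect_identical(sort(unique(as.vector(nuc[nuc > 0L]))), 1:10)
})

test_that("watershed splits touching nuclei into two objects", {
  for (s in c(2L, 5L, 13L)) {
    sf <- make_field(field_spec(n_cells = 2L, touching_pairs = 1L,
                                nucleus_radius_sd = 0.5, seed = s))
    nuc <- segment_nuclei(sf$field)
    expect_equal(attr(nuc, "n_objects"), 2L)
  }
})

test_that("area filter and border rule drop debris and partial cells", {
  sf <- small_field(n_cells = 8L, seed = 21L)
  nuc_all <- segment_nuclei(sf$field, min_area = 10)
  # raising min_area above the nuclei sizes removes everything
  nuc_none <- segment_nuclei(sf$field, min_area = 1e5)
  expect_equal(attr(nuc_none, "n_objects"), 0L)
  expect_gte(attr(nuc_all, "n_objects"), 8L - 1L)

  # paint an object across the border: it must be discarded
  dna <- matrix(100, 96, 96)
  dna[1:12, 40:52] <- 2000          # touches row 1
  dna[40:52, 40:52] <- 2000         # interior control object
  nuc <- segment_nuclei(field_image(list(dna = dna)), min_area = 20)
  expect_equal(attr(nuc, "n_objects"), 1L)
  expect_true(all(nuc[1L, ] == 0L))
})

test_that("cytoplasmic rings partition space and match brute-force dilation", {
  # single nucleus: ring equals dilation minus nucleus (within discretization)
  m <- matrix(0L, 64, 64)
  m[20:30, 20:30] <- 1L
  nuc <- as_label_mask(m)
  ring <- segment_cytoplasm(nuc, ring_width = 5)
  brush <- EBImage::makeBrush(11L, "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1), brush)) > 0
  brute <- dil & m == 0L
  expect_equal(unclass(ring) > 0L, brute, ignore_attr = TRUE)
  expect_true(all((ring > 0L) + (m > 0L) <= 1L))   # disjoint from nucleus

  # empty nuclei mask -> empty cytoplasm
  empty <- segment_cytoplasm(as_label_mask(matrix(0L, 16, 16)), 4)
  expect_equal(attr(empty, "n_objects"), 0L)

  expect_error(segment_cytoplasm(nuc, ring_width = 0), "ring_width")

  # two adjacent nuclei: annuli are disjoint and split along the midline
  m2 <- matrix(0L, 64, 64)
  m2[10:20, 28:38] <- 1L
  m2[40:50, 28:38] <- 2L
  rings <- segment_cytoplasm(as_label_mask(m2), ring_width = 8)
  expect_true(all(rings[m2 > 0L] == 0L))
  # every ring pixel claimed exactly once, nearer nucleus wins
  r1 <- which(rings == 1L, arr.ind = TRUE)
  r2 <- which(rings == 2L, arr.ind = TRUE)
  expect_true(all(r1[, 1L] <= 30L))   # midline between rows 20 and 40
  expect_true(all(r2[, 1L] >= 30L))
})

test_that("measure_cells computes means and population CV per label", {
  m <- matrix(0L, 32, 32)
  m[5:14, 5:14] <- 1L
  cyt <- matrix(0L, 32, 32)
  cyt[17:20, 1:32] <- 1L
  ch <- matrix(100, 32, 32)
  fld <- field_image(list(signal = ch))
  cells <- measure_cells(fld, as_label_mask(m), as_label_mask(cyt))
  expect_equal(cells$nuc_mean_signal, 100)
  expect_equal(cells$cyto_cv_signal, 0)

  # cytoplasm half 0, half 200: mean 100, population CV exactly 1
  ch2 <- matrix(0, 32, 32)
  ch2[, 17:32] <- 200
  cyt2 <- matrix(0L, 32, 32)
  cyt2[17:20, ] <- 1L
  cells2 <- measure_cells(field_image(list(signal = ch2)),
                          as_label_mask(m), as_label_mask(cyt2))
  expect_equal(cells2$cyto_mean_signal, 100)
  expect_equal(cells2$cyto_cv_signal, 1)

  # empty masks -> empty table
  e <- measure_cells(fld, as_label_mask(matrix(0L, 32, 32)))
  expect_equal(nrow(e), 0L)

  # zero-area cytoplasm: record kept, cyto fields NA
  cells3 <- measure_cells(fld, as_label_mask(m),
                          as_label_mask(matrix(0L, 32, 32)))
  expect_equal(nrow(cells3), 1L)
  expect_true(is.na(cells3$cyto_mean_signal))
})

test_that("measured statistics are invariant under relabelling", {
  sf <- small_field(n_cells = 6L, seed = 31L)
  nuc <- segment_nuclei(sf$field)
  k <- attr(nuc, "n_objects")
  perm <- c(k, seq_len(k - 1L))          # cyclic relabel
  relab <- matrix(0L, nrow(nuc), ncol(nuc))
  relab[nuc > 0L] <- perm[nuc[nuc > 0L]]
  relab <- as_label_mask(relab)
  a <- measure_cells(sf$field, nuc)
  b <- measure_cells(sf$field, relab)
  expect_equal(sort(a$nuc_mean_signal), sort(b$nuc_mean_signal))
  expect_equal(sort(a$nuclear_area), sort(b$nuclear_area))
})

test_that("measured means agree with the generator truth", {
  sf <- small_field(n_cells = 12L, seed = 41L, noise_frac = 0.02)
  nuc <- segment_nuclei(sf$field)
  cells <- measure_cells(sf$field, nuc)
  expect_equal(attr(nuc, "n_objects"), 12L)
  # match each segmented cell to the truth row at the same centroid
  for (i in seq_len(nrow(cells))) {
    px <- which(nuc == cells$cell_id[i], arr.ind = TRUE)
    cen <- colMeans(px)
    j <- which.min((sf$truth$cx - cen[1L])^2 + (sf$truth$cy - cen[2L])^2)
    noise_of_mean <- (0.02 * 1500) / sqrt(cells$nuclear_area[i])
    # segmentation adds a ring of sub-threshold edge pixels, so allow a
    # small multiplicative bias on top of 3x the noise-of-the-mean
    expect_lt(abs(cells$nuc_mean_signal[i] - sf$truth$mean_signal[j]),
              3 * noise_of_mean + 0.05 * sf$truth$mean_signal[j])
  }
})
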