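test_that("anchored inhibition interpolates between its anchors", {
  ctr <- rep(1000, 10)
  blank <- rep(200, 10)
  expect_equal(anchored_inhibition(ctr, ctr, blank), 0)
  expect_equal(anchored_inhibition(blank, ctr, blank), 100)
  expect_equal(anchored_inhibition(rep(600, 10), ctr, blank), 50)
  expect_error(anchored_inhibition(rep(5, 3), rep(7, 3), rep(7, 3)),
               "degenerate")
  # clipping is opt-in
  expect_lt(anchored_inhibition(rep(1200, 5), ctr, blank), 0)
  expect_equal(anchored_inhibition(rep(1200, 5), ctr, blank, clip = TRUE), 0)
})

test_that("anchored inhibition is scale- and shift-invariant", {
  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(50, 600, 30)
    ctr <- rnorm(50, 1000, 30)
    blank <- rnorm(50, 200, 30)
    base <- anchored_inhibition(v, ctr, blank)
    s <- runif(1, 0.1, 10)
    o <- runif(1, -50, 50)
    expect_equal(anchored_inhibition(s * v, s * ctr, s * blank), base,
                 tolerance = 1e-12)
    expect_equal(anchored_inhibition(v + o, ctr + o, blank + o), base,
                 tolerance = 1e-9)
  }
})

test_that("top-hat dot area recovers planted puncta and normalizes", {
  flat <- matrix(100, 64, 64)
  res <- calr_dot_area(list(list(image = flat, mask = NULL)),
                       list(list(image = flat, mask = NULL)),
                       timepoints = 0, high_threshold = 50)
  expect_equal(res$series$area_treated, 0L)

  sp <- field_spec(n_cells = 8L, seed = 3L, width = 320L, height = 320L,
                   channels = list(dna = c(background = 100, level = 2000,
                                           noise_sd = 20),
                                   dots = c(background = 100, level = 0,
                                            noise_sd = 20)),
                   planted_dots = c(count = 5, radius = 3, amplitude = 5000))
  treated <- make_field(sp)
  spc <- sp; spc$planted_dots$count <- 0; spc$seed <- 99L
  control <- make_field(spc)
  res <- calr_dot_area(list(list(image = treated$field$channels$dots, mask = NULL)),
                       list(list(image = control$field$channels$dots, mask = NULL)),
                       timepoints = 0, tophat_radius = 5)
  planted_area <- 8 * 5 * pi * 3^2
  expect_lt(abs(res$series$area_treated - planted_area) / planted_area, 0.2)

  # treated == control at every timepoint: ratio 1, AUC = t_last - t_first
  imgs <- lapply(1:4, function(t) list(image = treated$field$channels$dots,
                                       mask = NULL))
  res2 <- calr_dot_area(imgs, imgs, timepoints = c(0, 1, 2, 3),
                        tophat_radius = 5)
  expect_equal(res2$series$ratio, rep(1, 4))
  expect_equal(res2$auc, 3)

  # zero control area is flagged and excluded from the AUC
  res3 <- calr_dot_area(imgs, list(imgs[[1L]], list(image = flat, mask = NULL),
                                   imgs[[3L]], imgs[[4L]]),
                        timepoints = c(0, 1, 2, 3), tophat_radius = 5)
  expect_true(res3$series$flagged[2L])
  expect_equal(res3$auc, 3)   # trapezoid over the remaining grid 0, 2, 3
})

test_that("hmgb1 release speed telescopes and matches generator truth", {
  tr <- data.frame(subject_id = "a", t_hours = 0:3, value = c(100, 90, 80, 70))
  out <- hmgb1_release(tr)
  expect_equal(out$normalized$value, c(1, 0.9, 0.8, 0.7))
  expect_equal(out$statistic, -0.1)

  const <- data.frame(subject_id = "a", t_hours = 0:5, value = rep(7, 6))
  expect_equal(hmgb1_release(const)$statistic, 0)

  tr2 <- make_hmgb1_tracks(10L, 12L, decay_per_interval = 0.1, seed = 4L)
  closed_form <- (0.9^11 - 1) / 11
  expect_equal(hmgb1_release(tr2)$statistic, closed_form, tolerance = 1e-9)

  # telescoping: per-cell speed == (last - first) / (n - 1) exactly
  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    v <- abs(rnorm(n, 100, 30)) + 1
    tr3 <- data.frame(subject_id = "x", t_hours = seq_len(n) - 1, value = v)
    expect_equal(hmgb1_release(tr3)$per_cell$speed,
                 (v[n] / v[1L] - 1) / (n - 1), tolerance = 1e-12)
  }

  # non-positive first value: dropped with a count
  bad <- rbind(tr, data.frame(subject_id = "b", t_hours = 0:3,
                              value = c(0, 1, 2, 3)))
  expect_equal(hmgb1_release(bad)$n_dropped, 1L)
  expect_error(hmgb1_release(bad[bad$subject_id == "b", ]), "no usable")
})

test_that("positive_fraction thresholds between the control distributions", {
  set.seed(7)
  neg <- rnorm(1000, 100, 10)
  pos <- rnorm(1000, 300, 10)
  pf <- positive_fraction(rnorm(1000, 300, 10), neg, pos, "above")
  expect_gte(pf$fraction, 0.99)
  expect_gt(pf$threshold, 150); expect_lt(pf$threshold, 250)
  pf2 <- positive_fraction(neg, neg, pos, "above")
  expect_lte(pf2$fraction, 0.01)
  # direction = below mirrors the quinacrine-negative calling
  pf3 <- positive_fraction(rnorm(1000, 100, 10), pos, neg, "below")
  expect_gte(pf3$fraction, 0.99)
  expect_error(positive_fraction(neg, rnorm(500, 100, 10),
                                 rnorm(500, 100, 10), "above"),
               "chance")
})

test_that("soc equals brute-force pixel counting and is symmetric", {
  a <- matrix(FALSE, 20, 20); a[1:10, ] <- TRUE
  expect_equal(soc(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, ] <- TRUE
  expect_equal(soc(a, b), 0)
  # |A n B| = 50, |A u B| = 150
  a2 <- matrix(FALSE, 10, 15); a2[, 1:10] <- TRUE
  b2 <- matrix(FALSE, 10, 15); b2[, 6:15] <- TRUE
  expect_equal(soc(a2, b2), 1 / 3)
  expect_equal(soc(b2, a2), soc(a2, b2))
  expect_error(soc(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)), "empty")

  set.seed(11)
  for (i in 1:20) {
    x <- matrix(runif(400) < 0.4, 20, 20)
    y <- matrix(runif(400) < 0.4, 20, 20)
    if (!any(x | y)) next
    expect_identical(soc(x, y), brute_soc(x, y))
  }
})

test_that("soc decreases as masks are translated apart", {
  a <- matrix(FALSE, 40, 40); a[10:25, 10:25] <- TRUE
  socs <- vapply(0:12, function(sh) {
    b <- matrix(FALSE, 40, 40); b[10:25 + sh, 10:25] <- TRUE
    soc(a, b)
  }, numeric(1L))
  expect_true(all(diff(socs) <= 0))
  expect_equal(socs[1L], 1)
})

test_that("soc_rank anchors control at 0% and the minimum at 100%", {
  s <- c(ctr = 0.8, w1 = 0.5, w2 = 0.2)
  r <- soc_rank(s, "ctr")
  expect_equal(unname(r["ctr"]), 0)
  expect_equal(unname(r["w2"]), 100)
  expect_equal(unname(r["w1"]), 50)
  expect_error(soc_rank(c(ctr = 0.2, w = 0.8), "ctr"), "degenerate")
  expect_error(soc_rank(c(ctr = 0.5, w = 0.5), "ctr"), "distinct")
})

test_that("cv_translocation summarizes cytoplasmic CV scale-invariantly", {
  m <- matrix(0L, 32, 32); m[5:14, 5:14] <- 1L
  cyt <- matrix(0L, 32, 32); cyt[20:23, ] <- 1L
  uniform <- field_image(list(signal = matrix(100, 32, 32)))
  cells <- measure_cells(uniform, as_label_mask(m), as_label_mask(cyt))
  expect_equal(cv_translocation(cells)$value, 0)

  ch <- matrix(0, 32, 32); ch[, 17:32] <- 200
  cells2 <- measure_cells(field_image(list(signal = ch)),
                          as_label_mask(m), as_label_mask(cyt))
  expect_equal(cv_translocation(cells2)$value, 1)
  cells3 <- measure_cells(field_image(list(signal = 7.3 * ch)),
                          as_label_mask(m), as_label_mask(cyt))
  expect_equal(cv_translocation(cells3)$value,
               cv_translocation(cells2)$value, tolerance = 1e-12)
  expect_error(cv_translocation(cells[0, ]), "no cells")
})
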