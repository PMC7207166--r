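test_that("make_field is deterministic and honours the planted truth", {
  sp <- field_spec(n_cells = 10L, seed = 1L)
  a <- make_field(sp)
  b <- make_field(sp)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth, b$truth)

  # planted inhibition 0.5, zero background: truth-table mean ~ 0.5 x level
  sf <- make_field(field_spec(
    n_cells = 20L, seed = 3L,
    channels = list(dna = c(background = 100, level = 2000, noise_sd = 20),
                    signal = c(background = 0, level = 1500, noise_sd = 20)),
    planted_inhibition = 0.5))
  sem <- 20 / sqrt(min(sf$truth$area_px))
  expect_true(all(abs(sf$truth$mean_signal - 750) < 5 * sem))
})

test_that("make_field handles empty, invalid and overcrowded specs", {
  blank <- make_field(field_spec(n_cells = 0L, seed = 1L))
  expect_equal(nrow(blank$truth), 0L)
  expect_true(all(blank$mask == 0L))
  expect_equal(length(blank$field$channels), 2L)

  expect_error(field_spec(planted_inhibition = 1.5), "planted_inhibition")
  expect_error(field_spec(nucleus_radius = -1))
  expect_error(field_spec(channels = list(foo = c(background = 0, level = 1,
                                                  noise_sd = 0))), "roles")
  # 200 nuclei of radius 12 cannot fit a 64 px field
  expect_error(make_field(field_spec(width = 64L, height = 64L, n_cells = 200L,
                                     nucleus_radius = 12, seed = 1L)),
               "overcrowded|too small")
})

test_that("hmgb1 track generator follows its closed form", {
  tr <- make_hmgb1_tracks(4L, 8L, decay_per_interval = 0, seed = 2L)
  for (v in split(tr$value, tr$subject_id)) {
    expect_equal(v, rep(v[1L], 8L))
  }
  tr <- make_hmgb1_tracks(3L, 6L, decay_per_interval = 0.1, seed = 5L)
  i0 <- attr(tr, "i0")
  for (k in 1:3) {
    v <- tr$value[tr$subject_id == sprintf("cell_%03d", k)]
    expect_equal(v, i0[k] * 0.9^(0:5), tolerance = 1e-12)
  }
  expect_identical(make_hmgb1_tracks(3L, 6L, 0.1, seed = 5L), tr)
  expect_error(make_hmgb1_tracks(3L, 6L, decay_per_interval = 1.2), "decay")
  expect_error(make_hmgb1_tracks(3L, 1L, 0.1))
})

test_that("rush curve generator reproduces its boundary conditions", {
  # full, irreversible inhibition: continuous tracks the biotin control,
  # discontinuous tracks the avidin control
  rs <- make_rush_curves(planted_inhibition = 1, planted_reversibility = 1)
  expect_equal(rs$continuous, rs$biotin)
  expect_equal(rs$discontinuous, rs$avidin)

  rs <- make_rush_curves(planted_inhibition = 1, planted_reversibility = 0)
  expect_equal(rs$discontinuous, rs$continuous)

  rs <- make_rush_curves(planted_inhibition = 0.5)
  slope <- function(v) coef(lm(v ~ rs$timepoints))[[2L]]
  expect_equal(slope(rs$continuous), slope(rs$avidin) / 2, tolerance = 1e-10)

  expect_error(make_rush_curves(timepoints = c(0, 1, 3)), "uniform")
  expect_error(make_rush_curves(timepoints = c(0, 1)), ">= 3")
})

test_that("dose-response plates sit on the 4PL curve with stored truth", {
  doses <- 2^seq(-3, 4)
  pl <- make_dose_response(b = 1, c = 0, d = 1, e = 1, doses = doses,
                           n_cells_per_well = 1000L, seed = 1L)
  frac <- pl$healthy / 1000
  expect_true(all(abs(frac - 1 / (1 + doses)) <= 0.5 / 1000 + 1e-12))
  # 1 / (1 + x) = 0.4  =>  x = 1.5
  expect_equal(attr(pl, "true_ic60"), 1.5)
  expect_identical(make_dose_response(b = 1, c = 0, d = 1, e = 1, doses = doses,
                                      n_cells_per_well = 1000L, seed = 1L), pl)
  expect_error(make_dose_response(b = 1, c = 0, d = 1, e = -2, doses = doses),
               "e must be > 0")
})

test_that("compound table generator plants class shifts", {
  tbl <- make_compound_table(500L, 50L, planted_shift = 0, seed = 7L)
  inside <- tbl$icd_score[tbl$annotation == "annotated"]
  outside <- tbl$icd_score[tbl$annotation == ""]
  expect_gt(suppressWarnings(ks.test(inside, outside)$p.value), 0.01)

  tbl <- make_compound_table(500L, 50L, planted_shift = 3, seed = 7L)
  expect_gt(mean(tbl$icd_score[tbl$annotation == "annotated"]),
            mean(tbl$icd_score[tbl$annotation == ""]) + 2)
  expect_true(all(tbl$ic50_uM >= 1e-2 & tbl$ic50_uM <= 1e2))

  none <- make_compound_table(50L, 0L, seed = 1L)
  expect_equal(sum(none$annotation != ""), 0L)
  expect_error(ks_enrichment(none, "annotated"), "at least 2 members")
})

test_that("field TIFF round-trip preserves pixel data", {
  dir <- withr::local_tempdir()
  sf <- small_field(n_cells = 5L, seed = 9L)
  files <- write_field_tiffs(sf, dir, plate = "P1", well = "B02")
  expect_true(all(file.exists(files)))
  back <- read_field_tiffs(dir, plate = "P1", well = "B02")
  expect_equal(sort(names(back$channels)), sort(names(sf$field$channels)))
  expect_equal(back$channels$dna, unclass(sf$field$channels$dna),
               ignore_attr = TRUE)
})
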