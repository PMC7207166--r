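#' Define a plate layout
#'
#' Maps wells to compounds, doses and control roles. Anchored assays (EU,
#' AHA) require at least one `untreated_ctrl` and one `blank_ctrl` well;
#' positive/negative-control-based calling requires `pos_ctrl`/`neg_ctrl`.
#'
#' @param well Well identifiers (unique).
#' @param compound_id Compound per well (controls may use `""`).
#' @param role One of `treated`, `untreated_ctrl`, `blank_ctrl`,
#'   `pos_ctrl`, `neg_ctrl` per well.
#' @param dose_uM Dose per well in micromolar (`NA` for controls).
#' @return A data frame of class `plate_layout`.
#' @export
plate_layout <- function(well, compound_id, role, dose_uM = NA_real_) {
  roles <- c("treated", "untreated_ctrl", "blank_ctrl", "pos_ctrl", "neg_ctrl")
  stopifnot(length(well) == length(compound_id), length(well) == length(role))
  if (anyDuplicated(well)) stop("well identifiers must be unique")
  if (!all(role %in% roles)) {
    stop("roles must be among: ", paste(roles, collapse = ", "))
  }
  out <- data.frame(well = as.character(well),
                    compound_id = as.character(compound_id),
                    role = role,
                    dose_uM = rep_len(dose_uM, length(well)))
  class(out) <- c("plate_layout", "data.frame")
  out
}

required_roles <- function(assay) {
  switch(assay,
         eu = ,
         aha = c("untreated_ctrl", "blank_ctrl"),
         mx1 = ,
         quinacrine = c("neg_ctrl", "pos_ctrl"),
         c("untreated_ctrl"))
}

#' Validate a layout against an assay's control requirements
#'
#' @param layout A [plate_layout()].
#' @param assay Assay name (`eu`, `aha`, `mx1`, `quinacrine`, ...).
#' @return Invisibly `TRUE`; otherwise an error naming the missing role.
#' @export
validate_layout <- function(layout, assay) {
  stopifnot(inherits(layout, "plate_layout"))
  missing <- setdiff(required_roles(assay), layout$role)
  if (length(missing) > 0L) {
    stop(sprintf("layout for assay '%s' lacks required control role(s): %s",
                 assay, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Assemble a run configuration
#'
#' Collects the tunable assay parameters, seed and bookkeeping lists into a
#' single object that is serialized (as YAML) into every output for
#' provenance, together with its MD5 hash.
#'
#' @param seed Integer seed used for every stochastic step of a run.
#' @param min_area,max_area Nuclear area window for segmentation, px^2.
#' @param smooth_sd,watershed_tolerance Segmentation parameters (px).
#' @param ring_width Cytoplasmic ring width, px.
#' @param tophat_radius Disk radius for punctate quantification, px.
#' @param exclusions Character vector of excluded ids (wells, tracks or
#'   compounds) with no automatic additions.
#' @param reference_compound Reference compound id for hit gating.
#' @param ... Further named parameters carried verbatim.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, min_area = 50, max_area = Inf,
                       smooth_sd = 2, watershed_tolerance = 1,
                       ring_width = 8, tophat_radius = 5,
                       exclusions = character(0),
                       reference_compound = NA_character_, ...) {
  structure(list(seed = as.integer(seed), min_area = min_area,
                 max_area = max_area, smooth_sd = smooth_sd,
                 watershed_tolerance = watershed_tolerance,
                 ring_width = ring_width, tophat_radius = tophat_radius,
                 exclusions = exclusions,
                 reference_compound = reference_compound, ...),
            class = "run_config")
}

#' MD5 hash of a run configuration
#'
#' Hash of the canonical YAML serialization; embedded in every output table
#' so results can be traced back to the exact parameter set.
#'
#' @param config A [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  x <- config
  class(x) <- NULL
  x$max_area <- if (is.finite(x$max_area)) x$max_area else "Inf"
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}

#' Run one anchored assay over a plate
#'
#' Dispatches per-well quantification for the anchored-inhibition assays
#' (EU transcription, AHA translation): control roles are checked before
#' any computation, per-cell values of the untreated controls and blanks
#' are pooled into the anchors, and every treated well gets an anchored
#' inhibition percentage. Wells named in `config$exclusions` are dropped
#' and logged.
#'
#' @param layout A [plate_layout()].
#' @param well_values Named list mapping each well to its per-cell
#'   intensity vector (e.g. `nuc_mean_signal` from [measure_cells()]).
#' @param assay `"eu"` or `"aha"`.
#' @param config A [run_config()].
#' @return Data frame (`assay`, `well`, `compound_id`, `dose_uM`,
#'   `statistic`, `units`, `n_cells`, `anchors`, `config_hash`) with an
#'   attribute `log` recording every exclusion and its reason.
#' @export
run_assay <- function(layout, well_values, assay = c("eu", "aha"),
                      config = run_config()) {
  assay <- match.arg(assay)
  validate_layout(layout, assay)
  stopifnot(is.list(well_values), !is.null(names(well_values)))
  log <- character(0)
  excl <- intersect(layout$well, config$exclusions)
  if (length(excl) > 0L) {
    log <- c(log, sprintf("well %s excluded: listed in config$exclusions", excl))
    layout <- layout[!layout$well %in% excl, ]
  }
  missing_wells <- setdiff(layout$well, names(well_values))
  if (length(missing_wells) > 0L) {
    stop("no measurements for well(s): ", paste(missing_wells, collapse = ", "))
  }
  ctr_wells <- layout$well[layout$role == "untreated_ctrl"]
  blk_wells <- layout$well[layout$role == "blank_ctrl"]
  ctr <- unlist(well_values[ctr_wells], use.names = FALSE)
  blk <- unlist(well_values[blk_wells], use.names = FALSE)
  anchors <- sprintf("ctr=%s;blank=%s",
                     paste(ctr_wells, collapse = "+"),
                     paste(blk_wells, collapse = "+"))
  hash <- config_hash(config)
  treated <- layout[layout$role == "treated", ]
  out <- do.call(rbind, lapply(seq_len(nrow(treated)), function(i) {
    w <- treated$well[i]
    v <- well_values[[w]]
    data.frame(assay = assay, well = w,
               compound_id = treated$compound_id[i],
               dose_uM = treated$dose_uM[i],
               statistic = anchored_inhibition(v, ctr, blk),
               units = "%", n_cells = length(v),
               anchors = anchors, config_hash = hash)
  }))
  if (is.null(out)) {
    out <- data.frame(assay = character(0), well = character(0),
                      compound_id = character(0), dose_uM = numeric(0),
                      statistic = numeric(0), units = character(0),
                      n_cells = integer(0), anchors = character(0),
                      config_hash = character(0))
  }
  attr(out, "log") <- log
  out
}

#' Aggregate per-assay results into a compound table
#'
#' One row per compound with one z-scored column per assay. Replicates must
#' be flagged (`replicate` column); flagged replicates are averaged before
#' standardization, unflagged duplicates are an error. Compounds missing an
#' assay get `NA`. Columns with fewer than two finite values are kept on
#' their raw scale and reported in the `unscaled` attribute.
#'
#' @param results Data frame with columns `compound_id`, `assay`,
#'   `statistic` and optionally `replicate`.
#' @return Wide data frame `compound_id` x assays (z-scored), with
#'   attribute `unscaled` naming any non-standardized columns.
#' @export
aggregate_assays <- function(results) {
  need <- c("compound_id", "assay", "statistic")
  if (!all(need %in% names(results))) {
    stop("results must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(results$compound_id, results$assay, sep = "\r")
  if (anyDuplicated(key)) {
    if (!"replicate" %in% names(results)) {
      stop("duplicate (compound, assay) rows without a `replicate` flag")
    }
    dup_keys <- unique(key[duplicated(key)])
    bad <- key %in% dup_keys & !results$replicate
    if (any(bad)) {
      stop("duplicate (compound, assay) rows not flagged as replicates: ",
           paste(unique(results$compound_id[bad]), collapse = ", "))
    }
    agg <- stats::aggregate(statistic ~ compound_id + assay, data = results, FUN = mean)
  } else {
    agg <- results[, need]
  }
  compounds <- sort(unique(agg$compound_id))
  assays <- sort(unique(agg$assay))
  wide <- data.frame(compound_id = compounds)
  unscaled <- character(0)
  for (a in assays) {
    sub <- agg[agg$assay == a, ]
    v <- sub$statistic[match(compounds, sub$compound_id)]
    if (sum(is.finite(v)) >= 2L && sd(v[is.finite(v)]) > 0) {
      wide[[a]] <- zscore(v)
    } else {
      wide[[a]] <- v
      unscaled <- c(unscaled, a)
    }
  }
  attr(wide, "unscaled") <- unscaled
  wide
}

#' Run the full synthetic demonstration pipeline
#'
#' End-to-end exercise of the package on generated data: builds an EU-style
#' plate whose treated wells carry known planted inhibition fractions (plus
#' an untreated control and an unlabelled blank), renders one field per
#' well, segments nuclei, measures per-cell signal, computes anchored
#' inhibition per well and writes the per-cell tables, the assay results,
#' the configuration and its hash to `out_dir`. Fully deterministic:
#' rerunning with the same config writes byte-identical CSVs.
#'
#' @param out_dir Output directory.
#' @param config A [run_config()]; `config$seed` drives all randomness.
#' @param planted_inhibition Planted inhibition fractions of the treated
#'   wells.
#' @param n_cells Cells per field.
#' @param field_px Field side length in pixels.
#' @param noise_frac Gaussian read noise as a fraction of the signal level.
#' @return List with `assay_results` (data frame), `layout`, `files`
#'   (paths written) and `truth` (planted fractions by well).
#' @export
run_demo_pipeline <- function(out_dir, config = run_config(seed = 1L),
                              planted_inhibition = c(0, 0.3, 0.7, 1.0),
                              n_cells = 40L, field_px = 320L,
                              noise_frac = 0.05) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_tr <- length(planted_inhibition)
  wells <- sprintf("A%02d", seq_len(n_tr + 2L))
  layout <- plate_layout(
    well = wells,
    compound_id = c(sprintf("CPD%02d", seq_len(n_tr)), "", ""),
    role = c(rep("treated", n_tr), "untreated_ctrl", "blank_ctrl"),
    dose_uM = c(rep(1, n_tr), NA, NA))
  fractions <- c(planted_inhibition, 0, 1)   # ctr = 0, blank = 1 (no label)
  level <- 1500
  well_values <- list()
  files <- character(0)
  for (i in seq_along(wells)) {
    sp <- field_spec(width = field_px, height = field_px, n_cells = n_cells,
                     channels = list(
                       dna = c(background = 100, level = 2000,
                               noise_sd = noise_frac * 2000),
                       signal = c(background = 100, level = level,
                                  noise_sd = noise_frac * level)),
                     planted_inhibition = fractions[i],
                     seed = config$seed * 1000L + i)
    sf <- make_field(sp)
    nuc <- segment_nuclei(sf$field, min_area = config$min_area,
                          max_area = config$max_area,
                          smooth_sd = config$smooth_sd,
                          watershed_tolerance = config$watershed_tolerance)
    cells <- measure_cells(sf$field, nuc)
    well_values[[wells[i]]] <- cells$nuc_mean_signal
    f <- file.path(out_dir, sprintf("cells_%s.csv", wells[i]))
    write.csv(cells, f, row.names = FALSE)
    files <- c(files, f)
  }
  res <- run_assay(layout, well_values, assay = "eu", config = config)
  res_f <- file.path(out_dir, "assay_results.csv")
  write.csv(res, res_f, row.names = FALSE)
  cfg_f <- file.path(out_dir, "run_config.yaml")
  cfg <- config
  class(cfg) <- NULL
  cfg$max_area <- if (is.finite(cfg$max_area)) cfg$max_area else "Inf"
  cfg$hash <- config_hash(config)
  yaml::write_yaml(cfg, cfg_f)
  lay_f <- file.path(out_dir, "layout.csv")
  write.csv(as.data.frame(layout), lay_f, row.names = FALSE)
  list(assay_results = res, layout = layout,
       files = c(files, res_f, cfg_f, lay_f),
       truth = setNames(fractions, wells))
}
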