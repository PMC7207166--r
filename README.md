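# icdhallmarks

Quantification toolkit for image-based screens of **immunogenic cell death
(ICD)** hallmarks. ICD is a stress-driven death modality in which dying
cancer cells expose or release danger signals — calreticulin (CALR)
translocation, ATP secretion, HMGB1 nuclear exodus, type-1 interferon
signalling — and a recurring upstream correlate of these hallmarks is the
inhibition of transcription and translation. This package implements the
statistics such screens run on microscopy data, end to end, together with
synthetic-data generators that plant known ground truth for every stage,
so the whole chain is testable without any external images.

For high-content screeners and image analysts it provides:

* **Segmentation & measurement** — nuclear masks from the DNA channel
  (Gaussian smoothing + Otsu + distance-transform watershed), fixed-width
  cytoplasmic annuli with deterministic nearest-nucleus partitioning, and
  per-cell means/CVs (`segment_nuclei`, `segment_cytoplasm`,
  `measure_cells`).
* **Hallmark statistics** — anchored inhibition percentages for EU/AHA
  metabolic labelling, `100·(μ_ctr − μ_x)/(μ_ctr − μ_blank)`;
  top-hat puncta area with per-timepoint control normalization and
  trapezoid AUC; single-cell HMGB1 release speed (mean consecutive
  difference of first-frame-normalized tracks, which telescopes to
  `(last − first)/(n − 1)`); control-anchored positive-cell calling;
  surface overlap coefficient `SOC = |A∩B|/|A∪B|` with ranking between a
  control well and the dataset minimum; cytoplasmic CV translocation
  scores.
* **Dose–response** — healthy/pyknotic/dead partitioning and a bounded
  multi-start fit of the four-parameter log-logistic model
  `y(x) = c + (d−c)/(1+(x/e)^b)`, returning a classed model object with
  the usual `print`/`coef`/`predict`/`plot`/`residuals` methods, and the
  closed-form **IC60** (dose at 40% healthy cells),
  `e·((d−c)/(0.4−c) − 1)^{1/b}`.
* **RUSH kinetics** — inhibition as the complementary OLS-slope ratio
  against the avidin control, `100·(1 − s_cont/s_avidin)`, and
  reversibility as the area between continuous and discontinuous curves
  normalized by the control-curve area.
* **Compound integration** — z-scores, Pearson correlations with
  auditable exclusion lists, reference-anchored hit gating
  (−log10 IC50 > 6 and score above the reference inducer), and
  Kolmogorov–Smirnov class-vs-population enrichment with an exact
  conditional null distribution for small classes.

## Worked example

Simulate a plate whose treated wells carry planted transcription
inhibition of 0, 30, 70 and 100%, image it, segment it, and recover the
planted values by anchored inhibition:

```r
library(icdhallmarks)
out <- run_demo_pipeline(tempfile(), config = run_config(seed = 1L))
out$assay_results[, c("well", "compound_id", "statistic", "units", "n_cells")]
#>   well compound_id   statistic units n_cells
#> 1  A01       CPD01   0.2583038     %      40
#> 2  A02       CPD02  29.9354455     %      40
#> 3  A03       CPD03  70.1955798     %      40
#> 4  A04       CPD04 100.1038775     %      40
```

Each statistic is the inhibition percentage of one well, anchored at the
untreated control (0%) and the unlabelled blank (100%); the recovered
values sit within a fraction of a point of the planted 0/30/70/100.

Dose–response and IC60 on a noisy synthetic plate generated from known
parameters (b = 1.2, c = 0.05, d = 0.95, e = 2 µM):

```r
plate <- make_dose_response(b = 1.2, c = 0.05, d = 0.95, e = 2,
                            doses = 2^seq(-3, 4), n_cells_per_well = 500L,
                            noise_sd = 0.03, replicates = 3L, seed = 1L)
fit <- fit_4pl(plate$dose_uM, plate$healthy, total = 500L)
fit
#> Four-parameter log-logistic dose-response fit
#>   b = 1.25, c = 0.0604, d = 0.9454, e = 2.027 uM
#>   RSS = 0.01919 over 24 wells
ic60(fit)        # dose at which 40% of cells remain healthy
#> [1] 2.96  # uM; the generating parameters give 2.915
```

RUSH reversibility with full planted inhibition and 50% reversibility,
and KS enrichment of a 30-compound class shifted +3 sd inside a
5,000-compound screen:

```r
rs <- normalize_rush(make_rush_curves(planted_inhibition = 1,
                                      planted_reversibility = 0.5,
                                      noise_sd = 12, seed = 1L),
                     rep(100, 25))
inhibition_percent(rs); reversibility_percent(rs)
#> [1] 100.4
#> [1] 49.9

ks_enrichment(make_compound_table(5000L, 30L, planted_shift = 3, seed = 1L),
              "annotated")
#> KS enrichment of 'annotated' (n = 30) vs population (n = 5000)
#>   D = 0.8743, p = 3.64e-27 (two.sided), shift direction +1
```

A thin command-line wrapper over the same functions lives at
`inst/cli/icd-pipeline.R` (subcommands `demo`, `simulate`, `dose`,
`rush`, `enrich`).

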