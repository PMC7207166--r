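---
title: "Quantifying immunogenic cell death hallmarks from high-content screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunogenic cell death hallmarks from high-content screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdhallmarks)
```

## Scope and model of the data

Immunogenic cell death (ICD) is a mode of stress-driven cell death that
exposes or releases danger signals — surface calreticulin (CALR), secreted
ATP, nuclear exodus of HMGB1, type-1 interferon signalling — and thereby
recruits an adaptive antitumour immune response. In image-based screens
these hallmarks are read out per cell from multi-channel fluorescence
microscopy, summarized per well, and integrated per compound. This package
implements that quantification chain as composable functions:

1. **Synthetic data with planted truth** (`field_spec()`/`make_field()`,
   `make_hmgb1_tracks()`, `make_rush_curves()`, `make_dose_response()`,
   `make_compound_table()`): every generator returns the ground truth it
   planted, so each downstream statistic has an oracle.
2. **Segmentation and measurement** (`segment_nuclei()`,
   `segment_cytoplasm()`, `measure_cells()`).
3. **Hallmark statistics** (`anchored_inhibition()`, `calr_dot_area()`,
   `hmgb1_release()`, `positive_fraction()`, `soc()`, `soc_rank()`,
   `cv_translocation()`).
4. **Dose-response** (`classify_cells()`, `fit_4pl()`, `ic60()`).
5. **RUSH secretion kinetics** (`normalize_rush()`, `inhibition_percent()`,
   `reversibility_percent()`).
6. **Compound-level integration** (`zscore()`, `correlate()`,
   `select_hits()`, `ks_enrichment()`).
7. **Plate orchestration** (`plate_layout()`, `run_config()`, `run_assay()`,
   `aggregate_assays()`, `run_demo_pipeline()`), plus a thin command-line
   wrapper in `inst/cli/icd-pipeline.R`.

## Segmentation

Nuclei are segmented from the DNA-stain channel by Gaussian smoothing
(`smooth_sd`, default 2 px) followed by an Otsu threshold, with touching
nuclei split by a watershed on the Euclidean distance transform
(`watershed_tolerance`, default 1 px: the minimum saddle depth, in
distance-transform units, below which two candidate objects merge). The
method is deliberately parameter-light; commercial screening modules use
proprietary parameterizations that are not reconstructible, so all
thresholds here are declared defaults rather than reconstructions. Objects
outside a `[min_area, max_area]` window are treated as debris or clumps
and removed — this is also how dead-cell/debris exclusion before analysis
is expressed — and objects touching the image border are discarded because
partial nuclei bias intensity means.

Cytoplasmic ROIs are fixed-width annuli (`ring_width`, default 8 px)
around each nucleus rather than full-cell segmentations: the ring region
is the morphological dilation of the nuclear mask minus all nuclear
pixels, and where rings of neighbouring cells meet, each pixel goes to the
nucleus it is nearest to (Euclidean distance to the object; the lower
label wins exact ties, making the partition deterministic). Means are
arithmetic means over mask pixels; the cytoplasmic coefficient of
variation uses the *population* standard deviation, so a half-0/half-200
cytoplasm has CV exactly 1.

## Hallmark statistics

**Anchored inhibition.** Metabolic-labelling assays (EU for transcription,
AHA for translation) are scaled between two anchors: untreated labelled
cells define 0% inhibition and unlabelled cells define 100%. The statistic
is `100 * (mean(ctr) - mean(x)) / (mean(ctr) - mean(blank))`; it is
invariant to common rescaling and to offsets shared by all three samples,
which is why multiplicative segmentation bias (the ring of dim edge pixels
every mask picks up) cancels. Values are not clipped by default so
over-range conditions stay visible. Degenerate anchors (control and blank
means coinciding) are an explicit error, not a silent NaN.

**CALR puncta.** Punctate CALR-GFP is isolated with a white top-hat filter
(disk radius `tophat_radius`, default 5 px), thresholded at the control
field's top-hat mean + 3 sd (a declared default — the threshold rule is
configurable and computed per timepoint from that timepoint's own
control), and summed as area within the cytoplasmic mask. Each timepoint
is divided by its control; the series is summarized by a trapezoid AUC on
the acquired grid with no interpolation, and timepoints with zero control
area are flagged and excluded rather than propagating division by zero.

**HMGB1 release.** Single-cell nuclear tracks are normalized to their
first frame; the per-cell speed is the mean of consecutive differences,
which telescopes to `(last - first) / (n - 1)` — an exact closed-form
oracle used in the tests. Release is therefore a *negative* number
(intensity loss); the sign convention is kept in the reported value.
Tracks starting at non-positive intensity cannot be normalized and are
dropped with a count.

**Positive-cell calling.** The threshold between negative and positive
control distributions is the cut minimizing total misclassification of
the pooled control cells (1-D exhaustive search over midpoints of
consecutive sorted values; ties resolve to the midpoint of the two
control medians). Controls whose distributions are statistically
indistinguishable (two-sample KS, p > 0.01) are rejected: no threshold
separates them better than chance. The `direction` argument covers both
gain-of-signal calling (interferon-reporter activation) and
loss-of-signal calling (quinacrine-stained ATP vesicles).

**Colocalization.** The surface overlap coefficient of two thresholded
channels is `|A ∩ B| / |A ∪ B|` — symmetric, bounded in [0, 1], and
degenerate-safe (both-empty is an explicit error). The formula is
isolated in `soc()` so an alternative normalization such as
`|A ∩ B| / min(|A|, |B|)` is a one-line change. Per-well SOC values are
ranked between the control well (0% inhibition) and the dataset minimum
(100%) by `soc_rank()`.

## Dose-response and IC60

Cells are partitioned as dead (PI at/above threshold, taking precedence),
pyknotic (condensed nucleus AND Hoechst-high), or healthy. Cut-offs
default to control-derived values (Hoechst > control median + 2 MAD, area
< 0.6 × control median area, PI > control median + 6 MAD) because the
categories are standard but no universal intensities exist.

The healthy fraction versus dose is fitted with the four-parameter
log-logistic model `y(x) = c + (d - c) / (1 + (x/e)^b)` by bounded
Levenberg–Marquardt least squares (multi-start over `b ∈ {0.5, 1, 2, 4}`,
`c ≥ 0`, `d ≤ 1.05 × max fraction`). The fit is on fractions, not counts,
because per-well totals vary. It is performed on the dose scale, where
`y(0) = d` is well defined for `b > 0`, so control wells at dose zero
need no log-offset; a `zero_dose_offset` argument remains for strict
log-grid designs. Flat data (no dose effect) yields a non-converged
object rather than an arbitrary fit, and the IC60 — the dose at which
40% of cells remain healthy — is the closed-form inverse
`e * ((d - c)/(0.4 - c) - 1)^(1/b)`, defined only when 0.4 lies strictly
between the asymptotes.

## RUSH kinetics

The retention-using-selective-hooks assay keeps a GFP reporter on an ER
hook until biotin releases it; after washout, avidin scavenges biotin and
newly synthesized reporter re-accumulates. Four conditions on one uniform
hourly grid are required: biotin control (flat baseline), avidin control
(full re-accumulation — the 0% inhibition reference), continuous
treatment, and discontinuous (washed-out) treatment. After per-timepoint
normalization to an untreated control, inhibition is the complementary
OLS-slope ratio `100 * (1 - slope(cont)/slope(avidin))` — the convention
under which the avidin slope is 0% inhibition — and reversibility is the
trapezoid area between discontinuous and continuous curves normalized by
the area between the two control curves. Both statistics are invariant
under common rescaling, and both fail explicitly when the control
separation (avidin slope, or control area) is not positive. Outlier
timepoint exclusion is deliberately manual (explicit lists in the run
configuration); no automatic rejection rule is invented.

## Compound-level integration

Per-assay inhibition percentages are standardized as z-scores (sample sd;
`NA`s excluded from moments, propagated in place). Correlations between
hallmarks are Pearson with two-sided t-based p-values on
pairwise-complete records; exclusions are always explicit identifier
lists echoed into the output — mirroring screens that exclude named
outlier classes — never automatic.

Hit gating is anchored on a reference inducer: positives need
`-log10(IC50 in mol/L) > 6` (IC50 below 1 µM), a predicted ICD score
strictly above the reference compound's, and clinical-stage status;
negatives need IC50 above 1 µM and a score below 1. The strict inequality
means the reference itself is never a positive hit.

Class enrichment uses the two-sample Kolmogorov–Smirnov test of the
class's scores against the *entire* population, class included (a
disjoint-background variant sits behind a flag). Because annotated
classes are small (tens of compounds), the asymptotic KS p-value is
visibly conservative; `ks_enrichment()` therefore evaluates the exact
conditional null distribution of the statistic on the pooled (tied)
scores via `stats::psmirnov()` whenever `n_class × n_population ≤ 1e7`,
falling back to the asymptotic value beyond that. P-values are reported
raw, one per class, as is conventional for per-panel enrichment displays;
a Benjamini–Hochberg pass can be applied by the caller. The one-sided
option maps "class shifted high" onto the correct `psmirnov` tail.

## What the synthetic data does and does not emulate

Generated fields are 16-bit single-plane images: nuclei as filled
ellipses with Gaussian edge blur (sd 1 px) on the DNA channel, a sharp
nuclear signal channel attenuated by the planted inhibition fraction,
optional sharp perinuclear dots, and Gaussian read noise only. Defaults
(nucleus radius 9 ± 1 px, signal 1500 a.u. over a 100 a.u. background,
noise 5% of signal in the end-to-end runs, hourly time grids over 12–24 h,
4PL plates over two-fold dose ladders, 30-compound classes inside
5,000-compound screens) are chosen once to match routine 20×
high-content acquisition of U2OS-sized nuclei and screening-scale compound
sets. Deliberately *not* modelled: Poisson shot noise, illumination
gradients, point-spread functions, 3-D stacks, cell motility and focus
drift. Passing tests therefore demonstrate that the statistics recover
planted truth under idealized optics, not robustness to those artefacts;
the segmentation and threshold defaults will need adjustment on real
images.

Problem sizes in the test-suite and acceptance runs — five 800 px wells
of 200 cells for anchored recovery, 100–500 simulation seeds for the
noise sweeps, 25-timepoint RUSH grids — are the package's chosen
benchmark conditions, small enough to run routinely while leaving the
statistics well out of the small-sample regime.

## Numerical and degenerate-input conventions

* Identical spec + seed ⇒ bit-identical generator output; the caller's
  RNG state is saved and restored around every generator.
* Label masks renumber objects contiguously 1..K; relabelling inputs
  never changes any measured statistic multiset.
* Nucleus placement uses rejection sampling with bounded retries;
  overcrowded specs fail loudly rather than silently overlapping.
  Touching pairs are placed at 0.9 × the sum of radii (≈20% overlap),
  which leaves the distance-transform saddle a marker-free watershed
  needs; deeper fusions are not claimed to be splittable.
* Zero-area cytoplasm keeps its cell record with `NA` cytoplasmic fields;
  empty masks yield empty tables, not errors.
* All ratio statistics fail explicitly on degenerate denominators
  (anchor separation, avidin slope, control area, zero variance) with
  tolerances stated in the function signatures.
* Every output table of the orchestration layer embeds the MD5 hash of
  the YAML-serialized run configuration; reruns with the same
  configuration are byte-identical.

## Limitations

The cytoplasm model is a fixed annulus, not a cell boundary; quantities
needing true cell extents (total cell fluorescence, shape) are out of
scope. The dose-response layer fits the 4PL only — no Hill variants,
weighting schemes, or combination analysis. The enrichment layer takes
class membership as input and does not arbitrate annotation sources.
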