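---
title: "Automated hierarchical gating: models, primitives and quality control"
author: "cytogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated hierarchical gating: models, primitives and quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytogate)
```

## The problem

Flow cytometry quantifies cell populations by *gating*: selecting, in one- or
two-dimensional views of per-event measurements, the subsets that correspond
to cell types, and nesting those selections hierarchically (intact cells →
lymphocytes → CD3+ T cells → ...). Manual gating does not scale to cohorts of
thousands of samples and introduces operator variability. cytogate automates
the workflow while keeping its shape: strategies are ordinary R functions
that chain deterministic, data-driven gating primitives over each sample, a
batch runner applies them to whole cohorts reproducibly, and a post-hoc
quality-control step flags samples where the pattern recognition likely
failed, for human review.

The package deliberately mirrors manual 1D/2D hierarchical gating rather
than high-dimensional clustering: the output — population fractions per
sample — is directly comparable with expert gating and usable as a phenotype
in downstream analyses.

## Object model

- `EventTable` — events × channels matrix, row order fixed by the file;
  events are identified by 1-based row index throughout. (Indices are
  1-based because everything else in R is; a 0-based convention inside an R
  package would make every subscript error-prone.)
- `CytoSample` — one sample's events, metadata and accumulated `GateResult`s.
- `GateResult` — a named, strictly increasing set of event indices plus
  provenance: parent gate, view channels, producing method.
- `CytoExperiment` / `ExperimentConfig` — a batch of files plus the shared
  processing settings (compensation mode, per-channel display transforms,
  output paths, seed).
- `GatingView` — what a primitive sees: the parent population's values on
  one or two channels, display-transformed, with non-finite rows dropped
  (they can never enter a gate) and counted.

Stored event values are always raw or compensated *linear* data; display
transforms act at view time only, so counts and linear-scale statistics
remain computable after gating.

## File handling and compensation

The FCS reader supports versions 2.0/3.0/3.1, list mode, with `$DATATYPE`
`F` (float32), `D` (float64) and `I` (unsigned integers of 8/16/32 bits,
little- or big-endian, mixed channel widths allowed). ASCII data and
non-list modes are rejected with explicit errors naming the offending
keyword; a DATA segment shorter than `$TOT` implies is an integrity error.
Of chained multi-data-set files only the first set is read, with a warning.
The writer emits a single dialect — FCS 3.1, float32, little-endian — so the
write→read round trip is testable exactly at float32 precision.

Spillover matrices come from the `$SPILLOVER` keyword (or legacy
`SPILL`/`$COMP`), from tab-separated side files, or from code. Rows are
normalised to unit diagonal on read. Compensation solves the linear mixing
model `X = Y S` exactly (`Y = X S^{-1}`), touching only the labelled
channels; a condition-number bound (default 1e8) rejects numerically
unusable matrices. Computing spillover matrices or spectral unmixing is out
of scope by design — matrices are taken as provided.

## Display transforms

**Logicle.** The bi-exponential scale with parameters `T` (top of scale),
`M` (decades), `W` (linear width in decades), `A` (extra negative decades);
defaults `T = 262144, M = 4.5, W = 0.5, A = 0`, the common convention.
Internally the inverse (display → data) is the closed-form bi-exponential
`S(y) = a e^{by} − c e^{−dy} − f` (mirrored below the zero point), with
coefficients fixed by `S(x1) = 0`, `S(1) = T` and the standard width
equation `2(ln d − ln b) + w(d + b) = 0`. The forward direction is computed
by bracketed Newton iteration with bisection fallback (at most 100
iterations, residual tolerance `1e-10·T`); tests hold it to within 1e-8
display units of a pure-bisection inversion. Display units run 0 at bottom
of scale to `M + A` at `x = T`. Out-of-range inputs are transformed, not
clipped — clipping is a rendering concern.

**Bilog.** A symmetric linear/log hybrid used for fluorescence axes:
`f(x) = x/(L ln 10)` for `|x| ≤ L` and `f(x) = sign(x)(1/ln10 +
log10(|x|/L))` beyond, with `L` the linear bound. The linear slope
`1/(L ln 10)` makes the scale continuously differentiable at `±L` (a pure
`x/L` slope would leave a kink); beyond `100 L` the scale is exactly an
affine map of `log10 x`. The inverse is closed-form. The `decades`
parameter fixes the rendering range: one decade below the linear region to
`decades` above it. Axes should span the instrument's actual dynamic range —
stretching them far beyond the data compresses the populations into a
corner and dilutes the contrast QC imaging depends on.

## Gating primitives

Static shapes (threshold, quadrant, polygon, ellipse) use explicit boundary
rules so results are platform-stable: threshold boundaries belong to
"below", quadrant boundaries to the lower side, polygon edges and ellipse
boundaries are included. Polygons must be simple (checked by pairwise
segment intersection); membership is even-odd ray casting.

**Density-valley threshold.** Gaussian KDE on a 512-point grid over the view
range (optionally restricted), bandwidth by Silverman's rule unless given.
The threshold is the density minimum between the two highest *distinct*
local maxima, where a maximum only counts if the density dips by at least
10% of the lower peak between it and every stronger peak — without this
prominence rule, KDE wiggles on a single summit occasionally masquerade as
two modes. Unimodal densities raise a typed error so strategies can fall
back to a quantile. Because bandwidth dominates valley placement, the
shipped reference strategies pin their bandwidths per channel rather than
trusting the per-sample Silverman value.

**Shortest-path separation.** For two populations stacked along y, a 2D
histogram (default 256×256, Gaussian-smoothed, σ = 1 bin) is traversed by
the minimum-cost x-monotone path from the left to the right edge; step cost
is the entered bin's smoothed density plus `directionPenalty·|Δy|`, moves
are to `(x+1, y±{0,1})`, and all ties break toward the lower row. The
dynamic program is exact (verified against exhaustive path enumeration).
One wrapper-level choice matters: the search rows are restricted to the
band between the two strongest modes of the y-marginal density, because the
globally cheapest path otherwise runs through the empty margin below or
above both populations and separates nothing. The path becomes a
piecewise-linear boundary at bin centres; events strictly above it form the
upper gate.

**Mixture-model gate.** A Gaussian mixture (full covariances) is fitted by
EM via mclust — the field-standard implementation — with a seeded subset
initialisation for large views, tolerance 1e-6, at most 500 iterations, and
a regularising prior retry for degenerate covariances. One component is
selected by ascending mean (on the first view channel) or descending
weight; the gate is its `±sigma` interval (1D) or Mahalanobis-`sigma`
ellipse (2D). Gates are bit-reproducible given the seed.

**PCA ellipse.** The ellipse aligned with the principal axes of the view
covariance, scaled by the chi-square(2) quantile to enclose a target
fraction under a bivariate-normal assumption; optionally estimated on the
per-axis 10–90 percentile trimmed subset so stray events cannot inflate the
axes.

## Synthetic cohorts: what they emulate and what they do not

`referenceCohortSpec()` defines the panel used throughout the tests: five
channels (FSC-A, SSC-A, CD3, CD19, CD56), a log-normal low-scatter debris
cloud (10%), intact cells (90%) splitting into T (55%), B (25%) and NK
(12%) populations plus an unlabelled remainder, sibling populations
separated by well over 6σ on their gating channels, and a mild spillover
matrix mixed into the fluorescence channels and written into each file's
`$SPILLOVER`. At these separations a gating failure indicates a bug, not
ambiguity — that is the point of the fixture. Every sample is deterministic
given (cohort seed, sample index).

Anomaly modes emulate the failure classes batch QC is meant to catch:
`mean_shift` moves one population's signature marker (its brightest
fluorescence channel, as a staining failure would) by 4–8σ in a random
direction; `missing_population` removes a population, its weight absorbed
by the parent remainder; `debris_excess` triples the debris load. Anomalous
sample counts are exact (`round(rate · n)`).

The generator draws channels independently per population and models no
instrument noise physics, time drift, doublets, or cross-sample batch
effects. Passing tests therefore demonstrate that the algorithms recover
known structure under clean, well-separated conditions — they do not
certify performance on instrument data, where bandwidths, separations and
anomaly shapes must be validated per panel.

## Batch execution and determinism

`runExperiment()` processes samples independently: load → compensate →
strategy → statistics → QC images. Per-sample seeds are derived by hashing
the experiment seed with the sample id, results rows are ordered by sample
id, and outputs are written atomically at the end, so results are
byte-identical for any worker count (`parallel::mclapply` supplies the
parallelism). A sample that fails produces a `failed` row and never
disturbs the rest; a sample that only warns (e.g. missing spillover under
`from_file`) is marked `flagged`. The results table has one row per sample
with `<gate>_count` and `<gate>_fraction_of_parent` columns; missing
fractions are written as `NA`.

## Quality control

Per 2D-view gate, the parent view is rendered on *fixed* display ranges
(from the channel transforms, so images are comparable across samples) as a
256×256 histogram, log1p-scaled, max-normalised and block-averaged to 32×32.

Images of one gate are clustered with k-means (seeded; k by maximum mean
silhouette over 2..6). Three rules flag `image_outlier`s: membership in a
cluster smaller than `max(2, 5%)` of samples; membership in a non-dominant
cluster whose centroid lies farther from the dominant centroid than three
times the dominant cluster's RMS radius (a minority subset with a
substantially different visual aspect — small-cluster rules alone miss
anomaly groups of three or more at cohort sizes around fifty); and distance
to the own centroid beyond the 99th percentile of within-cluster distances.
Flags are invariant to input order (images are canonicalised by sample id).

Percentile flags mark, per reported statistic, samples strictly below the
`lowQ` (default 0.01) or above the `highQ` (default 0.99) interpolated
empirical quantile; missing values are never flagged. Note a structural
property: with interpolated quantiles the extreme order statistics of every
statistic are flagged whenever the values are distinct, so the expected
number of flagged samples grows with the number of statistics inspected —
with many statistics the false-positive load of this rule is substantial at
small cohort sizes. The far-point image rule similarly flags about one
sample per view by construction. Both rules are screening devices: QC never
discards samples, it orders them for inspection (contact sheets are emitted
flagged-first), and acting on flags remains the operator's decision.

## Numerical choices

- Logicle Newton: residual tolerance `1e-10·T`, 100-iteration cap,
  bisection fallback; non-convergence is a typed numerical error.
- Valley: 512-point KDE grid; 10% relative prominence; first (lowest)
  grid point taken on flat valley floors.
- Shortest path: all ties toward the lower row; smoothing kernel truncated
  at 3σ with edge renormalisation.
- Mixture fits: covariance floor via a prior-regularised retry; subset
  initialisation above 2000 events.
- Degenerate inputs: empty views render all-zero images with a warning;
  zero-variance axes raise typed errors; empty reference populations yield
  `NA` fractions, never 0.
- All condition classes are prefixed `cg_` so strategies can catch
  specific failures (`cg_no_valley`, `cg_containment_error`, ...).

## Problem sizes in the shipped checks

The test suite and the acceptance script regenerate everything they use:
100 randomised FCS round trips; a 1000-point logicle oracle grid; 100
random spillover closures; 100 random shortest-path grids up to 7×7 against
exhaustive enumeration; 1000 containment/partition fuzz views; recovery
fixtures of 5,000–20,000 events at 8σ separation; a clean 12-sample ×
20,000-event cohort for end-to-end recovery and worker invariance; and a
50-sample × 10,000-event cohort with 10% injected anomalies for QC. These
sizes put the binomial error bars well below the effects being checked
while keeping a full run in tens of seconds.

## Known limitations

- The Bilog formula is this package's definition of a linear/log hybrid
  scale; other software may parameterise such scales differently.
- The shortest-path wrapper presumes exactly two dominant modes along y;
  with one mode it degrades to an unrestricted cheapest path.
- mclust's EM replaces a from-scratch k-means++/EM implementation; the
  selection and gating logic around it are package code and fully tested,
  but initialisation details differ from other toolkits.
- The percentile QC rule's false-positive floor (extreme order statistics
  always flag) is inherent; tune `lowQ`/`highQ` and the statistic set to
  the cohort size at hand.
- QC image clustering sees only the views the strategy gates on; an
  aberration confined to an uninspected channel is invisible to it.
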