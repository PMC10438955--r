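# cytogate

Automated hierarchical gating of flow cytometry data at cohort scale.

Flow cytometry experiments measure thousands to millions of events per
sample across scatter and fluorescence channels; the analysis consists of
*gating* — selecting event subsets in 1D/2D views that correspond to cell
populations, nested hierarchically (intact cells → T cells → ...). Gating
thousands of samples by hand is slow and operator-dependent. cytogate is an
automation-first framework for users who write their gating strategy once,
as R code over deterministic pattern-recognition primitives, and then run
it over arbitrarily many FCS files with reproducible results and built-in
quality control. The per-sample output is the set of population fractions

    f(g) = |gate g| / |parent(g)|,

the statistic reported per sample and population (and used downstream as a
phenotype, e.g. in association studies).

What is inside:

* **FCS I/O** — an FCS 2.0/3.0/3.1 reader (float/double/integer data,
  either byte order, mixed channel widths) and an FCS 3.1 float32 writer;
  spillover extraction from `$SPILLOVER`/`SPILL`/`$COMP` keywords or
  tab-separated files, and compensation by exact inversion of the mixing
  model `X = Y S` (computing spillover matrices is out of scope).
* **Display transforms** — Logicle (bi-exponential, parameters `T, M, W, A`;
  forward direction by bracketed Newton against the closed-form inverse)
  and a C1 linear/log Bilog scale, plus log10/linear; all strictly
  monotone with exact or tolerance-bounded inverses, applied at view time
  only.
* **Gating primitives** — static threshold/quadrant/polygon/ellipse gates
  with fixed boundary rules; KDE valley thresholds with a peak-prominence
  rule; shortest-path valley separation on a smoothed density grid
  (enumeration-exact dynamic program); Gaussian-mixture component gates;
  PCA coverage ellipses.
* **Batch execution** — worker-count-invariant runs with per-sample derived
  seeds, fault isolation and a tab-separated results table.
* **Quality control** — down-sampled gate-view images on fixed display
  ranges, k-means/silhouette image clustering with three outlier rules,
  percentile flags on the reported statistics, merged flag tables and
  contact sheets ordered flagged-first.
* **Synthetic cohorts** — a generator of FCS cohorts with known ground
  truth (hierarchical Gaussian/log-normal populations, spillover mixing,
  injected anomalies) that makes the whole pipeline testable end to end.

## Worked example

Generate a small synthetic cohort, gate it with the shipped reference
strategy (scatter valley → shortest-path CD3 separation → CD19×CD56
quadrants → PCA core ellipse), and compare with the generator's truth:

```r
library(cytogate)

dir <- file.path(tempdir(), "cohort")
spec <- referenceCohortSpec(nSamples = 4, nEvents = 20000, seed = 1)
cohort <- generateCohort(spec, dir)

config <- referenceConfig(seed = 1, outputDir = file.path(tempdir(), "run"))
experiment <- buildExperiment(dir, config)
run <- runExperiment(experiment, "lymphocytes")

run$results[, c("sample_id", "status", "cells_count",
                "tcells_fraction_of_parent")]
#>    sample_id status cells_count tcells_fraction_of_parent
#> 1 sample_001     ok       18029                     0.553
#> 2 sample_002     ok       17984                     0.546
#> 3 sample_003     ok       17979                     0.551
#> 4 sample_004     ok       17985                     0.552
```

`cells_count` is the number of events passing the scatter gate (the
generator put 90% of events there), and `tcells_fraction_of_parent` the
CD3+ fraction of those cells. Against the realised truth labels:

```r
truth <- subset(cohort$truth, population == "tcells")
data.frame(sample_id = truth$sample_id,
           gated = round(run$results$tcells_fraction_of_parent, 4),
           truth = round(truth$true_fraction, 4))
#>    sample_id  gated  truth
#> 1 sample_001 0.5529 0.5529
#> 2 sample_002 0.5464 0.5464
#> 3 sample_003 0.5510 0.5510
#> 4 sample_004 0.5518 0.5518
```

The gated fractions match the per-sample truth to the fourth decimal: at
the cohort's population separations the automated hierarchy recovers the
ground truth essentially exactly. `buildQCReport(run$images, stats)` then
clusters the per-gate images and percentile-screens the statistics,
writing `flags.tsv` and per-gate contact sheets.

A thin command-line wrapper over the same functions ships in
`inst/cli/cytogate.R` (`simulate`, `run`, `qc`, `inspect` subcommands) for
driving batches from a shell.

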