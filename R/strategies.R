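# Reference gating strategies over the packaged synthetic panel
# (FSC-A / SSC-A / CD3 / CD19 / CD56). Together the two strategies exercise
# every gating primitive; `lymphocyteStrategy` is the hierarchy used by the
# end-to-end recovery checks.

valleyOrQuantile <- function(view, fallbackQ, bandwidth = NULL) {
  tryCatch(valleyThreshold(view, bandwidth = bandwidth),
           cg_no_valley = function(e) quantileThreshold(view, fallbackQ))
}

#' Reference strategy: scatter cleanup, then T / B / NK quadrants
#'
#' Three-level hierarchy over the reference panel:
#' 1. `cells` vs `debris` by a density-valley threshold on FSC-A;
#' 2. `tcells` vs `non_t` by the shortest-path valley between the CD3-high
#'    and CD3-low bands across FSC-A;
#' 3. within `non_t`, a quadrant gate on CD19 x CD56 at per-axis valley
#'    thresholds: `nkcells` (CD56+), `bcells` (CD19+), `b_nk_dp` (double
#'    positive), `non_t_rest`;
#' plus `tcells_core`, a 95% principal-component ellipse inside `tcells`.
#' Valley searches that find no valley (e.g. a missing population) fall
#' back to an extreme empirical quantile, so the strategy degrades rather
#' than fails on anomalous samples.
#'
#' @param sample A [CytoSample-class].
#' @param config The [ExperimentConfig-class] providing view transforms.
#' @return The sample with gates attached.
#' @export
lymphocyteStrategy <- function(sample, config) {
  # bandwidths are fixed per channel: valley placement must not depend on
  # sample-to-sample Silverman fluctuations (KDE wiggles can otherwise
  # split one mode into the two "highest" peaks)
  vFsc <- gateView(sample, "FSC-A", transforms = config)
  thr <- valleyOrQuantile(vFsc, 0.02, bandwidth = 2500)
  sample <- attachGate(sample, thresholdGate(vFsc, "cells", thr, "above"))
  sample <- attachGate(sample, thresholdGate(vFsc, "debris", thr, "below"))

  vT <- gateView(sample, c("FSC-A", "CD3"), parent = "cells",
                 transforms = config)
  sp <- shortestPathGate(vT, names = c("tcells", "non_t"), bins = c(128, 128))
  sample <- attachGate(sample, sp$upper)
  sample <- attachGate(sample, sp$lower)

  xThr <- valleyOrQuantile(gateView(sample, "CD19", parent = "non_t",
                                    transforms = config), 0.999,
                           bandwidth = 0.15)
  yThr <- valleyOrQuantile(gateView(sample, "CD56", parent = "non_t",
                                    transforms = config), 0.999,
                           bandwidth = 0.15)
  vBnk <- gateView(sample, c("CD19", "CD56"), parent = "non_t",
                   transforms = config)
  quads <- quadrantGate(vBnk, c("nkcells", "b_nk_dp", "non_t_rest", "bcells"),
                        xThr, yThr)
  for (g in quads) sample <- attachGate(sample, g)

  vCore <- gateView(sample, c("FSC-A", "CD3"), parent = "tcells",
                    transforms = config)
  sample <- attachGate(sample, pcaEllipseGate(vCore, "tcells_core",
                                              coverage = 0.95))
  sample
}

#' Reference strategy: mixture-model and static-shape gating
#'
#' Alternative route over the same panel exercising the model-based and
#' static primitives: a scatter cleanup threshold, a three-component 2D
#' Gaussian mixture on CD3 x CD19 selecting the heaviest component
#' (`tcells_gmm`), a fixed polygon for the CD3-high band (`tcells_poly`),
#' a fixed ellipse around the CD19+ region (`bcells_ellipse`) and a CD56
#' top-decile threshold (`cd56_top10`).
#'
#' @inheritParams lymphocyteStrategy
#' @return The sample with gates attached.
#' @export
mixtureStrategy <- function(sample, config) {
  vFsc <- gateView(sample, "FSC-A", transforms = config)
  thr <- valleyOrQuantile(vFsc, 0.1)
  sample <- attachGate(sample, thresholdGate(vFsc, "cells", thr, "above"))

  vTB <- gateView(sample, c("CD3", "CD19"), parent = "cells",
                  transforms = config)
  sample <- attachGate(sample,
    gmmGate(vTB, "tcells_gmm", nComponents = 3, select = "by_weight_rank",
            rank = 1, sigma = 3, seed = deriveSeed(config@seed, sample@id)))
  sample <- attachGate(sample,
    polygonGate(vTB, "tcells_poly",
                rbind(c(1.3, -1.0), c(3.5, -1.0), c(3.5, 1.3), c(1.3, 1.3))))

  vBnk <- gateView(sample, c("CD19", "CD56"), parent = "cells",
                   transforms = config)
  sample <- attachGate(sample,
    ellipseGate(vBnk, "bcells_ellipse", center = c(2.13, 0.11),
                semiAxes = c(0.7, 0.6)))

  vCd56 <- gateView(sample, "CD56", parent = "cells", transforms = config)
  sample <- attachGate(sample,
    thresholdGate(vCd56, "cd56_top10", quantileThreshold(vCd56, 0.9), "above"))
  sample
}

#' Configuration matched to the reference cohort
#'
#' Linear scatter, Bilog (linBound 500, 5 decades) fluorescence — the
#' transforms the reference strategies expect.
#'
#' @param ... Overrides passed to [experimentConfig()].
#' @return An [ExperimentConfig-class].
#' @export
referenceConfig <- function(...) {
  ch <- c("FSC-A", "SSC-A", "CD3", "CD19", "CD56")
  experimentConfig(transforms = defaultTransforms(ch), ...)
}

.onLoad <- function(libname, pkgname) {
  registerStrategy("lymphocytes", lymphocyteStrategy)
  registerStrategy("mixtures", mixtureStrategy)
}
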