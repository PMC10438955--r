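# Synthetic cytometry cohorts with known ground truth: hierarchical
# Gaussian/log-normal populations, spillover forward-mixing, injected
# anomalies. The fixture substrate that makes the whole framework testable
# without instrument data.

#' Describe one synthetic population
#'
#' @param name Population name.
#' @param parent Parent population name, or `"root"`.
#' @param weight Fraction of the parent in (0, 1]. Children weights of any
#'   parent must sum to <= 1; the remainder becomes parent-only events
#'   (label `<parent>__rest`, drawn from the parent's own channel
#'   parameters).
#' @param means Named numeric: per-channel mean on the linear data scale
#'   (for log-normal channels, the linear-scale median).
#' @param sds Named numeric: per-channel standard deviation (for log-normal
#'   channels, the standard deviation on the natural-log scale).
#' @param lognormal Character vector of channels drawn log-normally.
#' @return A population spec (list).
#' @export
populationSpec <- function(name, parent, weight, means, sds,
                           lognormal = character()) {
  if (weight <= 0 || weight > 1)
    cgStop("cg_validation_error", "population weight must lie in (0, 1]")
  if (!setequal(names(means), names(sds)))
    cgStop("cg_validation_error", "means and sds must name the same channels")
  if (any(sds <= 0))
    cgStop("cg_validation_error", "population sds must be > 0")
  list(name = name, parent = parent, weight = weight,
       means = means, sds = sds, lognormal = lognormal)
}

#' Describe a synthetic cohort
#'
#' @param nSamples Number of samples.
#' @param nEvents Events per sample.
#' @param channels Channel names.
#' @param populations List of [populationSpec()]s forming a tree rooted at
#'   `"root"`; root children weights must sum to 1.
#' @param spillover Optional [SpilloverMatrix-class] used to forward-mix the
#'   generated (true) signals; it is also written into each FCS file's
#'   `$SPILLOVER` keyword so compensation can close the loop.
#' @param anomalyRates Named numeric rates in `[0, 1]` for modes
#'   `mean_shift`, `missing_population`, `debris_excess`. Anomalous sample
#'   counts are exact (`round(rate * nSamples)`) and deterministic under
#'   `seed`.
#' @param seed Integer seed; every sample is deterministic given
#'   `(seed, sample index)`.
#' @return A cohort spec (list).
#' @export
cohortSpec <- function(nSamples, nEvents, channels, populations,
                       spillover = NULL,
                       anomalyRates = c(mean_shift = 0, missing_population = 0,
                                        debris_excess = 0),
                       seed = 1) {
  if (any(anomalyRates < 0) || any(anomalyRates > 1) || sum(anomalyRates) > 1)
    cgStop("cg_validation_error", "anomaly rates must lie in [0,1] and sum to <= 1")
  parents <- vapply(populations, `[[`, "", "parent")
  nm <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(nm))
    cgStop("cg_validation_error", "population names must be unique")
  for (p in unique(parents)) {
    w <- sum(vapply(populations[parents == p], `[[`, 0, "weight"))
    if (w > 1 + 1e-9)
      cgStop("cg_validation_error", "children of '%s' have weights summing to %g > 1", p, w)
    if (p == "root" && abs(w - 1) > 1e-9)
      cgStop("cg_validation_error", "root children weights must sum to 1 (got %g)", w)
  }
  for (pop in populations) {
    miss <- setdiff(names(pop$means), channels)
    if (length(miss))
      cgStop("cg_validation_error", "population '%s' references unknown channels: %s",
             pop$name, paste(miss, collapse = ", "))
  }
  if (!is.null(spillover)) {
    stopifnot(is(spillover, "SpilloverMatrix"))
    if (kappa(spillover@coefficients, exact = TRUE) > 1e8)
      cgStop("cg_validation_error", "cohort spillover matrix is not invertible")
  }
  list(nSamples = asCount(nSamples, "nSamples"),
       nEvents = asCount(nEvents, "nEvents"),
       channels = channels, populations = populations,
       spillover = spillover, anomalyRates = anomalyRates,
       seed = asCount(seed, "seed"))
}

# terminal labels of the population tree: leaves plus per-node residuals
terminalWeights <- function(populations) {
  nm <- vapply(populations, `[[`, "", "name")
  byName <- stats::setNames(populations, nm)
  absWeight <- function(name) {
    if (name == "root") return(1)
    p <- byName[[name]]
    p$weight * absWeight(p$parent)
  }
  parents <- vapply(populations, `[[`, "", "parent")
  out <- list()
  for (i in seq_along(populations)) {
    p <- populations[[i]]
    childW <- sum(vapply(populations[parents == p$name], `[[`, 0, "weight"))
    if (childW < 1 - 1e-9) {  # residual (for leaves: the whole population)
      label <- if (childW == 0) p$name else paste0(p$name, "__rest")
      out[[label]] <- list(weight = absWeight(p$name) * (1 - childW),
                           spec = p, population = p$name)
    }
  }
  out
}

# deterministic whole-cohort anomaly assignment: exact counts per mode
anomalyAssignments <- function(spec) {
  modes <- names(spec$anomalyRates)[spec$anomalyRates > 0]
  tags <- rep("none", spec$nSamples)
  if (!length(modes)) return(tags)
  withLocalSeed(deriveSeed(spec$seed, "anomaly_assignment"), {
    pool <- sample.int(spec$nSamples)
    off <- 0
    for (m in modes) {
      cnt <- round(spec$anomalyRates[[m]] * spec$nSamples)
      if (cnt > 0) tags[pool[(off + 1):(off + cnt)]] <- m
      off <- off + cnt
    }
  })
  tags
}

#' Generate one synthetic sample
#'
#' Draws events from the population tree (multinomial over terminal
#' weights, then per-channel Gaussians/log-normals), applies the sample's
#' anomaly if any, forward-mixes with the cohort spillover matrix and
#' shuffles event order. Deterministic given `(spec$seed, index)`.
#'
#' @param spec A [cohortSpec()].
#' @param index Sample index in `1..nSamples`.
#' @return A list: `table` (mixed [EventTable-class]), `truthTable` (the
#'   never-mixed events), `labels` (terminal population label per event),
#'   `fractions` (data.frame of realised per-population fractions of their
#'   parents), `anomaly` (tag) and `id`.
#' @export
generateSample <- function(spec, index) {
  if (index < 1 || index > spec$nSamples)
    cgStop("cg_validation_error", "sample index out of range")
  id <- sprintf("sample_%03d", index)
  anomaly <- anomalyAssignments(spec)[index]

  withLocalSeed(deriveSeed(spec$seed, id), {
    pops <- spec$populations
    anomalyDetail <- ""
    shiftable <- vapply(pops, function(p) p$parent != "root", TRUE)
    if (anomaly == "mean_shift" && any(shiftable)) {
      i <- resample(which(shiftable), 1)
      # shift the population's signature marker (its brightest fluorescence
      # channel): emulates a staining failure/drift, which is the kind of
      # aberration a gate view can in principle reveal
      fluor <- grep("^(FSC|SSC)|^Time$", names(pops[[i]]$means),
                    invert = TRUE, value = TRUE)
      if (!length(fluor)) fluor <- names(pops[[i]]$means)
      ch <- fluor[which.max(pops[[i]]$means[fluor])]
      mag <- (4 + stats::runif(1) * 4) * popLinearSd(pops[[i]], ch)
      dir <- sample(c(-1, 1), 1)
      pops[[i]]$means[ch] <- max(pops[[i]]$means[ch] + dir * mag,
                                 pops[[i]]$means[ch] / 10)
      anomalyDetail <- sprintf("%s:%s", pops[[i]]$name, ch)
    } else if (anomaly == "missing_population" && any(shiftable)) {
      i <- resample(which(shiftable), 1)
      anomalyDetail <- pops[[i]]$name
      pops <- dropPopulation(pops, pops[[i]]$name)
    } else if (anomaly == "debris_excess") {
      dbr <- which(vapply(pops, function(p)
        p$parent == "root" && grepl("debris", p$name), TRUE))
      if (length(dbr)) {
        extra <- min(2 * pops[[dbr[1]]]$weight, 0.9 - pops[[dbr[1]]]$weight)
        pops <- rescaleRootWeights(pops, dbr[1], extra)
        anomalyDetail <- pops[[dbr[1]]]$name
      }
    }

    term <- terminalWeights(pops)
    w <- vapply(term, `[[`, 0, "weight")
    counts <- as.vector(stats::rmultinom(1, spec$nEvents, w))
    labels <- rep(names(term), counts)
    values <- matrix(0, spec$nEvents, length(spec$channels),
                     dimnames = list(NULL, spec$channels))
    row <- 1
    for (t in seq_along(term)) {
      nt <- counts[t]
      if (nt == 0) next
      p <- term[[t]]$spec
      for (ch in spec$channels) {
        mu <- p$means[[ch]] %||% 0
        sd <- p$sds[[ch]] %||% 1
        values[row:(row + nt - 1), ch] <-
          if (ch %in% p$lognormal) stats::rlnorm(nt, log(max(mu, 1e-6)), sd)
          else stats::rnorm(nt, mu, sd)
      }
      row <- row + nt
    }
    perm <- sample.int(spec$nEvents)
    values <- values[perm, , drop = FALSE]
    labels <- labels[perm]
    truth <- EventTable(values, spec$channels)

    mixed <- values
    if (!is.null(spec$spillover)) {
      lb <- spec$spillover@labels
      mixed[, lb] <- mixed[, lb, drop = FALSE] %*% spec$spillover@coefficients
    }

    fractions <- realizedFractions(pops, labels, spec$nEvents)
    list(table = EventTable(mixed, spec$channels), truthTable = truth,
         labels = labels, fractions = fractions,
         anomaly = if (anomaly == "none") "none"
                   else paste0(anomaly, ":", anomalyDetail),
         id = id)
  })
}

# sample() that does not unpack a length-1 x
resample <- function(x, n) x[sample.int(length(x), n)]

popLinearSd <- function(pop, ch) {
  sd <- pop$sds[[ch]]
  if (ch %in% pop$lognormal) pop$means[[ch]] * sd else sd
}

# remove a (non-root-child) population and its subtree; the parent's
# residual absorbs the freed weight
dropPopulation <- function(pops, name) {
  nm <- vapply(pops, `[[`, "", "name")
  parents <- vapply(pops, `[[`, "", "parent")
  doomed <- name
  repeat {
    more <- nm[parents %in% doomed & !nm %in% doomed]
    if (!length(more)) break
    doomed <- c(doomed, more)
  }
  pops[!nm %in% doomed]
}

rescaleRootWeights <- function(pops, grow, extra) {
  pops[[grow]]$weight <- pops[[grow]]$weight + extra
  others <- which(vapply(pops, function(p) p$parent == "root", TRUE))
  others <- setdiff(others, grow)
  tot <- sum(vapply(pops[others], `[[`, 0, "weight"))
  for (i in others)
    pops[[i]]$weight <- pops[[i]]$weight * (1 - pops[[grow]]$weight) / tot
  pops
}

# realised fraction of each population relative to its parent
realizedFractions <- function(pops, labels, n) {
  nm <- vapply(pops, `[[`, "", "name")
  term <- terminalWeights(pops)
  termPop <- vapply(term, `[[`, "", "population")
  termCount <- vapply(names(term), function(l) sum(labels == l), 0L)
  subtreeCount <- function(name) {
    own <- sum(termCount[termPop == name])
    kids <- nm[vapply(pops, function(p) p$parent == name, TRUE)]
    own + sum(vapply(kids, subtreeCount, 0))
  }
  parentOf <- stats::setNames(vapply(pops, `[[`, "", "parent"), nm)
  counts <- vapply(nm, subtreeCount, 0)
  parentCounts <- vapply(nm, function(x) {
    p <- parentOf[[x]]
    if (p == "root") n else subtreeCount(p)
  }, 0)
  data.frame(population = nm, parent = unname(parentOf),
             count = unname(counts),
             parent_count = unname(parentCounts),
             fraction = unname(ifelse(parentCounts > 0, counts / parentCounts, NA)),
             stringsAsFactors = FALSE)
}

#' Generate a cohort of FCS files plus a ground-truth table
#'
#' Writes `nSamples` FCS 3.1 files (with the cohort spillover in
#' `$SPILLOVER`) and `truth.tsv` with columns `sample_id`, `population`,
#' `parent`, `true_fraction` (realised fraction of parent), `anomaly`.
#'
#' @param spec A [cohortSpec()].
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `files` and `truth` (the truth
#'   table as a data.frame).
#' @export
generateCohort <- function(spec, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  files <- character(spec$nSamples)
  for (i in seq_len(spec$nSamples)) {
    s <- generateSample(spec, i)
    keywords <- list()
    if (!is.null(spec$spillover))
      keywords[["$SPILLOVER"]] <- serializeSpillover(spec$spillover)
    md <- FCSMetadata(spec$channels, nEvents(s$table), keywords = keywords)
    files[i] <- file.path(outDir, paste0(s$id, ".fcs"))
    writeFCS(s$table, files[i], md)
    rows[[i]] <- data.frame(sample_id = s$id,
                            population = s$fractions$population,
                            parent = s$fractions$parent,
                            true_fraction = s$fractions$fraction,
                            anomaly = s$anomaly,
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  utils::write.table(truth, file.path(outDir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(list(dir = outDir, files = files, truth = truth))
}

#' The packaged reference cohort description
#'
#' A lymphocyte-like five-channel panel: scatter debris vs intact cells,
#' then CD3+ T cells versus CD19+ B cells and CD56+ NK cells, with an
#' unlabelled remainder. Sibling populations are separated by well over 6
#' standard deviations on their gating channels, so gating failures indicate
#' bugs rather than ambiguity. Fluorescence channels are forward-mixed with
#' a mild spillover matrix that is also written into the files.
#'
#' @param nSamples Number of samples. Default 12.
#' @param nEvents Events per sample. Default 20000.
#' @param anomalyRates Passed to [cohortSpec()]. Default: none.
#' @param seed Cohort seed. Default 1.
#' @return A [cohortSpec()].
#' @export
referenceCohortSpec <- function(nSamples = 12, nEvents = 20000,
                                anomalyRates = c(mean_shift = 0,
                                                 missing_population = 0,
                                                 debris_excess = 0),
                                seed = 1) {
  ch <- c("FSC-A", "SSC-A", "CD3", "CD19", "CD56")
  lowF <- c(CD3 = 120, CD19 = 120, CD56 = 130)
  lowS <- c(CD3 = 70, CD19 = 70, CD56 = 70)
  pops <- list(
    populationSpec("debris", "root", 0.10,
                   means = c("FSC-A" = 2500, "SSC-A" = 2000, lowF),
                   sds = c("FSC-A" = 0.35, "SSC-A" = 0.4, lowS),
                   lognormal = c("FSC-A", "SSC-A")),
    populationSpec("cells", "root", 0.90,
                   means = c("FSC-A" = 60000, "SSC-A" = 30000, lowF),
                   sds = c("FSC-A" = 5000, "SSC-A" = 5000, lowS)),
    populationSpec("tcells", "cells", 0.55,
                   means = c("FSC-A" = 60000, "SSC-A" = 28000,
                             CD3 = 30000, CD19 = 120, CD56 = 130),
                   sds = c("FSC-A" = 5000, "SSC-A" = 4000,
                           CD3 = 3000, CD19 = 70, CD56 = 70)),
    populationSpec("bcells", "cells", 0.25,
                   means = c("FSC-A" = 58000, "SSC-A" = 30000,
                             CD3 = 120, CD19 = 25000, CD56 = 130),
                   sds = c("FSC-A" = 5000, "SSC-A" = 4500,
                           CD3 = 70, CD19 = 2500, CD56 = 70)),
    populationSpec("nkcells", "cells", 0.12,
                   means = c("FSC-A" = 61000, "SSC-A" = 32000,
                             CD3 = 130, CD19 = 120, CD56 = 18000),
                   sds = c("FSC-A" = 5000, "SSC-A" = 4500,
                           CD3 = 70, CD19 = 70, CD56 = 2000))
  )
  spill <- SpilloverMatrix(matrix(c(1, 0.06, 0.03,
                                    0.05, 1, 0.04,
                                    0.02, 0.05, 1), 3, 3, byrow = TRUE),
                           c("CD3", "CD19", "CD56"), normalize = FALSE)
  cohortSpec(nSamples, nEvents, ch, pops, spillover = spill,
             anomalyRates = anomalyRates, seed = seed)
}
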