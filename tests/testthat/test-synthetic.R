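tinySpec <- function(seed = 1, spill = NULL, rates = c(mean_shift = 0,
                                                       missing_population = 0,
                                                       debris_excess = 0),
                     n = 10000, samples = 2) {
  pops <- list(
    populationSpec("low", "root", 0.7, means = c(a = 0, b = 0),
                   sds = c(a = 1, b = 1)),
    populationSpec("high", "root", 0.3, means = c(a = 10, b = 10),
                   sds = c(a = 1, b = 1)))
  cohortSpec(samples, n, c("a", "b"), pops, spillover = spill,
             anomalyRates = rates, seed = seed)
}

test_that("realised fractions match spec weights within binomial error", {
  s <- generateSample(tinySpec(seed = 5), 1)
  fr <- s$fractions
  expect_setequal(fr$population, c("low", "high"))
  se <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(fr$fraction[fr$population == "low"] - 0.7), 3 * se)
  expect_identical(sum(fr$count), 10000)
  expect_identical(length(s$labels), 10000L)
})

test_that("generation is deterministic per (seed, index) and mixes spillover", {
  sp <- SpilloverMatrix(matrix(c(1, 0.1, 0.05, 1), 2, 2, byrow = TRUE),
                        c("a", "b"), normalize = FALSE)
  s1 <- generateSample(tinySpec(seed = 9, spill = sp), 1)
  s2 <- generateSample(tinySpec(seed = 9, spill = sp), 1)
  expect_identical(eventValues(s1$table), eventValues(s2$table))
  expect_identical(s1$labels, s2$labels)
  sOther <- generateSample(tinySpec(seed = 9, spill = sp), 2)
  expect_false(identical(eventValues(s1$table), eventValues(sOther$table)))

  # the mixed table is exactly truth %*% S
  expect_equal(eventValues(s1$table),
               eventValues(s1$truthTable) %*% sp@coefficients,
               ignore_attr = TRUE)

  # identity spillover: mixed equals unmixed
  id <- SpilloverMatrix(diag(2), c("a", "b"), normalize = FALSE)
  s3 <- generateSample(tinySpec(seed = 9, spill = id), 1)
  expect_identical(eventValues(s3$table), eventValues(s3$truthTable))
})

test_that("cohort generation writes readable files and a truth table", {
  dir <- withr::local_tempdir()
  spec <- referenceCohortSpec(nSamples = 4, nEvents = 2000, seed = 3)
  co <- generateCohort(spec, dir)
  expect_length(co$files, 4)
  for (f in co$files) {
    rt <- readFCS(f)
    expect_identical(nEvents(rt$metadata), 2000L)
    expect_identical(channels(rt$table), spec$channels)
    expect_s4_class(extractSpillover(rt$metadata), "SpilloverMatrix")
  }
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  tr <- read.delim(file.path(dir, "truth.tsv"))
  expect_setequal(unique(tr$population),
                  c("debris", "cells", "tcells", "bcells", "nkcells"))
  expect_identical(nrow(tr), 4L * 5L)
})

test_that("anomaly counts are exact and tagged deterministically", {
  spec <- referenceCohortSpec(nSamples = 20, nEvents = 500,
                              anomalyRates = c(mean_shift = 0.1,
                                               missing_population = 0.1,
                                               debris_excess = 0.05),
                              seed = 11)
  tags <- vapply(1:20, function(i) generateSample(spec, i)$anomaly, "")
  expect_identical(sum(grepl("^mean_shift", tags)), 2L)
  expect_identical(sum(grepl("^missing_population", tags)), 2L)
  expect_identical(sum(grepl("^debris_excess", tags)), 1L)
  # missing populations really vanish from the truth labels
  gone <- sub("missing_population:", "", tags[grepl("^missing_population", tags)])
  i <- which(grepl("^missing_population", tags))[1]
  s <- generateSample(spec, i)
  expect_false(gone[1] %in% sub("__rest", "", s$labels))
})

test_that("compensating mixed data recovers gating on never-mixed data", {
  sp <- SpilloverMatrix(matrix(c(1, 0.12, 0.08, 1), 2, 2, byrow = TRUE),
                        c("a", "b"), normalize = FALSE)
  s <- generateSample(tinySpec(seed = 21, spill = sp), 1)
  comp <- applyCompensation(s$table, sp)
  # per-event agreement of a mid-valley threshold gate on channel a
  gMixed <- eventValues(comp)[, "a"] > 5
  gTruth <- eventValues(s$truthTable)[, "a"] > 5
  expect_gte(mean(gMixed == gTruth), 0.995)
  expect_lt(max(abs(eventValues(comp) - eventValues(s$truthTable))), 1e-8)
})

test_that("population specs are validated", {
  expect_error(populationSpec("x", "root", 0, c(a = 1), c(a = 1)),
               class = "cg_validation_error")
  expect_error(populationSpec("x", "root", 0.5, c(a = 1), c(b = 1)),
               class = "cg_validation_error")
  pops <- list(populationSpec("a", "root", 0.6, c(x = 0), c(x = 1)),
               populationSpec("b", "root", 0.6, c(x = 5), c(x = 1)))
  expect_error(cohortSpec(2, 100, "x", pops), class = "cg_validation_error")
  ok <- list(populationSpec("a", "root", 1, c(x = 0), c(x = 1)))
  expect_error(cohortSpec(2, 100, "x",
                          list(populationSpec("a", "root", 1, c(y = 0), c(y = 1)))),
               class = "cg_validation_error")
  expect_silent(cohortSpec(2, 100, "x", ok))
})
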