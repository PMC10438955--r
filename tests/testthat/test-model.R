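writeCohortDir <- function(n = 3, events = 200, seed = 1) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  set.seed(seed)
  for (i in seq_len(n)) {
    et <- EventTable(matrix(rnorm(events * 2), events, 2), c("a", "b"))
    writeFCS(et, file.path(dir, sprintf("s%02d.fcs", i)))
  }
  dir
}

test_that("experiments enumerate files in order and flag unreadable ones", {
  dir <- writeCohortDir(3)
  ex <- buildExperiment(dir, experimentConfig("none"))
  expect_identical(sampleIds(ex), c("s01", "s02", "s03"))

  # corrupt one file: still three paths, one flagged parse_failure
  writeLines("not an fcs file", file.path(dir, "s02.fcs"))
  ex2 <- buildExperiment(dir, experimentConfig("none"))
  expect_identical(length(ex2@samplePaths), 3L)
  expect_identical(ex2@flagged$sample_id, "s02")
  expect_identical(ex2@flagged$reason, "parse_failure")

  empty <- withr::local_tempdir()
  expect_error(buildExperiment(empty, experimentConfig("none")),
               class = "cg_config_error")
})

test_that("loading applies compensation per the configured mode", {
  spillKw <- "2,a,b,1,0.08,0.05,1"
  S <- matrix(c(1, 0.08, 0.05, 1), 2, 2, byrow = TRUE)
  set.seed(3)
  truth <- matrix(rexp(400, 1e-2), 200, 2, dimnames = list(NULL, c("a", "b")))
  mixed <- truth %*% S
  dir <- withr::local_tempdir()
  md <- FCSMetadata(c("a", "b"), 200, keywords = list("$SPILLOVER" = spillKw))
  writeFCS(EventTable(mixed, c("a", "b")), file.path(dir, "m.fcs"), md)

  # from_file: values match the pre-mix truth
  ex <- buildExperiment(dir, experimentConfig("from_file"))
  s <- loadSample(ex, "m")
  expect_lt(max(abs(eventValues(s@table) - truth) / pmax(truth, 1)), 1e-4)

  # none: values are the mixed raw data (float32 precision)
  exNone <- buildExperiment(dir, experimentConfig("none"))
  sN <- loadSample(exNone, "m")
  expect_equal(as.vector(eventValues(sN@table)), asFloat32(mixed))

  # external file wins over the keyword
  spillPath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t0.08", "0.05\t1"), spillPath)
  exExt <- buildExperiment(dir, experimentConfig("external",
                                                 externalSpilloverPath = spillPath))
  sE <- loadSample(exExt, "m")
  expect_lt(max(abs(eventValues(sE@table) - truth) / pmax(truth, 1)), 1e-4)

  # from_file without a spillover keyword warns and loads uncompensated
  writeFCS(EventTable(mixed, c("a", "b")), file.path(dir, "plain.fcs"))
  ex2 <- buildExperiment(dir, experimentConfig("from_file"))
  expect_warning(s2 <- loadSample(ex2, "plain"), class = "cg_no_spillover")
  expect_equal(as.vector(eventValues(s2@table)), asFloat32(mixed))

  expect_error(loadSample(ex, "nope"), class = "cg_lookup_error")
})

test_that("gate attachment enforces lineage, containment and unique names", {
  s <- makeSample(cbind(a = 1:1000))
  root <- GateResult("all", 1:1000, "root", "a", "manual")
  s <- attachGate(s, root)
  expect_identical(gateNames(s), "all")

  child <- GateResult("top", 501:1000, "all", "a", "manual")
  s <- attachGate(s, child)
  expect_error(attachGate(s, GateResult("top", 1:5, "all", "a")),
               class = "cg_name_collision")
  expect_error(attachGate(s, GateResult("o", 1:5, "ghost", "a")),
               class = "cg_lineage_error")
  bad <- GateResult("bad", c(400, 600), "top", "a")
  expect_error(attachGate(s, bad), class = "cg_containment_error")
})

test_that("population fractions are exact ratios with NA for empty references", {
  s <- makeSample(cbind(a = 1:1000))
  s <- attachGate(s, GateResult("all", 1:1000, "root", "a"))
  s <- attachGate(s, GateResult("quarter", 1:250, "all", "a"))
  s <- attachGate(s, GateResult("none", integer(), "quarter", "a"))
  s <- attachGate(s, GateResult("orphan_leaf", integer(), "none", "a"))

  expect_identical(populationFraction(s, "quarter", "all"), 0.25)
  expect_identical(populationFraction(s, "quarter", "quarter"), 1)
  expect_true(is.na(populationFraction(s, "orphan_leaf", "none")))
  expect_error(populationFraction(s, "nope"), class = "cg_lookup_error")
  expect_error(populationFraction(s, "quarter", "none"),
               class = "cg_lineage_error")
})

test_that("fractions along a root-to-leaf chain multiply to the root fraction", {
  set.seed(8)
  for (rep in 1:20) {
    n <- 500
    s <- makeSample(cbind(a = runif(n)))
    parent <- "root"
    idx <- seq_len(n)
    prod <- 1
    for (lvl in 1:4) {
      keep <- sort(sample(idx, max(1, floor(length(idx) * runif(1, 0.3, 0.9)))))
      name <- paste0("g", lvl)
      s <- attachGate(s, GateResult(name, keep, parent, "a"))
      prod <- prod * populationFraction(s, name, parent)
      # containment is transitive: always a subset of the root population
      expect_true(all(keep %in% seq_len(n)))
      parent <- name
      idx <- keep
    }
    expect_equal(prod, populationFraction(s, "g4", "root"), tolerance = 1e-12)
  }
})

test_that("configuration files round trip through yaml and json", {
  cfg <- experimentConfig("none",
                          transforms = list(CD3 = bilogTransform(300, 4),
                                            "FSC-A" = linearTransform()),
                          imageResolution = 16L, workers = 2L, seed = 9L)
  for (ext in c(".yaml", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    writeExperimentConfig(cfg, p)
    cfg2 <- readExperimentConfig(p)
    expect_identical(cfg2@compensationMode, "none")
    expect_identical(cfg2@imageResolution, 16L)
    expect_identical(cfg2@workers, 2L)
    expect_identical(cfg2@seed, 9L)
    expect_s4_class(cfg2@transforms$CD3, "BilogTransform")
    expect_identical(cfg2@transforms$CD3@linBound, 300)
    expect_s4_class(cfg2@transforms$`FSC-A`, "LinearTransform")
  }
})
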