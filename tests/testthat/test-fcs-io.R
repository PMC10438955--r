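test_that("write/read round trip is the identity at float32 precision", {
  set.seed(11)
  et <- EventTable(matrix(rnorm(1000 * 5, sd = 1e4), 1000, 5),
                   c("FSC-A", "SSC-A", "FL1", "FL2", "Time"))
  p <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(et, p)
  rt <- readFCS(p)
  expect_identical(dim(eventValues(rt$table)), c(1000L, 5L))
  expect_identical(channels(rt$table), channels(et))
  expect_identical(as.vector(eventValues(rt$table)),
                   asFloat32(eventValues(et)))
  expect_equal(nEvents(rt$metadata), 1000L)

  # exactly representable values come back bit-identical
  et2 <- EventTable(matrix(c(1.5, -3.25, 1e6, 0), 2, 2), c("a", "b"))
  p2 <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(et2, p2)
  expect_identical(as.vector(eventValues(readFCS(p2)$table)),
                   c(1.5, -3.25, 1e6, 0))
})

test_that("writer records header bookkeeping and handles zero events", {
  et <- EventTable(matrix(rnorm(20), 10, 2), c("a", "b"))
  p <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(et, p)
  md <- readFCS(p, what = "metadata")$metadata
  expect_identical(md@keywords[["$TOT"]], "10")
  expect_identical(md@keywords[["$PAR"]], "2")
  expect_identical(md@datatype, "float32")

  empty <- EventTable(matrix(numeric(0), 0, 3), c("x", "y", "z"))
  p0 <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(empty, p0)
  rt <- readFCS(p0)
  expect_identical(nrow(eventValues(rt$table)), 0L)
  expect_identical(channels(rt$table), c("x", "y", "z"))
})

test_that("a truncated DATA segment is an integrity error", {
  et <- EventTable(matrix(rnorm(500), 100, 5), paste0("c", 1:5))
  p <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(et, p)
  full <- readBin(p, "raw", file.size(p))
  # keep the header/TEXT but only half the declared events
  truncated <- full[seq_len(length(full) - 50 * 5 * 4)]
  p2 <- withr::local_tempfile(fileext = ".fcs")
  writeBin(truncated, p2)
  expect_error(readFCS(p2), class = "cg_integrity_error")
})

test_that("unsupported formats name the offending keyword", {
  p <- withr::local_tempfile(fileext = ".fcs")
  kw <- baseKeywords(1, 0, "F", "1,2,3,4", 32)
  kw[["$MODE"]] <- "C"
  writeRawFCS(p, kw)
  expect_error(readFCS(p), "\\$MODE", class = "cg_unsupported_format")

  kw <- baseKeywords(1, 0, "A", "1,2,3,4", 32)
  writeRawFCS(p, kw)
  expect_error(readFCS(p), "\\$DATATYPE", class = "cg_unsupported_format")

  con <- file(p, "wb"); writeChar("FCS9.9    ", con, eos = NULL)
  writeChar(sprintf("%48s", ""), con, eos = NULL); close(con)
  expect_error(readFCS(p), class = "cg_unsupported_format")
})

test_that("integer data decode matches hand-packed bytes", {
  # 16-bit little-endian, one channel, values {0, 65535, 258}
  p <- withr::local_tempfile(fileext = ".fcs")
  writeRawFCS(p, baseKeywords(1, 3, "I", "1,2,3,4", 16),
              as.raw(c(0x00, 0x00, 0xFF, 0xFF, 0x02, 0x01)))
  expect_identical(as.vector(eventValues(readFCS(p)$table)),
                   c(0, 65535, 258))

  # big-endian 16-bit: same bytes read the other way round
  writeRawFCS(p, baseKeywords(1, 2, "I", "4,3,2,1", 16),
              as.raw(c(0x01, 0x02, 0xFF, 0x00)))
  expect_identical(as.vector(eventValues(readFCS(p)$table)), c(258, 65280))

  # mixed widths: 8-bit then 16-bit channel, event-interleaved
  writeRawFCS(p, baseKeywords(2, 2, "I", "1,2,3,4", c(8, 16)),
              as.raw(c(0x07, 0x02, 0x01, 0xFF, 0x10, 0x00)))
  m <- eventValues(readFCS(p)$table)
  expect_identical(m[1, ], c(ch1 = 7, ch2 = 258))
  expect_identical(m[2, ], c(ch1 = 255, ch2 = 16))

  # 32-bit unsigned survives values beyond the signed range
  writeRawFCS(p, baseKeywords(1, 1, "I", "1,2,3,4", 32),
              as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)))
  expect_identical(as.vector(eventValues(readFCS(p)$table)), 2^32 - 1)
})

test_that("spillover keyword parsing matches a hand parse", {
  md <- FCSMetadata(c("FL1", "FL2"), 0,
                    keywords = list("$SPILLOVER" = "2,FL1,FL2,1,0.1,0.05,1"))
  sp <- extractSpillover(md)
  expect_identical(channels(sp), c("FL1", "FL2"))
  expect_equal(sp@coefficients,
               matrix(c(1, 0.05, 0.1, 1), 2, 2,
                      dimnames = list(c("FL1", "FL2"), c("FL1", "FL2"))))

  # no keyword at all -> absent
  expect_null(extractSpillover(FCSMetadata("a", 0)))

  # identity matrix stays the identity
  sp2 <- extractSpillover(FCSMetadata(c("A", "B"), 0,
                                      keywords = list(SPILL = "2,A,B,1,0,0,1")))
  expect_equal(unname(sp2@coefficients), diag(2))

  # rows are rescaled so the diagonal is one
  sp3 <- extractSpillover(FCSMetadata(c("A", "B"), 0,
                                      keywords = list("$COMP" = "2,A,B,2,0.4,0.1,4")))
  expect_equal(unname(sp3@coefficients),
               matrix(c(1, 0.025, 0.2, 1), 2, 2))

  expect_error(parseSpilloverKeyword_ <- extractSpillover(
    FCSMetadata("a", 0, keywords = list("$SPILLOVER" = "2,A,B,1,0,0"))),
    class = "cg_parse_error")
  expect_error(extractSpillover(
    FCSMetadata("a", 0, keywords = list("$SPILLOVER" = "2,A,B,1,x,0,1"))),
    class = "cg_parse_error")
})

test_that("serialize/extract is the identity on well-formed matrices", {
  sp <- SpilloverMatrix(matrix(c(1, 0.06, 0.03,
                                 0.05, 1, 0.04,
                                 0.02, 0.05, 1), 3, 3, byrow = TRUE),
                        c("X", "Y", "Z"), normalize = FALSE)
  md <- FCSMetadata("a", 0, keywords = list("$SPILLOVER" = serializeSpillover(sp)))
  back <- extractSpillover(md)
  expect_identical(channels(back), channels(sp))
  expect_equal(back@coefficients, sp@coefficients, tolerance = 1e-12)
})

test_that("compensation inverts a forward mix and leaves other channels alone", {
  sp <- SpilloverMatrix(matrix(c(1, 0.1, 0, 1), 2, 2, byrow = TRUE),
                        c("FL1", "FL2"), normalize = FALSE)
  # forward-mix the known truth by hand: X = Y %*% S
  Y <- matrix(c(100, 50), 1, 2, dimnames = list(NULL, c("FL1", "FL2")))
  X <- Y %*% sp@coefficients
  expect_equal(as.vector(X), c(100, 60))
  tab <- EventTable(cbind(X, Time = 7), c("FL1", "FL2", "Time"))
  comp <- applyCompensation(tab, sp)
  expect_equal(eventValues(comp)[, c("FL1", "FL2")], Y[1, ])
  expect_identical(eventValues(comp)[, "Time"], c(Time = 7))

  # identity spillover is a no-op
  idsp <- SpilloverMatrix(diag(2), c("FL1", "FL2"), normalize = FALSE)
  expect_equal(eventValues(applyCompensation(tab, idsp)), eventValues(tab))

  # random invertible spillovers: relative recovery error below 1e-4
  set.seed(42)
  for (i in 1:25) {
    S <- diag(3)
    S[upper.tri(S) | lower.tri(S)] <- runif(6, 0, 0.15)
    sp3 <- SpilloverMatrix(S, c("a", "b", "c"), normalize = FALSE)
    truth <- matrix(rexp(300, rate = 1e-3), 100, 3,
                    dimnames = list(NULL, c("a", "b", "c")))
    mixed <- EventTable(truth %*% S, c("a", "b", "c"))
    rec <- eventValues(applyCompensation(mixed, sp3))
    expect_lt(max(abs(rec - truth) / pmax(abs(truth), 1)), 1e-4)
  }
})

test_that("compensation rejects bad inputs", {
  tab <- EventTable(matrix(1:4, 2, 2), c("a", "b"))
  spMissing <- SpilloverMatrix(diag(2), c("a", "zz"), normalize = FALSE)
  expect_error(applyCompensation(tab, spMissing), class = "cg_validation_error")
  nearSing <- SpilloverMatrix(matrix(c(1, 1, 1, 1 + 1e-12), 2, 2),
                              c("a", "b"), normalize = FALSE)
  expect_error(applyCompensation(tab, nearSing), class = "cg_numerical_error")
})

test_that("external spillover files are parsed and normalised", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("FL1\tFL2", "2\t0.2", "0.1\t1"), p)
  sp <- readSpilloverFile(p)
  expect_identical(channels(sp), c("FL1", "FL2"))
  expect_equal(unname(sp@coefficients), matrix(c(1, 0.1, 0.1, 1), 2, 2))
  writeLines(c("FL1\tFL2", "1\t0"), p)
  expect_error(readSpilloverFile(p), class = "cg_parse_error")
})
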