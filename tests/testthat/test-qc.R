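makeImages <- function(n, shift = 0, seed = 1, prefix = "s", res = 16) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- makeView(rnorm(2000, shift), rnorm(2000, shift))
    renderGateImage(v, "g", sprintf("%s%03d", prefix, i), resolution = res,
                    xlim = c(-8, 8), ylim = c(-8, 8))
  })
}

test_that("gate images are deterministic histograms on fixed ranges", {
  v <- makeView(rep(2, 100), rep(3, 100))
  im <- renderGateImage(v, "g", "s1", resolution = 8,
                       xlim = c(0, 8), ylim = c(0, 8))
  expect_identical(dim(im@pixels), c(8L, 8L))
  expect_identical(sum(im@pixels > 0), 1L)   # a point mass hits one block
  # one saturated fine bin, block-averaged over the 8x8 oversampling window
  expect_equal(im@pixels[2, 3], 1 / 64)

  set.seed(12)
  v2 <- makeView(rnorm(5000), rnorm(5000))
  im1 <- renderGateImage(v2, "g", "s", 16, c(-4, 4), c(-4, 4))
  im2 <- renderGateImage(v2, "g", "s", 16, c(-4, 4), c(-4, 4))
  expect_identical(im1@pixels, im2@pixels)

  expect_warning(im0 <- renderGateImage(makeView(numeric(), numeric()),
                                        "g", "s", 8),
                 class = "cg_empty_view")
  expect_identical(sum(im0@pixels), 0)
  expect_error(renderGateImage(v, "g", "s", resolution = 4),
               class = "cg_validation_error")
})

test_that("a uniform cloud renders near-uniform blocks", {
  set.seed(14)
  n <- 128000
  v <- makeView(runif(n), runif(n))
  im <- renderGateImage(v, "g", "s", resolution = 8, xlim = c(0, 1),
                        ylim = c(0, 1), oversample = 1)
  # per-block counts are n/64 +- multinomial noise; after log1p + max
  # normalisation a 3-SE count spread maps to under ~2% of the scale
  counts <- n / 64
  spread3se <- 2 * 3 * sqrt(counts * (1 - 1 / 64)) / counts / log1p(counts)
  expect_lt(max(im@pixels) - min(im@pixels), spread3se)
})

test_that("image clustering flags shifted samples and ignores homogeneity", {
  # 40 from one generator, 4 from clearly different ones
  normals <- makeImages(40, 0, seed = 31)
  odd <- c(makeImages(1, 5, seed = 32, prefix = "odd_a"),
           makeImages(1, -5, seed = 33, prefix = "odd_b"),
           makeImages(1, 3.5, seed = 34, prefix = "odd_c"),
           makeImages(1, -3.5, seed = 35, prefix = "odd_d"))
  cl <- clusterQCImages(c(normals, odd), seed = 1)
  oddIds <- vapply(odd, function(im) im@sampleId, "")
  expect_gte(length(intersect(cl$flagged, oddIds)), 3)

  # identical images: one cluster, nothing flagged
  one <- renderGateImage(makeView(rep(1, 50), rep(1, 50)), "g", "x", 8,
                         c(0, 2), c(0, 2))
  same <- lapply(1:40, function(i) QCImage(sprintf("t%02d", i), "g", one@pixels))
  cl2 <- clusterQCImages(same, seed = 1)
  expect_identical(unname(unique(cl2$labels)), 1L)
  expect_length(cl2$flagged, 0)
})

test_that("image clustering is invariant to input order", {
  imgs <- c(makeImages(20, 0, seed = 41), makeImages(2, 4, seed = 42, prefix = "z"))
  cl1 <- clusterQCImages(imgs, seed = 3)
  set.seed(44)
  cl2 <- clusterQCImages(sample(imgs), seed = 3)
  expect_identical(cl1$flagged, cl2$flagged)
  expect_identical(cl1$labels, cl2$labels)
  expect_error(clusterQCImages(imgs[1:3], k = 2), class = "cg_validation_error")
})

test_that("percentile outliers flag exactly the extreme order statistics", {
  stats <- data.frame(sample_id = sprintf("s%03d", 1:100),
                      stat = (1:100) / 100)
  fl <- percentileOutliers(stats, 0.01, 0.99)
  expect_identical(sort(fl$sample_id), c("s001", "s100"))
  expect_identical(fl$reason[fl$sample_id == "s001"], "low_percentile")
  expect_identical(fl$reason[fl$sample_id == "s100"], "high_percentile")

  # constant statistics flag nothing (strict inequalities)
  expect_identical(nrow(percentileOutliers(
    data.frame(sample_id = letters[1:10], stat = rep(1, 10)))), 0L)

  # missing values are never flagged
  withNA <- data.frame(sample_id = sprintf("s%02d", 1:99),
                       stat = c(NA, (2:99) / 99))
  fl2 <- percentileOutliers(withNA, 0.01, 0.99)
  expect_false("s01" %in% fl2$sample_id)

  expect_error(percentileOutliers(data.frame()), class = "cg_validation_error")
  expect_error(percentileOutliers(stats, 0.9, 0.1), class = "cg_validation_error")
})

test_that("the merged QC report conserves and merges flags", {
  imgs <- list(gateA = c(makeImages(20, 0, seed = 51),
                         makeImages(1, 6, seed = 52, prefix = "bad_")))
  stats <- data.frame(sample_id = c(sprintf("s%03d", 1:20), "bad_001"),
                      frac = c(seq(0.4, 0.6, length.out = 20), 0.01))
  out <- withr::local_tempdir()
  rep <- buildQCReport(imgs, stats, outputDir = out)
  # the doubly guilty sample carries one row per reason
  badRows <- rep@flags[rep@flags$sample_id == "bad_001", ]
  expect_setequal(badRows$reason, c("image_outlier", "low_percentile"))
  # conservation: report rows equal the sum of upstream flags
  po <- percentileOutliers(stats)
  ic <- clusterQCImages(imgs$gateA, seed = 1)
  expect_identical(nrow(rep@flags), nrow(po) + length(ic$flagged))
  expect_identical(sum(rep@summary$n), nrow(rep@flags))
  expect_true(file.exists(file.path(out, "flags.tsv")))
  expect_true(file.exists(file.path(out, "contact_gateA.png")))

  # no flags at all: empty table, contact sheets still emitted
  imgsSame <- list(g = lapply(1:10, function(i)
    QCImage(sprintf("c%02d", i), "g", matrix(0.5, 8, 8))))
  out2 <- withr::local_tempdir()
  rep2 <- buildQCReport(imgsSame, stats = NULL, outputDir = out2)
  expect_identical(nrow(rep2@flags), 0L)
  expect_true(file.exists(file.path(out2, "contact_g.png")))
})
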