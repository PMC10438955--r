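test_that("valley thresholds land between the two main modes", {
  set.seed(101)
  # equal mixture: symmetry puts the analytic valley at 5.0
  x <- c(rnorm(2500), rnorm(2500, 10))
  thr <- valleyThreshold(makeView(x))
  expect_gt(thr, 4.5); expect_lt(thr, 5.5)

  # unequal weights: fine-grid minimisation of the analytic density
  # 0.9 N(0,1) + 0.1 N(10,1) puts the valley at 5.2289
  set.seed(102)
  x2 <- c(rnorm(4500), rnorm(500, 10))
  thr2 <- valleyThreshold(makeView(x2))
  expect_gt(thr2, 3.5); expect_lt(thr2, 6.5)

  # a single mode has no valley
  set.seed(103)
  expect_error(valleyThreshold(makeView(rnorm(1000))), class = "cg_no_valley")
  expect_error(valleyThreshold(makeView(1)), class = "cg_validation_error")
})

test_that("valley search respects an explicit interval and bandwidth", {
  set.seed(104)
  x <- c(rnorm(3000), rnorm(3000, 6), rnorm(3000, 12))
  thrRight <- valleyThreshold(makeView(x), searchInterval = c(3, 15))
  expect_gt(thrRight, 7); expect_lt(thrRight, 11)
  # an over-smoothed bandwidth merges the modes into one: no valley
  expect_error(valleyThreshold(makeView(x), bandwidth = 10),
               class = "cg_no_valley")
})

test_that("the shortest-path dynamic program equals exhaustive enumeration", {
  # a hand-set grid with a unique cheap corridor
  costs <- matrix(5, 6, 6)
  corridor <- c(2, 2, 3, 4, 4, 3)
  for (x in 1:6) costs[x, corridor[x]] <- 0.1
  sp <- gridShortestPath(costs, directionPenalty = 0.01)
  expect_identical(sp$path, as.integer(corridor))
  expect_equal(sp$cost, enumBestPathCost(costs, 0.01), tolerance = 1e-12)

  set.seed(55)
  for (i in 1:40) {
    nx <- sample(4:7, 1); ny <- sample(4:7, 1)
    costs <- matrix(runif(nx * ny), nx, ny)
    penalty <- sample(c(0, 0.2, 1), 1)
    sp <- gridShortestPath(costs, penalty)
    expect_equal(sp$cost, enumBestPathCost(costs, penalty), tolerance = 1e-12)
  }
})

test_that("path ties break toward the lowest row", {
  flat <- matrix(1, 5, 6)
  expect_identical(gridShortestPath(flat, 0)$path, rep(1L, 5))
  expect_identical(gridShortestPath(flat, 0.5)$path, rep(1L, 5))
})

test_that("shortest-path gating separates two bands and recovers labels", {
  cloud <- twoBandCloud(10000, sep = 10, seed = 77)
  v <- makeView(cloud$x, cloud$y)
  sp <- shortestPathGate(v, names = c("up", "down"), bins = c(64, 64))
  # the boundary stays between the bands for every x bin
  yc <- min(cloud$y) + (sp$path[, "y_bin"] - 0.5) / 64 * diff(range(cloud$y))
  expect_true(all(yc > 3 & yc < 7))
  agree <- mean((seq_along(cloud$x) %in% sp$upper@indices) == (cloud$labels == 1L))
  expect_gte(agree, 0.99)
  expect_identical(sort(c(sp$upper@indices, sp$lower@indices)), 1:10000)
  expect_error(shortestPathGate(v, bins = c(3, 10)), class = "cg_validation_error")
})

test_that("gmm gates recover mixture components and are seed-reproducible", {
  set.seed(61)
  x <- c(rnorm(2000), rnorm(2000, 8))
  v <- makeView(x)
  g <- gmmGate(v, "hi", nComponents = 2, select = "by_mean_rank", rank = 2,
               sigma = 2, seed = 9)
  expect_gt(attr(g, "mean"), 7.8); expect_lt(attr(g, "mean"), 8.2)
  # expected capture: w * P(|Z| <= 2) with w = 1/2
  frac <- length(g@indices) / 4000
  expected <- 0.5 * (pnorm(2) - pnorm(-2))
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_lt(abs(frac - expected), 3 * se)

  g2 <- gmmGate(v, "hi", nComponents = 2, select = "by_mean_rank", rank = 2,
                sigma = 2, seed = 9)
  expect_identical(g@indices, g2@indices)

  # one component with a huge region is the whole parent
  gAll <- gmmGate(v, "all", nComponents = 1, sigma = 50, seed = 1)
  expect_identical(gAll@indices, 1:4000)

  expect_error(gmmGate(makeView(rnorm(15)), "x", nComponents = 2),
               class = "cg_validation_error")
  expect_error(gmmGate(v, "x", nComponents = 2, rank = 3),
               class = "cg_validation_error")
})

test_that("2D gmm gates select by weight and cover their component", {
  set.seed(62)
  n1 <- 3000; n2 <- 1000
  pts <- rbind(cbind(rnorm(n1), rnorm(n1)),
               cbind(rnorm(n2, 8), rnorm(n2, 8)))
  v <- makeView(pts[, 1], pts[, 2])
  g <- gmmGate(v, "big", nComponents = 2, select = "by_weight_rank", rank = 1,
               sigma = 3, seed = 4)
  expect_gt(attr(g, "weight"), 0.5)
  expect_lt(sum(attr(g, "mean")^2), 1)  # the origin component
  inBig <- g@indices <= n1
  expect_gt(mean(inBig), 0.99)
})

test_that("pca ellipse gates hit nominal coverage and principal angles", {
  set.seed(71)
  n <- 20000
  x <- rnorm(n, sd = 2); y <- rnorm(n, sd = 2)
  v <- makeView(x, y)
  g <- pcaEllipseGate(v, "cov", coverage = 0.9)
  frac <- length(g@indices) / n
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(frac - 0.9), 3 * se)
  # isotropic cloud: the ellipse is a circle within sampling error
  lens <- attr(g, "lengths")
  expect_gt(lens[1] / lens[2], 0.95 / 1.05)
  expect_lt(lens[1] / lens[2], 1.05 / 0.95)

  # a cloud rotated by 30 degrees has its principal angle at 30 degrees
  set.seed(72)
  a <- rnorm(n, sd = 3); b <- rnorm(n, sd = 0.5)
  th <- pi / 6
  vr <- makeView(cos(th) * a - sin(th) * b, sin(th) * a + cos(th) * b)
  gr <- pcaEllipseGate(vr, "rot", coverage = 0.9)
  ang <- attr(gr, "angle") %% pi
  expect_lt(abs(ang - th) * 180 / pi, 2)

  # robust estimation shrugs off stray events
  set.seed(73)
  xs <- c(rnorm(5000), rep(500, 5)); ys <- c(rnorm(5000), rep(500, 5))
  gRob <- pcaEllipseGate(makeView(xs, ys), "rob", coverage = 0.9, robust = TRUE)
  expect_lt(max(attr(gRob, "lengths")), 10)

  expect_error(pcaEllipseGate(makeView(rep(1, 50), rnorm(50)), "x"),
               class = "cg_degenerate_geometry")
  expect_error(pcaEllipseGate(makeView(rnorm(5), rnorm(5)), "x"),
               class = "cg_validation_error")
})

test_that("every primitive returns a subset of its parent view", {
  set.seed(81)
  for (i in 1:30) {
    n <- 300
    v1 <- makeView(rnorm(n))
    v2 <- makeView(rnorm(n), rnorm(n))
    gates <- list(
      thresholdGate(v1, "t", rnorm(1), sample(c("above", "below"), 1)),
      polygonGate(v2, "p", rbind(c(-1, -1), c(1, -1), c(0, 1.5))),
      ellipseGate(v2, "e", rnorm(2), runif(2, 0.5, 2), runif(1, 0, pi))
    )
    gates <- c(gates, quadrantGate(v2, paste0("q", 1:4), rnorm(1), rnorm(1)))
    for (g in gates) {
      expect_true(all(g@indices %in% 1:n))
      expect_false(is.unsorted(g@indices, strictly = TRUE))
    }
  }
})
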