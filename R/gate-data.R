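# Data-driven gating primitives: KDE valley thresholds, shortest-path valley
# separation on a density grid, Gaussian-mixture gates, PCA ellipse gates.

# Mclust resolves mclustBIC in the calling frame, so it must be visible in
# this namespace.
#' @importFrom mclust Mclust mclustBIC emControl priorControl
NULL

#' Density-valley threshold on a 1D view
#'
#' Estimates a Gaussian kernel density on a 512-point grid spanning the view
#' range (or `searchInterval` when given) and returns the grid position of
#' the minimum density between the two highest local maxima. Maxima must be
#' genuinely distinct: a peak is discarded unless the density dips by at
#' least 10% of the lower peak between it and every stronger peak, so KDE
#' wiggles on one mode's summit never count as two modes. Bandwidth defaults
#' to Silverman's rule of thumb; bandwidth dominates valley placement, so
#' strategies should set it explicitly where it matters.
#'
#' @param view A 1D [GatingView-class] with >= 2 events.
#' @param bandwidth Kernel bandwidth on the view scale, or `NULL` for
#'   Silverman's rule.
#' @param searchInterval Optional `c(lo, hi)` restricting the density grid.
#' @return The threshold value (a density-grid position).
#' @section Errors: a density with fewer than two interior maxima raises a
#'   `cg_no_valley` error; callers typically fall back to
#'   [quantileThreshold()] or a fixed threshold.
#' @export
valleyThreshold <- function(view, bandwidth = NULL, searchInterval = NULL) {
  stopifnot(is(view, "GatingView"), ncol(view@values) == 1)
  x <- view@values[, 1]
  if (length(x) < 2)
    cgStop("cg_validation_error", "valleyThreshold needs at least 2 events")
  lim <- range(x)
  if (!is.null(searchInterval)) {
    lim <- c(max(lim[1], min(searchInterval)), min(lim[2], max(searchInterval)))
    if (lim[1] >= lim[2])
      cgStop("cg_validation_error", "searchInterval excludes all data")
  }
  bw <- bandwidth %||% stats::bw.nrd0(x)
  d <- stats::density(x, bw = bw, n = 512, from = lim[1], to = lim[2])
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  if (length(peaks) > 1) {
    # prominence filter: KDE wiggles put sibling "maxima" on one mode's
    # summit; a peak only counts if the density dips by >= 10% of the lower
    # peak on the way to every stronger accepted peak
    ord <- peaks[order(d$y[peaks], decreasing = TRUE)]
    accepted <- ord[1]
    for (p in ord[-1]) {
      distinct <- TRUE
      for (a in accepted) {
        dip <- min(d$y[min(p, a):max(p, a)])
        if (dip > 0.9 * min(d$y[p], d$y[a])) { distinct <- FALSE; break }
      }
      if (distinct) accepted <- c(accepted, p)
    }
    peaks <- sort(accepted)
  }
  if (length(peaks) < 2)
    cgStop("cg_no_valley",
           "density has %d local maximum/a; no valley to split at", length(peaks))
  top2 <- sort(peaks[order(d$y[peaks], decreasing = TRUE)][1:2])
  between <- top2[1]:top2[2]
  d$x[between[which.min(d$y[between])]]
}

# ---------------------------------------------------------------------------
# density grids and the shortest-path dynamic program

# 2D histogram: rows = x bins, cols = y bins; out-of-range values are clamped
# into the edge bins so the count total is preserved.
binCounts2D <- function(x, y, nx, ny, xlim, ylim) {
  ix <- pmin(pmax(ceiling((x - xlim[1]) / diff(xlim) * nx), 1L), nx)
  iy <- pmin(pmax(ceiling((y - ylim[1]) / diff(ylim) * ny), 1L), ny)
  counts <- matrix(tabulate((iy - 1L) * nx + ix, nbins = nx * ny), nx, ny)
  counts
}

binCenters <- function(lim, n) lim[1] + (seq_len(n) - 0.5) / n * diff(lim)

# separable Gaussian smoothing with edge renormalisation
gaussSmooth2D <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(mat) {  # along rows (first dimension)
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    wt <- numeric(n)
    for (o in -r:r) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + k[o + r + 1] * mat[src, , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(m))))
}

#' Minimum-cost x-monotone path across a cost grid
#'
#' Dynamic program over paths that start in any row of the left edge, end in
#' any row of the right edge, and step from column `x` to `x + 1` changing
#' the row by at most 1. A path's cost is the sum of the entered bins' costs
#' plus `directionPenalty * |delta row|` per step. Ties are broken toward the
#' lower row at every step, so the result is platform-stable.
#'
#' @param costs Numeric matrix; rows are x bins (path direction), columns are
#'   y bins (rows of the grid in the path sense).
#' @param directionPenalty Nonnegative per-step penalty on vertical movement.
#' @return A list with `path` (integer y-bin per x-bin) and `cost`.
#' @export
gridShortestPath <- function(costs, directionPenalty = 0) {
  nx <- nrow(costs); ny <- ncol(costs)
  if (nx < 1 || ny < 1) cgStop("cg_validation_error", "empty cost grid")
  dp <- matrix(Inf, nx, ny)
  ptr <- matrix(0L, nx, ny)
  dp[1, ] <- costs[1, ]
  for (x in seq_len(nx)[-1]) {
    for (y in seq_len(ny)) {
      best <- Inf; bestPrev <- 0L
      for (py in (y - 1):(y + 1)) {        # low predecessor first: tie-break
        if (py < 1 || py > ny) next
        cand <- dp[x - 1, py] + costs[x, y] + directionPenalty * abs(y - py)
        if (cand < best) { best <- cand; bestPrev <- py }
      }
      dp[x, y] <- best
      ptr[x, y] <- bestPrev
    }
  }
  endY <- which.min(dp[nx, ])              # which.min takes the lowest on ties
  path <- integer(nx)
  path[nx] <- endY
  if (nx > 1) for (x in nx:2) path[x - 1] <- ptr[x, path[x]]
  list(path = path, cost = dp[nx, endY])
}

#' Shortest-path valley gate on a 2D view
#'
#' Separates two populations stacked along y by tracing the lowest-density
#' x-monotone path across a (optionally Gaussian-smoothed) 2D histogram of
#' the view, from the left edge to the right edge. The dynamic program is
#' the one of [gridShortestPath()]. To keep the path between the
#' populations rather than in the empty margins, the search rows are
#' restricted to the band between the two strongest modes of the y-marginal
#' density (full range when the marginal is unimodal). The path is converted
#' to a piecewise-linear boundary at bin centres; events strictly above the
#' boundary form the upper gate, all others the lower gate.
#'
#' @param view A 2D [GatingView-class].
#' @param names Gate names `c(upper, lower)`.
#' @param bins `c(nx, ny)` histogram bins, each >= 4. Default `c(256, 256)`.
#' @param smoothingSigma Gaussian smoothing of the counts, in bins. Default 1.
#' @param directionPenalty Per-step penalty on vertical movement, in
#'   events-per-bin units. Default 0.1.
#' @param startEdge Edge the path starts from; only `"left"` is defined.
#' @return A list with [GateResult-class] elements `upper` and `lower`, and
#'   `path`, a two-column matrix of (x bin, y bin) grid positions.
#' @export
shortestPathGate <- function(view, names = c("upper", "lower"),
                             bins = c(256, 256), smoothingSigma = 1,
                             directionPenalty = 0.1, startEdge = "left") {
  stopifnot(is(view, "GatingView"), ncol(view@values) == 2)
  startEdge <- match.arg(startEdge, "left")
  bins <- asCount(bins, "bins")
  if (length(bins) != 2 || any(bins < 4))
    cgStop("cg_validation_error", "bins must be two integers >= 4")
  if (length(names) != 2)
    cgStop("cg_validation_error", "shortestPathGate needs two gate names")
  x <- view@values[, 1]; y <- view@values[, 2]
  xlim <- range(x); ylim <- range(y)
  if (diff(xlim) == 0) xlim <- xlim + c(-0.5, 0.5)
  if (diff(ylim) == 0) ylim <- ylim + c(-0.5, 0.5)
  nx <- bins[1]; ny <- bins[2]
  counts <- binCounts2D(x, y, nx, ny, xlim, ylim)
  dens <- gaussSmooth2D(counts, smoothingSigma)
  yc <- binCenters(ylim, ny)

  # restrict rows to the inter-mode band of the y marginal
  rows <- seq_len(ny)
  dy <- stats::density(y, n = 512)
  pk <- which(diff(sign(diff(dy$y))) == -2) + 1
  if (length(pk) >= 2) {
    top2 <- sort(dy$x[pk[order(dy$y[pk], decreasing = TRUE)][1:2]])
    band <- which(yc > top2[1] & yc < top2[2])
    if (length(band) >= 2) rows <- band
  }

  sp <- gridShortestPath(dens[, rows, drop = FALSE], directionPenalty)
  pathRows <- rows[sp$path]
  boundary <- stats::approx(binCenters(xlim, nx), yc[pathRows],
                            xout = x, rule = 2)$y
  upperSel <- y > boundary
  list(upper = viewGate(view, names[1], upperSel, "shortest_path"),
       lower = viewGate(view, names[2], !upperSel, "shortest_path"),
       path = cbind(x_bin = seq_len(nx), y_bin = pathRows))
}

# ---------------------------------------------------------------------------

#' Gaussian-mixture-model gate
#'
#' Fits a Gaussian mixture to the view (EM, deterministic under `seed`;
#' large views use a seeded subset for initialisation), selects one
#' component by mean rank or weight rank, and gates the interval
#' (1D: mean +/- `sigma` standard deviations) or covariance ellipse
#' (2D: Mahalanobis radius `sigma`) of that component.
#'
#' @param view A 1D or 2D [GatingView-class] with at least
#'   `10 * nComponents` events.
#' @param name Gate name.
#' @param nComponents Number of mixture components.
#' @param select `"by_mean_rank"` (components ordered by ascending mean on
#'   the first view channel) or `"by_weight_rank"` (descending mixing
#'   weight).
#' @param rank Rank of the component to select, 1-based.
#' @param sigma Region half-width in standard deviations. Default 2.
#' @param seed Integer seed; the same seed always yields the same gate.
#' @return A [GateResult-class] with the fitted component's parameters
#'   attached as attributes `mean`, `cov` and `weight`.
#' @export
gmmGate <- function(view, name, nComponents, select = c("by_mean_rank", "by_weight_rank"),
                    rank = 1, sigma = 2, seed = 1) {
  select <- match.arg(select)
  stopifnot(is(view, "GatingView"))
  d <- ncol(view@values)
  n <- nrow(view@values)
  if (n < 10 * nComponents)
    cgStop("cg_validation_error",
           "gmmGate needs at least 10 * nComponents events (have %d)", n)
  if (rank < 1 || rank > nComponents)
    cgStop("cg_validation_error", "rank must lie in 1..nComponents")
  dat <- if (d == 1) view@values[, 1] else view@values

  fit <- withLocalSeed(seed, {
    init <- if (n > 2000) list(subset = sample.int(n, 2000)) else NULL
    ctl <- mclust::emControl(tol = 1e-6, itmax = 500)
    f <- tryCatch(
      mclust::Mclust(dat, G = nComponents,
                     modelNames = if (d == 1) "V" else "VVV",
                     initialization = init, control = ctl, verbose = FALSE),
      error = function(e) NULL)
    if (is.null(f))  # degenerate covariances: refit with a regularising prior
      f <- tryCatch(
        mclust::Mclust(dat, G = nComponents,
                       modelNames = if (d == 1) "V" else "VVV",
                       prior = mclust::priorControl(scale = 1e-6),
                       initialization = init, control = ctl, verbose = FALSE),
        error = function(e) NULL)
    f
  })
  if (is.null(fit))
    cgStop("cg_fit_error", "mixture fit failed for gate '%s'", name)

  weights <- fit$parameters$pro
  if (d == 1) {
    means <- as.numeric(fit$parameters$mean)
    vars <- pmax(fit$parameters$variance$sigmasq, 1e-6)
    if (length(vars) == 1) vars <- rep(vars, nComponents)
  } else {
    means <- fit$parameters$mean  # d x G
    sig <- fit$parameters$variance$sigma  # d x d x G
  }
  ord <- if (select == "by_mean_rank") {
    if (d == 1) order(means) else order(means[1, ])
  } else order(weights, decreasing = TRUE)
  comp <- ord[rank]

  if (d == 1) {
    mu <- means[comp]; sd <- sqrt(vars[comp])
    keep <- abs(view@values[, 1] - mu) <= sigma * sd
    covOut <- matrix(vars[comp])
  } else {
    mu <- means[, comp]
    S <- sig[, , comp] + diag(1e-6 * max(diag(sig[, , comp]), 1e-12), d)
    delta <- sweep(view@values, 2, mu)
    md2 <- rowSums((delta %*% solve(S)) * delta)
    keep <- md2 <= sigma^2
    covOut <- S
  }
  g <- viewGate(view, name, keep, "gmm")
  attr(g, "mean") <- mu
  attr(g, "cov") <- covOut
  attr(g, "weight") <- weights[comp]
  g
}

#' Principal-component ellipse gate
#'
#' Gates the ellipse aligned to the principal axes of the view covariance,
#' scaled so that under a bivariate normal assumption the chi-square(2)
#' quantile at `coverage` is enclosed. With `robust = TRUE` the centre and
#' covariance are computed on the per-axis 10-90 percentile trimmed subset,
#' making the axes insensitive to stray events.
#'
#' @param view A 2D [GatingView-class] with >= 10 events.
#' @param name Gate name.
#' @param coverage Target coverage fraction in (0, 1). Default 0.9.
#' @param robust Trim each axis to its 10-90 percentile band before
#'   estimating the axes. Default `FALSE`.
#' @return A [GateResult-class] with attributes `center`, `axes`
#'   (eigenvectors in columns), `lengths` (semi-axis lengths) and `angle`.
#' @export
pcaEllipseGate <- function(view, name, coverage = 0.9, robust = FALSE) {
  stopifnot(is(view, "GatingView"), ncol(view@values) == 2)
  if (coverage <= 0 || coverage >= 1)
    cgStop("cg_validation_error", "coverage must lie strictly inside (0, 1)")
  if (nrow(view@values) < 10)
    cgStop("cg_validation_error", "pcaEllipseGate needs at least 10 events")
  est <- view@values
  if (robust) {
    qx <- stats::quantile(est[, 1], c(0.1, 0.9), type = 7)
    qy <- stats::quantile(est[, 2], c(0.1, 0.9), type = 7)
    keep <- est[, 1] >= qx[1] & est[, 1] <= qx[2] &
            est[, 2] >= qy[1] & est[, 2] <= qy[2]
    est <- est[keep, , drop = FALSE]
  }
  ctr <- colMeans(est)
  S <- stats::cov(est)
  if (any(diag(S) <= 0) || det(S) <= 0)
    cgStop("cg_degenerate_geometry", "zero-variance axis; ellipse is degenerate")
  eg <- eigen(S, symmetric = TRUE)
  r2 <- stats::qchisq(coverage, df = 2)
  delta <- sweep(view@values, 2, ctr)
  proj <- delta %*% eg$vectors
  md2 <- proj[, 1]^2 / eg$values[1] + proj[, 2]^2 / eg$values[2]
  g <- viewGate(view, name, md2 <= r2, "pca_ellipse")
  attr(g, "center") <- ctr
  attr(g, "axes") <- eg$vectors
  attr(g, "lengths") <- sqrt(eg$values * r2)
  attr(g, "angle") <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  g
}
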