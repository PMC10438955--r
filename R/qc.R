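# Post-gating quality control: down-sampled gate images, cross-sample image
# clustering, percentile-based statistical outliers, merged reporting.

#' Construct a QC image
#' @param sampleId Sample identifier.
#' @param gateName Gate the image depicts.
#' @param pixels Square numeric matrix in `[0, 1]`.
#' @param normalization Normalisation tag.
#' @return A [QCImage-class].
#' @export
QCImage <- function(sampleId, gateName, pixels, normalization = "log1p_max") {
  new("QCImage", sampleId = sampleId, gateName = gateName,
      pixels = pixels, normalization = normalization)
}

setMethod("show", "QCImage", function(object) {
  cat(sprintf("QCImage %dx%d: sample '%s', gate '%s' (%s)\n",
              nrow(object@pixels), ncol(object@pixels),
              object@sampleId, object@gateName, object@normalization))
})

#' Render a down-sampled QC image of a gate view
#'
#' 2D histogram of the parent view on fixed display-scale ranges, log1p
#' scaled, max-normalised to `[0, 1]`, then block-mean down-sampled to
#' `resolution x resolution`. Fixed ranges (from the channel transforms, or
#' supplied explicitly) make images comparable across samples — the point of
#' QC clustering. Rows index x bins, columns y bins; out-of-range events are
#' clamped into the edge bins.
#'
#' @param view A 2D [GatingView-class].
#' @param gateName Gate name recorded on the image.
#' @param sampleId Sample id recorded on the image.
#' @param resolution Image side length, >= 8. Default 32.
#' @param xlim,ylim Fixed display ranges; default to the view's data range
#'   (with a warning-free fallback) — pass transform [displayRange()]s for
#'   cross-sample comparability.
#' @param oversample Histogram bins per image pixel before block averaging.
#'   Default 8.
#' @return A [QCImage-class].
#' @export
renderGateImage <- function(view, gateName, sampleId, resolution = 32L,
                            xlim = NULL, ylim = NULL, oversample = 8L) {
  stopifnot(is(view, "GatingView"), ncol(view@values) == 2)
  resolution <- asCount(resolution, "resolution")
  if (resolution < 8L)
    cgStop("cg_validation_error", "image resolution must be >= 8")
  K <- resolution * asCount(oversample, "oversample")
  x <- view@values[, 1]; y <- view@values[, 2]
  if (length(x) == 0) {
    cgWarn("cg_empty_view", "empty view for gate '%s' sample '%s'; all-zero image",
           gateName, sampleId)
    return(QCImage(sampleId, gateName,
                   matrix(0, resolution, resolution)))
  }
  if (is.null(xlim)) xlim <- range(x)
  if (is.null(ylim)) ylim <- range(y)
  if (diff(xlim) == 0) xlim <- xlim + c(-0.5, 0.5)
  if (diff(ylim) == 0) ylim <- ylim + c(-0.5, 0.5)
  counts <- binCounts2D(x, y, K, K, xlim, ylim)
  img <- log1p(counts)
  mx <- max(img)
  if (mx > 0) img <- img / mx
  QCImage(sampleId, gateName, blockMean(img, resolution))
}

# block-mean down-sample a K x K matrix to R x R (K a multiple of R)
blockMean <- function(m, R) {
  K <- nrow(m)
  f <- K / R
  stopifnot(f == as.integer(f))
  # average rows then columns via grouping
  rowG <- rep(seq_len(R), each = f)
  m2 <- rowsum(m, rowG) / f
  t(rowsum(t(m2), rowG) / f)
}

#' Cluster QC images of one gate and flag visual outliers
#'
#' Images are flattened to vectors and clustered with k-means under a fixed
#' seed; with `k = "auto"` the k in 2..6 with the highest mean silhouette
#' width is used. Samples are flagged `image_outlier` when they fall in a
#' cluster smaller than `max(2, 5%)` of samples, when their cluster's
#' centroid lies farther from the dominant cluster's centroid than three
#' times the dominant cluster's RMS radius (a minority subset with a
#' substantially different visual aspect), or when they lie farther from
#' their own centroid than the 99th percentile of within-cluster distances.
#' Input order never matters: images are canonicalised by sample id.
#'
#' @param images List of [QCImage-class] for one gate (>= 2 * k).
#' @param k Number of clusters, or `"auto"`.
#' @param seed Integer seed for k-means.
#' @return A list with `labels` (named integer cluster per sample, in sorted
#'   sample-id order), `flagged` (character sample ids) and `k`.
#' @export
clusterQCImages <- function(images, k = "auto", seed = 1) {
  ids <- vapply(images, function(im) im@sampleId, "")
  ord <- order(ids, method = "radix")
  images <- images[ord]; ids <- ids[ord]
  n <- length(images)
  X <- do.call(rbind, lapply(images, function(im) as.vector(im@pixels)))
  auto <- identical(k, "auto")
  if (!auto) {
    k <- asCount(k, "k")
    if (n < 2 * k)
      cgStop("cg_validation_error", "need at least 2*k images (have %d, k=%d)", n, k)
  }
  nDistinct <- nrow(unique(X))
  if (nDistinct < 2) {  # homogeneous batch: one cluster, nothing to flag
    labels <- rep(1L, n); names(labels) <- ids
    return(list(labels = labels, flagged = character(), k = 1L))
  }

  fitK <- function(kk) withLocalSeed(seed, stats::kmeans(X, centers = kk,
                                                         nstart = 10,
                                                         iter.max = 100))
  if (auto) {
    kMax <- min(6, nDistinct, floor(n / 2))
    if (kMax < 2) {  # too few images to cluster: one cluster, no flags
      labels <- rep(1L, n); names(labels) <- ids
      return(list(labels = labels, flagged = character(), k = 1L))
    }
    ks <- 2:kMax
    dX <- stats::dist(X)
    best <- NULL; bestSil <- -Inf; bestK <- ks[1]
    for (kk in ks) {
      cl <- fitK(kk)
      sil <- mean(cluster::silhouette(cl$cluster, dX)[, "sil_width"])
      if (sil > bestSil + 1e-12) { bestSil <- sil; best <- cl; bestK <- kk }
    }
    cl <- best; k <- bestK
  } else {
    if (k > nDistinct)
      cgStop("cg_validation_error", "k exceeds the number of distinct images")
    cl <- fitK(k)
  }

  labels <- cl$cluster; names(labels) <- ids
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < max(2, 0.05 * n)])
  dists <- sqrt(rowSums((X - cl$centers[labels, , drop = FALSE])^2))
  farCut <- stats::quantile(dists, 0.99, type = 7)
  # minority clusters with a substantially different visual aspect: centroid
  # farther from the dominant cluster than 3x its RMS within-cluster radius
  dom <- as.integer(names(sizes)[which.max(sizes)])
  domRms <- sqrt(mean(dists[labels == dom]^2))
  separated <- integer()
  for (cid in setdiff(as.integer(names(sizes)), dom)) {
    gap <- sqrt(sum((cl$centers[cid, ] - cl$centers[dom, ])^2))
    if (gap > 3 * max(domRms, 1e-12)) separated <- c(separated, cid)
  }
  flagged <- ids[labels %in% c(small, separated) | dists > farCut]
  list(labels = labels, flagged = unique(flagged), k = k)
}

#' Percentile-based statistical outliers
#'
#' Per statistic, flags samples strictly below the `lowQ` empirical quantile
#' (`low_percentile`) or strictly above the `highQ` quantile
#' (`high_percentile`). Missing values are never flagged; a constant
#' statistic flags nothing.
#'
#' @param stats data.frame with a `sample_id` column and one numeric column
#'   per reported statistic.
#' @param lowQ,highQ Quantiles with `0 <= lowQ < highQ <= 1`. Defaults
#'   0.01 / 0.99.
#' @return data.frame with columns `sample_id`, `statistic`, `reason`,
#'   `value` (zero rows when nothing is flagged).
#' @export
percentileOutliers <- function(stats, lowQ = 0.01, highQ = 0.99) {
  if (!is.data.frame(stats) || nrow(stats) == 0 || !"sample_id" %in% names(stats))
    cgStop("cg_validation_error",
           "stats must be a nonempty data.frame with a sample_id column")
  if (!(lowQ >= 0 && lowQ < highQ && highQ <= 1))
    cgStop("cg_validation_error", "need 0 <= lowQ < highQ <= 1")
  out <- list()
  for (col in setdiff(names(stats), "sample_id")) {
    v <- stats[[col]]
    if (!is.numeric(v)) next
    ok <- !is.na(v)
    if (!any(ok)) next
    qs <- stats::quantile(v[ok], c(lowQ, highQ), type = 7)
    lo <- ok & v < qs[1]
    hi <- ok & v > qs[2]
    if (any(lo))
      out[[length(out) + 1]] <- data.frame(sample_id = stats$sample_id[lo],
                                           statistic = col,
                                           reason = "low_percentile",
                                           value = v[lo],
                                           stringsAsFactors = FALSE)
    if (any(hi))
      out[[length(out) + 1]] <- data.frame(sample_id = stats$sample_id[hi],
                                           statistic = col,
                                           reason = "high_percentile",
                                           value = v[hi],
                                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample_id = character(), statistic = character(),
                      reason = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# tile a list of equally sized images into one contact-sheet matrix
tileImages <- function(images, perRow = NULL) {
  R <- nrow(images[[1]]@pixels)
  n <- length(images)
  if (is.null(perRow)) perRow <- ceiling(sqrt(n))
  rows <- ceiling(n / perRow)
  sheet <- matrix(0, rows * (R + 1) + 1, perRow * (R + 1) + 1)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% perRow
    c <- (i - 1) %% perRow
    sheet[(r * (R + 1) + 2):(r * (R + 1) + R + 1),
          (c * (R + 1) + 2):(c * (R + 1) + R + 1)] <- images[[i]]@pixels
  }
  sheet
}

#' Build the merged quality-control report
#'
#' Combines image-clustering outliers (per gate) with percentile outliers of
#' the reported statistics into one flag table, writes it as
#' `flags.tsv` and emits one PNG contact sheet per gate with flagged samples
#' ordered first. Flags never discard samples — acting on them is the
#' operator's decision.
#'
#' @param images Named list: per gate, a list of [QCImage-class] (one per
#'   sample).
#' @param stats data.frame of reported statistics (see
#'   [percentileOutliers()]); may be `NULL` to skip percentile flags.
#' @param lowQ,highQ Percentile flag quantiles. Defaults 0.01 / 0.99.
#' @param k Cluster count or `"auto"`.
#' @param seed Integer seed.
#' @param outputDir Directory for `flags.tsv` and contact sheets; `NULL`
#'   writes nothing.
#' @return A [QCReport-class].
#' @export
buildQCReport <- function(images, stats = NULL, lowQ = 0.01, highQ = 0.99,
                          k = "auto", seed = 1, outputDir = NULL) {
  flags <- list()
  clusters <- list()
  for (gate in names(images)) {
    cl <- clusterQCImages(images[[gate]], k = k, seed = seed)
    clusters[[gate]] <- cl$labels
    if (length(cl$flagged))
      flags[[length(flags) + 1]] <- data.frame(sample_id = cl$flagged,
                                               gate = gate,
                                               reason = "image_outlier",
                                               value = NA_real_,
                                               stringsAsFactors = FALSE)
  }
  if (!is.null(stats)) {
    po <- percentileOutliers(stats, lowQ, highQ)
    if (nrow(po))
      flags[[length(flags) + 1]] <- data.frame(sample_id = po$sample_id,
                                               gate = po$statistic,
                                               reason = po$reason,
                                               value = po$value,
                                               stringsAsFactors = FALSE)
  }
  flags <- if (length(flags)) do.call(rbind, flags)
           else data.frame(sample_id = character(), gate = character(),
                           reason = character(), value = numeric(),
                           stringsAsFactors = FALSE)
  flags <- flags[order(flags$sample_id, flags$gate, flags$reason,
                       method = "radix"), , drop = FALSE]
  rownames(flags) <- NULL
  summary <- if (nrow(flags))
    stats::aggregate(cbind(n = rep(1L, nrow(flags))) ~ gate + reason,
                     data = flags, FUN = sum)
  else data.frame(gate = character(), reason = character(), n = integer())

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(flags, file.path(outputDir, "flags.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    flaggedIds <- unique(flags$sample_id)
    for (gate in names(images)) {
      imgs <- images[[gate]]
      ids <- vapply(imgs, function(im) im@sampleId, "")
      ord <- order(!(ids %in% flaggedIds), ids, method = "radix")
      sheet <- tileImages(imgs[ord])
      png::writePNG(sheet, file.path(outputDir,
                                     sprintf("contact_%s.png", gate)))
    }
  }
  new("QCReport", flags = flags, clusters = clusters, summary = summary)
}

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d flags over %d gates\n",
              nrow(object@flags), length(object@clusters)))
  if (nrow(object@summary)) print(object@summary)
})
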