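# Static gating shapes: threshold, quadrant, polygon, ellipse.
# All primitives are pure functions from views to GateResults; every result's
# indices are a subset of the view's parent indices.

#' Threshold gate on a 1D view
#'
#' `direction = "above"` keeps events with value strictly greater than the
#' threshold; `"below"` keeps the rest (the boundary belongs to "below"), so
#' the two directions partition the parent exactly.
#'
#' @param view A 1D [GatingView-class].
#' @param name Gate name.
#' @param threshold Finite threshold on the view's (transformed) scale.
#' @param direction `"above"` or `"below"`.
#' @return A [GateResult-class].
#' @export
thresholdGate <- function(view, name, threshold, direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(is(view, "GatingView"), ncol(view@values) == 1)
  if (!is.finite(threshold))
    cgStop("cg_validation_error", "threshold must be finite")
  x <- view@values[, 1]
  keep <- if (direction == "above") x > threshold else x <= threshold
  viewGate(view, name, keep, paste0("threshold_", direction))
}

#' Empirical quantile threshold
#'
#' One member of the threshold-selection family: the empirical quantile of
#' the view values, linearly interpolated between order statistics.
#'
#' @param view A nonempty 1D [GatingView-class].
#' @param q Quantile in (0, 1).
#' @return The threshold value on the view scale.
#' @export
quantileThreshold <- function(view, q) {
  stopifnot(is(view, "GatingView"), ncol(view@values) == 1)
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q <= 0 || q >= 1)
    cgStop("cg_validation_error", "q must lie strictly inside (0, 1)")
  if (nrow(view@values) == 0)
    cgStop("cg_validation_error", "cannot take a quantile of an empty view")
  unname(stats::quantile(view@values[, 1], q, type = 7))
}

#' Quadrant gate on a 2D view
#'
#' Splits the parent into four disjoint populations around the two
#' thresholds; boundary events are assigned to the lower side. Quadrants
#' follow the cytometry convention: Q1 upper-left (x low, y high), Q2
#' upper-right, Q3 lower-left, Q4 lower-right. The four populations
#' partition the parent exactly.
#'
#' @param view A 2D [GatingView-class].
#' @param names Four gate names, in Q1..Q4 order.
#' @param xThreshold,yThreshold Finite thresholds on the view scales.
#' @return Named list of four [GateResult-class] (Q1..Q4).
#' @export
quadrantGate <- function(view, names, xThreshold, yThreshold) {
  stopifnot(is(view, "GatingView"), ncol(view@values) == 2)
  if (length(names) != 4)
    cgStop("cg_validation_error", "quadrantGate needs four gate names (Q1..Q4)")
  if (!is.finite(xThreshold) || !is.finite(yThreshold))
    cgStop("cg_validation_error", "quadrant thresholds must be finite")
  x <- view@values[, 1]; y <- view@values[, 2]
  hiX <- x > xThreshold; hiY <- y > yThreshold
  sel <- list(!hiX & hiY, hiX & hiY, !hiX & !hiY, hiX & !hiY)
  out <- lapply(1:4, function(q) viewGate(view, names[q], sel[[q]], "quadrant"))
  names(out) <- names
  out
}

# orientation sign of the triangle (a, b, c)
orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

segmentsIntersect <- function(p1, p2, p3, p4) {
  d1 <- orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  onSeg <- function(px, py, qx, qy, rx, ry)  # r collinear with p-q, on it?
    min(px, qx) <= rx && rx <= max(px, qx) && min(py, qy) <= ry && ry <= max(py, qy)
  (d1 == 0 && onSeg(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])) ||
  (d2 == 0 && onSeg(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])) ||
  (d3 == 0 && onSeg(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])) ||
  (d4 == 0 && onSeg(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2]))
}

validateSimplePolygon <- function(vertices) {
  n <- nrow(vertices)
  if (n < 3)
    cgStop("cg_validation_error", "a polygon needs at least 3 vertices")
  edges <- lapply(seq_len(n), function(i)
    list(a = vertices[i, ], b = vertices[if (i == n) 1 else i + 1, ]))
  for (i in seq_len(n - 2)) {
    lastJ <- if (i == 1) n - 1 else n  # skip edges adjacent to edge i
    if (i + 2 > lastJ) next
    for (j in (i + 2):lastJ) {
      if (segmentsIntersect(edges[[i]]$a, edges[[i]]$b,
                            edges[[j]]$a, edges[[j]]$b))
        cgStop("cg_geometry_error",
               "polygon is self-intersecting (edges %d and %d)", i, j)
    }
  }
  invisible(TRUE)
}

#' Polygon gate on a 2D view
#'
#' Membership by ray casting with the even-odd rule; points lying exactly on
#' an edge are included. The polygon must be simple (non-self-intersecting);
#' this is validated with a pairwise segment-intersection check.
#'
#' @param view A 2D [GatingView-class].
#' @param name Gate name.
#' @param vertices Numeric matrix (>= 3 x 2) of polygon vertices in order.
#' @return A [GateResult-class].
#' @export
polygonGate <- function(view, name, vertices) {
  stopifnot(is(view, "GatingView"), ncol(view@values) == 2)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || anyNA(vertices))
    cgStop("cg_validation_error", "vertices must be a finite n x 2 matrix")
  validateSimplePolygon(vertices)

  px <- view@values[, 1]; py <- view@values[, 2]
  n <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  onEdge <- rep(FALSE, length(px))
  tol <- 1e-12 * max(1, max(abs(vertices)))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    # exact-edge membership (collinear and within the segment bbox)
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    onEdge <- onEdge | (abs(cross) <= tol &
                        px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
                        py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol)
    # even-odd ray crossing
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  viewGate(view, name, inside | onEdge, "polygon")
}

#' Ellipse gate on a 2D view
#'
#' Membership where the rotated, axis-scaled radius is at most 1; the
#' boundary is included.
#'
#' @param view A 2D [GatingView-class].
#' @param name Gate name.
#' @param center Numeric length-2 ellipse centre.
#' @param semiAxes Numeric length-2 semi-axis lengths (> 0).
#' @param angle Rotation of the first axis, radians counter-clockwise.
#' @return A [GateResult-class].
#' @export
ellipseGate <- function(view, name, center, semiAxes, angle = 0) {
  stopifnot(is(view, "GatingView"), ncol(view@values) == 2)
  if (any(semiAxes <= 0))
    cgStop("cg_validation_error", "semi-axes must be > 0")
  dx <- view@values[, 1] - center[1]
  dy <- view@values[, 2] - center[2]
  u <- cos(angle) * dx + sin(angle) * dy
  v <- -sin(angle) * dx + cos(angle) * dy
  r2 <- (u / semiAxes[1])^2 + (v / semiAxes[2])^2
  viewGate(view, name, r2 <= 1 + 1e-12, "ellipse")
}
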