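# Logicle bi-exponential machinery.
#
# The display scale is parameterised internally on y in [0, 1] covering
# M + A decades; public display units are y * (M + A), so the top of scale
# T maps to M + A display units (= M with the default A = 0). The
# bi-exponential is
#
#   S(y) = a e^{b y} - c e^{-d y} - f          for y >= x1,
#   S(y) = -S(2 x1 - y)                         for y <  x1 (sign mirror),
#
# with coefficients chosen so S(x1) = 0, S(1) = T, and d solving
# 2 (ln d - ln b) + w (d + b) = 0 for the requested linear width.

logicleSolveD <- function(b, w) {
  if (w == 0) return(b)
  g <- function(d) 2 * (log(d) - log(b)) + w * (d + b)
  stats::uniroot(g, lower = b * 1e-12, upper = b, tol = .Machine$double.eps * b)$root
}

#' Construct a Logicle transform
#'
#' Defaults follow the common convention for the bi-exponential scale:
#' `T = 262144`, `M = 4.5`, `W = 0.5`, `A = 0`.
#'
#' @param T Top-of-scale data value (> 0).
#' @param M Total display decades (> 0).
#' @param W Linearisation width in decades (`0 <= W <= M/2`).
#' @param A Additional negative display decades (>= 0).
#' @return A [LogicleTransform-class].
#' @examples
#' lg <- logicleTransform()
#' transformForward(lg, c(0, 100, 262144))
#' @export
logicleTransform <- function(T = 262144, M = 4.5, W = 0.5, A = 0) {
  if (T <= 0 || M <= 0 || W < 0 || W > M / 2 || A < 0)
    cgStop("cg_validation_error",
           "invalid logicle parameters: need T>0, M>0, 0<=W<=M/2, A>=0")
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b <- (M + A) * log(10)
  d <- logicleSolveD(b, w)
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a / exp(d * x1)
  a <- T / (exp(b) - mf_a - c_a / exp(d))
  new("LogicleTransform", T = T, M = M, W = W, A = A,
      a = a, b = b, c = c_a * a, d = d, f = mf_a * a, x1 = x1)
}

# bi-exponential on the internal [0,1] scale, vectorised
logicleBiexp <- function(spec, y) {
  lo <- y < spec@x1
  ym <- ifelse(lo, 2 * spec@x1 - y, y)
  s <- spec@a * exp(spec@b * ym) - spec@c * exp(-spec@d * ym) - spec@f
  ifelse(lo, -s, s)
}

logicleBiexpDeriv <- function(spec, y) {
  ym <- ifelse(y < spec@x1, 2 * spec@x1 - y, y)
  spec@a * spec@b * exp(spec@b * ym) + spec@c * spec@d * exp(-spec@d * ym)
}

#' @rdname transformForward
#' @export
setMethod("transformForward", "LogicleTransform", function(spec, x) {
  if (!length(x)) return(numeric(0))
  bad <- !is.finite(x)
  out <- rep(NA_real_, length(x))
  if (all(bad)) return(out)
  xs <- x[!bad]
  # bracket each value, then vectorised Newton with bisection fallback
  lo <- rep(spec@x1 - 1, length(xs))
  hi <- rep(2, length(xs))
  for (i in 1:60) {
    expand <- logicleBiexp(spec, lo) > xs
    if (!any(expand)) break
    lo[expand] <- lo[expand] - 2^(i / 4)
  }
  for (i in 1:60) {
    expand <- logicleBiexp(spec, hi) < xs
    if (!any(expand)) break
    hi[expand] <- hi[expand] + 2^(i / 4)
  }
  y <- (lo + hi) / 2
  tol <- 1e-10 * max(spec@T, 1)
  done <- rep(FALSE, length(xs))
  for (iter in 1:100) {
    fv <- logicleBiexp(spec, y) - xs
    done <- done | (abs(fv) <= tol & (hi - lo) < 1e-12)
    if (all(done)) break
    hi <- ifelse(fv > 0 & !done, y, hi)
    lo <- ifelse(fv <= 0 & !done, y, lo)
    step <- fv / logicleBiexpDeriv(spec, y)
    cand <- y - step
    ok <- is.finite(cand) & cand > lo & cand < hi
    y <- ifelse(done, y, ifelse(ok, cand, (lo + hi) / 2))
  }
  fv <- logicleBiexp(spec, y) - xs
  if (any(abs(fv) > 1e-8 * max(spec@T, 1)))
    cgStop("cg_numerical_error",
           "logicle forward failed to converge for value %g",
           xs[which.max(abs(fv))])
  out[!bad] <- y * (spec@M + spec@A)
  out
})

#' @rdname transformInverse
#' @export
setMethod("transformInverse", "LogicleTransform", function(spec, x) {
  logicleBiexp(spec, x / (spec@M + spec@A))
})

#' @rdname displayRange
#' @export
setMethod("displayRange", "LogicleTransform", function(spec) c(0, spec@M + spec@A))

setMethod("show", "LogicleTransform", function(object) {
  cat(sprintf("LogicleTransform(T=%g, M=%g, W=%g, A=%g)\n",
              object@T, object@M, object@W, object@A))
})

#' Construct a Bilog transform
#'
#' Symmetric linear/log hybrid: `f(x) = x / (linBound * ln 10)` for
#' `|x| <= linBound` and `f(x) = sign(x) * (1/ln 10 + log10(|x|/linBound))`
#' beyond — continuous with continuous first derivative at the junction,
#' strictly increasing, with an exact closed-form inverse. Display units are
#' decades.
#'
#' @param linBound Data value below which the scale is linear (> 0).
#' @param decades Decades spanned by the log region; fixes the display range
#'   used for rendering. Default 5.
#' @return A [BilogTransform-class].
#' @export
bilogTransform <- function(linBound, decades = 5) {
  new("BilogTransform", linBound = as.numeric(linBound),
      decades = as.numeric(decades))
}

#' @rdname transformForward
#' @export
setMethod("transformForward", "BilogTransform", function(spec, x) {
  L <- spec@linBound
  ax <- abs(x)
  ifelse(ax <= L, x / (L * log(10)),
         sign(x) * (1 / log(10) + log10(ax / L)))
})

#' @rdname transformInverse
#' @export
setMethod("transformInverse", "BilogTransform", function(spec, x) {
  L <- spec@linBound
  lim <- 1 / log(10)
  ax <- abs(x)
  ifelse(ax <= lim, x * L * log(10), sign(x) * L * 10^(ax - lim))
})

#' @rdname displayRange
#' @export
setMethod("displayRange", "BilogTransform", function(spec) {
  # fluorescence axes run `decades` above the linear region but only one
  # decade below it: compensated data rarely reach further negative, and
  # blank display area dilutes QC image contrast
  c(-(1 / log(10) + 1), 1 / log(10) + spec@decades)
})

setMethod("show", "BilogTransform", function(object) {
  cat(sprintf("BilogTransform(linBound=%g, decades=%g)\n",
              object@linBound, object@decades))
})

#' Construct a log10 transform
#' @return A [Log10Transform-class].
#' @export
log10Transform <- function() new("Log10Transform")

#' @rdname transformForward
#' @export
setMethod("transformForward", "Log10Transform", function(spec, x) {
  suppressWarnings(log10(x))  # x <= 0 -> non-finite, dropped at view time
})

#' @rdname transformInverse
#' @export
setMethod("transformInverse", "Log10Transform", function(spec, x) 10^x)

#' @rdname displayRange
#' @export
setMethod("displayRange", "Log10Transform", function(spec) NULL)

#' Construct an identity (linear) transform
#' @return A [LinearTransform-class].
#' @export
linearTransform <- function() new("LinearTransform")

#' @rdname transformForward
#' @export
setMethod("transformForward", "LinearTransform", function(spec, x) x)

#' @rdname transformInverse
#' @export
setMethod("transformInverse", "LinearTransform", function(spec, x) x)

#' @rdname displayRange
#' @export
setMethod("displayRange", "LinearTransform", function(spec) NULL)

# (de)serialisation for configuration files ----------------------------------

#' Build a transform from a configuration list
#'
#' Inverse of [transformToList()]; used when reading experiment
#' configuration files.
#'
#' @param x A list with element `kind` (one of `logicle`, `bilog`, `log10`,
#'   `linear`) plus the transform's named parameters.
#' @return A [TransformSpec-class].
#' @export
transformFromList <- function(x) {
  kind <- x$kind
  if (is.null(kind))
    cgStop("cg_config_error", "transform specification lacks a 'kind'")
  switch(kind,
    logicle = logicleTransform(
      T = x$T %||% 262144, M = x$M %||% 4.5, W = x$W %||% 0.5, A = x$A %||% 0),
    bilog = bilogTransform(
      linBound = x$lin_bound %||% x$linBound %||%
        cgStop("cg_config_error", "bilog transform needs lin_bound"),
      decades = x$decades %||% 5),
    log10 = log10Transform(),
    linear = linearTransform(),
    cgStop("cg_config_error", "unknown transform kind '%s'", kind))
}

#' Serialise a transform to a configuration list
#' @param spec A [TransformSpec-class].
#' @return A named list with `kind` and parameters.
#' @export
transformToList <- function(spec) {
  if (is(spec, "LogicleTransform"))
    list(kind = "logicle", T = spec@T, M = spec@M, W = spec@W, A = spec@A)
  else if (is(spec, "BilogTransform"))
    list(kind = "bilog", lin_bound = spec@linBound, decades = spec@decades)
  else if (is(spec, "Log10Transform")) list(kind = "log10")
  else list(kind = "linear")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
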