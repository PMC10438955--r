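#' Build a 1D or 2D gating view
#'
#' Extracts the parent population's values on one or two channels and applies
#' the per-channel display transform. Events whose transformed values are not
#' finite are dropped from the view (with their count recorded); dropped
#' events can never enter a gate but remain in the sample.
#'
#' @param sample A [CytoSample-class].
#' @param channels One or two channel names.
#' @param parent Parent gate name, `"root"` by default.
#' @param transforms A named list of [TransformSpec-class] per channel, a
#'   single spec applied to every view channel, or an
#'   [ExperimentConfig-class] whose `transforms` are consulted. Channels
#'   without an entry are viewed linearly.
#' @return A [GatingView-class].
#' @examples
#' s <- CytoSample("ex", EventTable(cbind(a = rnorm(100), b = rnorm(100))))
#' v <- gateView(s, c("a", "b"))
#' @export
gateView <- function(sample, channels, parent = "root", transforms = NULL) {
  stopifnot(is(sample, "CytoSample"))
  channels <- as.character(channels)
  if (!length(channels) %in% 1:2)
    cgStop("cg_validation_error", "a view needs one or two channels")
  missing <- setdiff(channels, channels(sample))
  if (length(missing))
    cgStop("cg_lookup_error", "channels not in sample: %s",
           paste(missing, collapse = ", "))

  specFor <- function(ch) {
    if (is.null(transforms)) linearTransform()
    else if (is(transforms, "ExperimentConfig")) configTransform(transforms, ch)
    else if (is(transforms, "TransformSpec")) transforms
    else transforms[[ch]] %||% linearTransform()
  }

  idx <- gateIndices(sample, parent)
  vals <- sample@table@values[idx, channels, drop = FALSE]
  for (j in seq_along(channels))
    vals[, j] <- transformForward(specFor(channels[j]), vals[, j])
  keep <- rowSums(!is.finite(vals)) == 0
  new("GatingView", parentName = as.character(parent),
      parentIndices = as.integer(idx[keep]),
      channels = channels,
      values = vals[keep, , drop = FALSE],
      droppedNonFinite = as.integer(sum(!keep)))
}

#' @describeIn gateView Number of (finite) events in a view.
#' @param x A `GatingView`.
#' @export
setMethod("nEvents", "GatingView", function(x) length(x@parentIndices))

#' @rdname gateView
#' @export
setMethod("channels", "GatingView", function(x) x@channels)

setMethod("show", "GatingView", function(object) {
  cat(sprintf("GatingView on %s: %d events of parent '%s' (%d non-finite dropped)\n",
              paste(object@channels, collapse = " x "),
              length(object@parentIndices), object@parentName,
              object@droppedNonFinite))
})

# build a GateResult from a logical selector over the view rows
viewGate <- function(view, name, keep, method) {
  new("GateResult", name = name,
      indices = view@parentIndices[keep],
      parent = view@parentName, view = view@channels, method = method)
}
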