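#' Channel names of an object
#' @param x An object with channels.
#' @return Character vector of channel names.
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' Number of events in an object
#' @param x An object holding events.
#' @return Integer event count.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Event value matrix
#' @param x An object holding an event matrix.
#' @return Numeric matrix, events x channels.
#' @export
setGeneric("eventValues", function(x) standardGeneric("eventValues"))

#' Map data values to display units
#'
#' Applies a display transform forward: data scale to display scale. All
#' transforms are strictly increasing; out-of-range inputs are transformed,
#' not clipped.
#'
#' @param spec A [TransformSpec-class].
#' @param x Numeric vector of data values.
#' @return Numeric vector of display values.
#' @export
setGeneric("transformForward", function(spec, x) standardGeneric("transformForward"))

#' Map display units back to data values
#'
#' Closed-form inverse of [transformForward()];
#' `transformInverse(spec, transformForward(spec, x))` recovers `x` within
#' the documented tolerance of each transform.
#'
#' @param spec A [TransformSpec-class].
#' @param x Numeric vector of display values.
#' @return Numeric vector of data values.
#' @export
setGeneric("transformInverse", function(spec, x) standardGeneric("transformInverse"))

#' Fixed display range of a transform
#'
#' The display-unit interval used for rendering and QC images so images are
#' comparable across samples. `NULL` for transforms with no intrinsic range
#' (linear, log10), in which case callers fall back to data-driven ranges.
#'
#' @param spec A [TransformSpec-class].
#' @return Numeric length-2 vector, or `NULL`.
#' @export
setGeneric("displayRange", function(spec) standardGeneric("displayRange"))

#' Serialise a spillover matrix to its FCS keyword value
#' @param x A [SpilloverMatrix-class].
#' @return The `$SPILLOVER` keyword string `"n,label1,...,v11,..."`.
#' @export
setGeneric("serializeSpillover", function(x) standardGeneric("serializeSpillover"))

#' Gate names attached to a sample
#' @param x A [CytoSample-class].
#' @return Character vector of gate names in attachment order.
#' @export
setGeneric("gateNames", function(x) standardGeneric("gateNames"))

#' Sample identifiers of an object
#' @param x A [CytoExperiment-class] or [CytoSample-class].
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
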