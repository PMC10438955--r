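#' @import methods
NULL

#' FCS file metadata
#'
#' Keyword-level description of one FCS data set: version label, the verbatim
#' TEXT-segment keywords, channel short names (`$PnN`) and stain labels
#' (`$PnS`), the declared event count and the on-disk data encoding.
#'
#' @slot version Version label, e.g. `"FCS3.1"`.
#' @slot keywords Named list of TEXT-segment keyword values, preserved verbatim.
#' @slot channelNames Ordered `$PnN` short names, one per channel.
#' @slot channelLabels Ordered `$PnS` stain labels (`""` where absent).
#' @slot nEvents Declared number of events (`$TOT`).
#' @slot datatype One of `"float32"`, `"float64"`, `"integer"`.
#' @slot byteOrder One of `"little"`, `"big"`.
#' @export
setClass("FCSMetadata",
  slots = c(
    version       = "character",
    keywords      = "list",
    channelNames  = "character",
    channelLabels = "character",
    nEvents       = "integer",
    datatype      = "character",
    byteOrder     = "character"
  )
)

setValidity("FCSMetadata", function(object) {
  msg <- character()
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names ($PnN) must be unique")
  if (length(object@channelLabels) != length(object@channelNames))
    msg <- c(msg, "channelLabels must parallel channelNames")
  if (length(object@nEvents) != 1L || is.na(object@nEvents) || object@nEvents < 0L)
    msg <- c(msg, "nEvents must be a single nonnegative integer")
  if (!object@datatype %in% c("float32", "float64", "integer"))
    msg <- c(msg, "datatype must be float32, float64 or integer")
  if (!object@byteOrder %in% c("little", "big"))
    msg <- c(msg, "byteOrder must be little or big")
  if (length(msg)) msg else TRUE
})

#' Event table: events x channels
#'
#' The substrate for all gating: a numeric matrix with one row per measured
#' event and one column per detector channel, in file order. Row order is
#' stable identity — gates refer to events by 1-based row index.
#'
#' @slot values Numeric matrix, events in rows, channels in columns.
#' @slot channels Ordered channel-name vector, parallel to the columns.
#' @export
setClass("EventTable",
  slots = c(values = "matrix", channels = "character")
)

setValidity("EventTable", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be numeric")
  if (ncol(object@values) != length(object@channels))
    msg <- c(msg, "column count must equal length(channels)")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel names must be unique")
  if (anyNA(object@values))
    msg <- c(msg, "values must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Spillover (compensation) matrix
#'
#' Square channel-mixing matrix with channel-name labels. Mixing follows
#' `X = Y %*% S` for true signal `Y`; compensation applies the inverse.
#' Diagonal entries are normalised to 1 on read.
#'
#' @slot labels Ordered fluorescence-channel names.
#' @slot coefficients Square numeric matrix, `labels` on both dimensions.
#' @export
setClass("SpilloverMatrix",
  slots = c(labels = "character", coefficients = "matrix")
)

setValidity("SpilloverMatrix", function(object) {
  msg <- character()
  d <- dim(object@coefficients)
  if (d[1] != d[2])
    msg <- c(msg, "coefficients must be square")
  if (d[1] != length(object@labels))
    msg <- c(msg, "labels must match matrix dimension")
  if (anyNA(object@coefficients) || any(!is.finite(object@coefficients)))
    msg <- c(msg, "coefficients must be finite")
  else if (any(diag(object@coefficients) <= 0))
    msg <- c(msg, "diagonal entries must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Display transforms
#'
#' Virtual parent of the display-scale transforms used for gating views and
#' image rendering: [LogicleTransform-class], [BilogTransform-class],
#' [Log10Transform-class] and [LinearTransform-class]. All transforms are
#' strictly increasing and invertible on their domain; they are applied at
#' view time only, never destructively to stored events.
#'
#' @export
setClass("TransformSpec", representation("VIRTUAL"))

#' Logicle (bi-exponential) transform
#'
#' The bi-exponential display scale: approximately linear around zero and
#' logarithmic at high intensities. Parameterised by top-of-scale value `T`,
#' total display decades `M`, linearisation width `W` (decades) and additional
#' negative decades `A`. Display units run from 0 at the bottom of scale to
#' `M + A` at `x = T`. The derived bi-exponential coefficients are computed
#' once at construction.
#'
#' @slot T Top-of-scale data value (> 0).
#' @slot M Total display decades (> 0).
#' @slot W Linearisation width in decades (0 <= W <= M/2).
#' @slot A Additional negative display decades (>= 0).
#' @slot a,b,c,d,f Derived bi-exponential coefficients.
#' @slot x1 Display position (on the internal 0..1 scale) of data value 0.
#' @export
setClass("LogicleTransform",
  contains = "TransformSpec",
  slots = c(T = "numeric", M = "numeric", W = "numeric", A = "numeric",
            a = "numeric", b = "numeric", c = "numeric", d = "numeric",
            f = "numeric", x1 = "numeric")
)

setValidity("LogicleTransform", function(object) {
  msg <- character()
  if (object@T <= 0) msg <- c(msg, "T must be > 0")
  if (object@M <= 0) msg <- c(msg, "M must be > 0")
  if (object@W < 0 || object@W > object@M / 2)
    msg <- c(msg, "W must satisfy 0 <= W <= M/2")
  if (object@A < 0) msg <- c(msg, "A must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Bilog transform
#'
#' Symmetric hybrid linear/log display scale: linear on
#' `[-linBound, +linBound]`, base-10 logarithmic in `|x|` beyond, mirrored in
#' sign. The linear slope is `1/(linBound * ln 10)` so the scale is
#' continuously differentiable at the junction. Display units are decades:
#' one display unit per decade in the log region.
#'
#' @slot linBound Data value below which the scale is linear (> 0).
#' @slot decades Decades spanned by the log region (used for display ranges).
#' @export
setClass("BilogTransform",
  contains = "TransformSpec",
  slots = c(linBound = "numeric", decades = "numeric")
)

setValidity("BilogTransform", function(object) {
  msg <- character()
  if (object@linBound <= 0) msg <- c(msg, "linBound must be > 0")
  if (object@decades <= 0) msg <- c(msg, "decades must be > 0")
  if (length(msg)) msg else TRUE
})

#' Plain log10 transform
#' @export
setClass("Log10Transform", contains = "TransformSpec")

#' Identity (linear) transform
#' @export
setClass("LinearTransform", contains = "TransformSpec")

#' An annotated gated population
#'
#' Ordered set of event indices (1-based, relative to one sample's event
#' table) plus provenance: the parent gate, the view channels the gate was
#' drawn on, and a tag naming the producing method.
#'
#' @slot name Gate name, unique within a sample.
#' @slot indices Strictly increasing 1-based event indices.
#' @slot parent Parent gate name, or `"root"`.
#' @slot view One or two channel names defining the gating view.
#' @slot method Text tag of the producing operation.
#' @export
setClass("GateResult",
  slots = c(name = "character", indices = "integer",
            parent = "character", view = "character", method = "character")
)

setValidity("GateResult", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  idx <- object@indices
  if (length(idx) && (anyNA(idx) || any(idx < 1L)))
    msg <- c(msg, "indices must be positive")
  if (is.unsorted(idx, strictly = TRUE))
    msg <- c(msg, "indices must be strictly increasing (no duplicates)")
  if (!length(object@view) %in% 1:2)
    msg <- c(msg, "view must name one or two channels")
  if (length(msg)) msg else TRUE
})

#' One loaded sample with its gates
#'
#' Container for one sample's event data, metadata and accumulated gating
#' results. Stored event values are raw/compensated linear data; display
#' transforms are applied at view time only.
#'
#' @slot id Sample identifier (file basename without extension).
#' @slot table The sample's [EventTable-class].
#' @slot metadata The sample's [FCSMetadata-class].
#' @slot gates Named list of [GateResult-class], in attachment order.
#' @export
setClass("CytoSample",
  slots = c(id = "character", table = "EventTable",
            metadata = "FCSMetadata", gates = "list")
)

setValidity("CytoSample", function(object) {
  msg <- character()
  n <- nrow(object@table@values)
  for (g in object@gates) {
    if (!is(g, "GateResult")) { msg <- c(msg, "gates must be GateResult objects"); break }
    if (length(g@indices) && max(g@indices) > n) {
      msg <- c(msg, sprintf("gate '%s' has indices beyond the event table", g@name))
      break
    }
  }
  if (length(object@gates) &&
      !identical(names(object@gates),
                 unname(vapply(object@gates, function(g) g@name, ""))))
    msg <- c(msg, "gates list names must match gate names")
  if (length(msg)) msg else TRUE
})

#' Experiment configuration
#'
#' Pre-gate processing and output settings shared by all samples of an
#' experiment: compensation mode, per-channel display transforms, output
#' directory, QC image resolution, worker count and the global seed.
#'
#' @slot compensationMode `"from_file"`, `"external"` or `"none"`.
#' @slot externalSpilloverPath Path to a tab-separated spillover matrix
#'   (used when `compensationMode == "external"`; `NA` otherwise).
#' @slot transforms Named list of [TransformSpec-class] per channel; channels
#'   without an entry default to linear.
#' @slot outputDir Directory for results tables and diagnostic images.
#' @slot imageResolution Side length of square QC images (>= 8).
#' @slot workers Default worker count for batch runs (>= 1).
#' @slot seed Global random seed for the experiment.
#' @export
setClass("ExperimentConfig",
  slots = c(compensationMode = "character",
            externalSpilloverPath = "character",
            transforms = "list",
            outputDir = "character",
            imageResolution = "integer",
            workers = "integer",
            seed = "integer")
)

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (!object@compensationMode %in% c("from_file", "external", "none"))
    msg <- c(msg, "compensationMode must be from_file, external or none")
  if (object@imageResolution < 8L)
    msg <- c(msg, "imageResolution must be >= 8")
  if (object@workers < 1L)
    msg <- c(msg, "workers must be >= 1")
  if (length(object@transforms) &&
      !all(vapply(object@transforms, function(t) is(t, "TransformSpec"), TRUE)))
    msg <- c(msg, "transforms must be TransformSpec objects")
  if (length(msg)) msg else TRUE
})

#' A batch of samples to be gated
#'
#' The top-level workflow object: the enumerated sample paths, the shared
#' configuration, collected per-sample results and any flagged samples
#' (unreadable files, missing spillover, ...). A flagged or failed sample
#' never aborts the batch.
#'
#' @slot samplePaths Ordered FCS file paths.
#' @slot sampleIds Unique sample ids derived from the paths.
#' @slot config The shared [ExperimentConfig-class].
#' @slot results Per-sample named list of result records.
#' @slot flagged data.frame with columns `sample_id`, `reason`.
#' @export
setClass("CytoExperiment",
  slots = c(samplePaths = "character", sampleIds = "character",
            config = "ExperimentConfig", results = "list",
            flagged = "data.frame")
)

setValidity("CytoExperiment", function(object) {
  msg <- character()
  if (length(object@samplePaths) != length(object@sampleIds))
    msg <- c(msg, "samplePaths and sampleIds must be parallel")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' A 1D or 2D gating view
#'
#' The values a gating primitive sees: the parent population's events on one
#' or two channels with the per-channel display transform applied. Rows with
#' non-finite transformed values are dropped from the view (their indices can
#' never enter a gate) and counted in `droppedNonFinite`.
#'
#' @slot parentName Name of the parent gate (`"root"` for all events).
#' @slot parentIndices 1-based event indices backing the view rows.
#' @slot channels One or two channel names.
#' @slot values Numeric matrix (n x 1 or n x 2) of transformed values.
#' @slot droppedNonFinite Number of parent events dropped as non-finite.
#' @export
setClass("GatingView",
  slots = c(parentName = "character", parentIndices = "integer",
            channels = "character", values = "matrix",
            droppedNonFinite = "integer")
)

setValidity("GatingView", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@parentIndices))
    msg <- c(msg, "values rows must parallel parentIndices")
  if (ncol(object@values) != length(object@channels))
    msg <- c(msg, "values columns must parallel channels")
  if (!length(object@channels) %in% 1:2)
    msg <- c(msg, "a view has one or two channels")
  if (length(object@values) && any(!is.finite(object@values)))
    msg <- c(msg, "view values must be finite")
  if (is.unsorted(object@parentIndices, strictly = TRUE))
    msg <- c(msg, "parentIndices must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Down-sampled QC image of one gate view
#'
#' Fixed-resolution intensity image of one gate view of one sample: 2D
#' histogram on fixed transformed-scale ranges, log1p-scaled, max-normalised
#' to `[0, 1]`, block-mean down-sampled. The feature object for QC clustering.
#'
#' @slot sampleId Sample identifier.
#' @slot gateName Gate the image depicts.
#' @slot pixels R x R numeric matrix in `[0, 1]`.
#' @slot normalization Normalisation tag (e.g. `"log1p_max"`).
#' @export
setClass("QCImage",
  slots = c(sampleId = "character", gateName = "character",
            pixels = "matrix", normalization = "character")
)

setValidity("QCImage", function(object) {
  msg <- character()
  p <- object@pixels
  if (nrow(p) != ncol(p)) msg <- c(msg, "pixels must be square")
  if (nrow(p) < 8) msg <- c(msg, "resolution must be >= 8")
  if (length(p) && (anyNA(p) || min(p) < 0 || max(p) > 1))
    msg <- c(msg, "pixel values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Post-gating quality-control report
#'
#' Merged image-clustering and percentile outlier flags across an experiment,
#' plus per-gate cluster labels and summary counts.
#'
#' @slot flags data.frame with columns `sample_id`, `gate`, `reason`, `value`.
#' @slot clusters Named list (per gate) of integer cluster labels per sample.
#' @slot summary data.frame of per-gate/per-reason flag counts.
#' @export
setClass("QCReport",
  slots = c(flags = "data.frame", clusters = "list", summary = "data.frame")
)
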