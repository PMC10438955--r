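#' Construct a gate result
#'
#' Normally produced by the gating primitives; exposed for custom gates.
#'
#' @param name Gate name.
#' @param indices 1-based event indices (sorted and de-duplicated here).
#' @param parent Parent gate name, `"root"` by default.
#' @param view One or two channel names.
#' @param method Text tag of the producing operation.
#' @return A [GateResult-class].
#' @export
GateResult <- function(name, indices, parent = "root", view = character(),
                       method = "manual") {
  new("GateResult", name = name,
      indices = sort(unique(as.integer(indices))),
      parent = parent, view = as.character(view), method = method)
}

#' @describeIn GateResult Number of events in the gate.
#' @param x A `GateResult`.
#' @export
setMethod("nEvents", "GateResult", function(x) length(x@indices))

setMethod("show", "GateResult", function(object) {
  cat(sprintf("GateResult '%s': %d events (parent '%s', view %s, method %s)\n",
              object@name, length(object@indices), object@parent,
              paste(object@view, collapse = " x "), object@method))
})

#' Construct a sample container
#'
#' @param id Sample identifier.
#' @param table The sample's [EventTable-class].
#' @param metadata The sample's [FCSMetadata-class]; derived from the table
#'   when omitted.
#' @return A [CytoSample-class] with no gates attached.
#' @export
CytoSample <- function(id, table, metadata = NULL) {
  if (is.null(metadata))
    metadata <- FCSMetadata(channels(table), nEvents(table))
  new("CytoSample", id = id, table = table, metadata = metadata, gates = list())
}

#' @describeIn CytoSample Number of events.
#' @param x A `CytoSample`.
#' @export
setMethod("nEvents", "CytoSample", function(x) nEvents(x@table))

#' @describeIn CytoSample Channel names.
#' @export
setMethod("channels", "CytoSample", function(x) channels(x@table))

#' @rdname gateNames
#' @export
setMethod("gateNames", "CytoSample", function(x) names(x@gates))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "CytoSample", function(x) x@id)

setMethod("show", "CytoSample", function(object) {
  cat(sprintf("CytoSample '%s': %d events x %d channels, %d gates\n",
              object@id, nEvents(object), length(channels(object)),
              length(object@gates)))
  if (length(object@gates))
    cat("gates:", paste(names(object@gates), collapse = ", "), "\n")
})

# indices of a gate, with "root" meaning all events
gateIndices <- function(sample, name) {
  if (identical(name, "root")) return(seq_len(nEvents(sample)))
  g <- sample@gates[[name]]
  if (is.null(g))
    cgStop("cg_lookup_error", "unknown gate '%s' in sample '%s'", name, sample@id)
  g@indices
}

#' Attach a gate to a sample
#'
#' Enforces the hierarchy contract: the declared parent must exist (or be
#' `"root"`), the gate's indices must be a subset of the parent's, and gate
#' names are unique within a sample.
#'
#' @param sample A [CytoSample-class].
#' @param gate A [GateResult-class].
#' @return The updated sample.
#' @export
attachGate <- function(sample, gate) {
  stopifnot(is(sample, "CytoSample"), is(gate, "GateResult"))
  if (gate@name %in% names(sample@gates))
    cgStop("cg_name_collision", "gate '%s' already attached to sample '%s'",
           gate@name, sample@id)
  if (!identical(gate@parent, "root") && is.null(sample@gates[[gate@parent]]))
    cgStop("cg_lineage_error", "parent gate '%s' of '%s' does not exist",
           gate@parent, gate@name)
  parentIdx <- gateIndices(sample, gate@parent)
  if (length(gate@indices) && !all(gate@indices %in% parentIdx))
    cgStop("cg_containment_error",
           "gate '%s' contains events outside its parent '%s'",
           gate@name, gate@parent)
  sample@gates[[gate@name]] <- gate
  validObject(sample)
  sample
}

#' Fraction of a reference population captured by a gate
#'
#' The statistic the framework reports: `count(gate) / count(reference)`.
#' The gate must be a descendant of the reference (or the reference `"root"`).
#' An empty reference yields `NA`, never 0.
#'
#' @param sample A gated [CytoSample-class].
#' @param gate Gate name.
#' @param reference Ancestor gate name, default `"root"`.
#' @return A ratio in `[0, 1]`, or `NA_real_` for an empty reference.
#' @export
populationFraction <- function(sample, gate, reference = "root") {
  gIdx <- gateIndices(sample, gate)
  rIdx <- gateIndices(sample, reference)
  if (!identical(reference, "root")) {
    anc <- gate
    repeat {
      if (identical(anc, reference)) break
      if (identical(anc, "root"))
        cgStop("cg_lineage_error",
               "gate '%s' is not a descendant of reference '%s'", gate, reference)
      anc <- sample@gates[[anc]]@parent
    }
  }
  if (length(rIdx) == 0) return(NA_real_)
  length(gIdx) / length(rIdx)
}

# ---------------------------------------------------------------------------

#' Assemble an experiment from FCS files
#'
#' Enumerates `.fcs` paths (lexicographically when given a directory),
#' derives unique sample ids from file basenames, and validates each file's
#' header/TEXT without decoding events. Unreadable files are flagged
#' (`parse_failure`), never fatal; an experiment with zero readable files is
#' a configuration error.
#'
#' @param paths A directory containing `.fcs` files, or a character vector
#'   of file paths.
#' @param config An [ExperimentConfig-class].
#' @return A [CytoExperiment-class].
#' @export
buildExperiment <- function(paths, config = experimentConfig()) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.fcs$", full.names = TRUE,
                        ignore.case = TRUE)
  paths <- sort(paths, method = "radix")
  if (!length(paths))
    cgStop("cg_config_error", "no .fcs files to build an experiment from")

  ids <- sub("\\.fcs$", "", basename(paths), ignore.case = TRUE)
  dup <- duplicated(ids)
  if (any(dup)) {
    cgWarn("cg_id_collision", "duplicate sample ids suffixed: %s",
           paste(unique(ids[dup]), collapse = ", "))
    ids <- make.unique(ids, sep = "_")
  }

  flagged <- data.frame(sample_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  readable <- logical(length(paths))
  for (i in seq_along(paths)) {
    ok <- tryCatch({
      suppressWarnings(readFCS(paths[i], what = "metadata")); TRUE
    }, error = function(e) FALSE)
    readable[i] <- ok
    if (!ok)
      flagged <- rbind(flagged, data.frame(sample_id = ids[i],
                                           reason = "parse_failure",
                                           stringsAsFactors = FALSE))
  }
  if (!any(readable))
    cgStop("cg_config_error", "no readable .fcs files among %d paths", length(paths))

  new("CytoExperiment", samplePaths = paths, sampleIds = ids,
      config = config, results = list(), flagged = flagged)
}

#' @describeIn buildExperiment Sample ids of an experiment.
#' @param x A `CytoExperiment`.
#' @export
setMethod("sampleIds", "CytoExperiment", function(x) x@sampleIds)

setMethod("show", "CytoExperiment", function(object) {
  cat(sprintf("CytoExperiment: %d samples (%d flagged), compensation '%s'\n",
              length(object@samplePaths), nrow(object@flagged),
              object@config@compensationMode))
})

#' Load one sample of an experiment
#'
#' Reads the events and applies compensation per the experiment
#' configuration: the file's own `$SPILLOVER` when
#' `compensationMode == "from_file"` (a missing keyword loads the sample
#' uncompensated with a `cg_no_spillover` warning), an external matrix when
#' `"external"`, or nothing. Display transforms are never applied to stored
#' values — they act at view time.
#'
#' @param experiment A [CytoExperiment-class].
#' @param id A sample id of the experiment.
#' @return A [CytoSample-class].
#' @export
loadSample <- function(experiment, id) {
  i <- match(id, experiment@sampleIds)
  if (is.na(i))
    cgStop("cg_lookup_error", "sample '%s' is not part of the experiment", id)
  parsed <- readFCS(experiment@samplePaths[i])
  table <- parsed$table
  mode <- experiment@config@compensationMode
  if (mode == "from_file") {
    spill <- extractSpillover(parsed$metadata)
    if (is.null(spill))
      cgWarn("cg_no_spillover",
             "sample '%s' has no spillover keyword; loading uncompensated", id)
    else table <- applyCompensation(table, spill)
  } else if (mode == "external") {
    spill <- readSpilloverFile(experiment@config@externalSpilloverPath)
    table <- applyCompensation(table, spill)
  }
  CytoSample(id = id, table = table, metadata = parsed$metadata)
}
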