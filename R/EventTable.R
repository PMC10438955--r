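#' Construct an event table
#'
#' @param values Numeric matrix, events in rows, channels in columns.
#' @param channels Channel names; defaults to `colnames(values)`.
#' @return An [EventTable-class].
#' @examples
#' et <- EventTable(matrix(rnorm(20), 10, 2), c("FSC-A", "CD3"))
#' nEvents(et)
#' @export
EventTable <- function(values, channels = colnames(values)) {
  if (is.null(channels))
    cgStop("cg_validation_error", "channel names are required")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  colnames(values) <- channels
  new("EventTable", values = values, channels = as.character(channels))
}

#' @describeIn EventTable Channel names.
#' @param x An `EventTable`.
#' @export
setMethod("channels", "EventTable", function(x) x@channels)

#' @describeIn EventTable Number of events (rows).
#' @export
setMethod("nEvents", "EventTable", function(x) nrow(x@values))

#' @describeIn EventTable The underlying events x channels matrix.
#' @export
setMethod("eventValues", "EventTable", function(x) x@values)

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d events x %d channels\n",
              nrow(object@values), ncol(object@values)))
  cat("channels:", paste(object@channels, collapse = ", "), "\n")
})
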