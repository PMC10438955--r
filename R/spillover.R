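#' Construct a spillover matrix
#'
#' @param coefficients Square numeric matrix; row/column order follows
#'   `labels`. Mixing convention: measured `X = true Y %*% S`.
#' @param labels Fluorescence channel names; defaults to
#'   `colnames(coefficients)`.
#' @param normalize Rescale each row so its diagonal entry is 1 (the FCS
#'   convention on read). Default `TRUE`.
#' @return A [SpilloverMatrix-class].
#' @export
SpilloverMatrix <- function(coefficients, labels = colnames(coefficients),
                            normalize = TRUE) {
  coefficients <- as.matrix(coefficients)
  if (is.null(labels))
    cgStop("cg_validation_error", "spillover labels are required")
  if (normalize) {
    dg <- diag(coefficients)
    if (any(!is.finite(dg)) || any(dg <= 0))
      cgStop("cg_parse_error", "spillover diagonal entries must be positive")
    coefficients <- coefficients / dg
  }
  dimnames(coefficients) <- list(labels, labels)
  new("SpilloverMatrix", labels = as.character(labels),
      coefficients = coefficients)
}

#' @describeIn SpilloverMatrix Channel labels.
#' @param x A `SpilloverMatrix`.
#' @export
setMethod("channels", "SpilloverMatrix", function(x) x@labels)

setMethod("show", "SpilloverMatrix", function(object) {
  cat(sprintf("SpilloverMatrix over %d channels: %s\n",
              length(object@labels), paste(object@labels, collapse = ", ")))
  print(round(object@coefficients, 4))
})

#' @rdname serializeSpillover
#' @export
setMethod("serializeSpillover", "SpilloverMatrix", function(x) {
  paste(c(length(x@labels), x@labels,
          format(as.vector(t(x@coefficients)), trim = TRUE, digits = 15,
                 scientific = FALSE)),
        collapse = ",")
})

#' Extract the spillover matrix stored in FCS metadata
#'
#' Parses the `$SPILLOVER` keyword (FCS3.1) or the legacy `SPILL` / `$COMP`
#' keywords: `"n,label1,...,labeln,v11,v12,..."` with the n^2 coefficients in
#' row-major order. Rows are rescaled so the diagonal is 1.
#'
#' @param metadata An [FCSMetadata-class].
#' @return A [SpilloverMatrix-class], or `NULL` when no spillover keyword is
#'   present.
#' @examples
#' md <- FCSMetadata(c("FL1", "FL2"), 0,
#'                   keywords = list("$SPILLOVER" = "2,FL1,FL2,1,0.1,0.05,1"))
#' extractSpillover(md)
#' @export
extractSpillover <- function(metadata) {
  value <- NULL
  for (key in c("$SPILLOVER", "SPILL", "$COMP")) {
    value <- fcsKeyword(metadata@keywords, key)
    if (!is.null(value)) break
  }
  if (is.null(value)) return(NULL)
  parseSpilloverKeyword(value)
}

parseSpilloverKeyword <- function(value) {
  fields <- trimws(strsplit(value, ",", fixed = TRUE)[[1]])
  n <- suppressWarnings(as.integer(fields[1]))
  if (is.na(n) || n < 1)
    cgStop("cg_parse_error", "malformed spillover keyword (bad channel count): '%s'", value)
  if (length(fields) != 1 + n + n * n)
    cgStop("cg_parse_error",
           "malformed spillover keyword (expected %d fields, got %d): '%s'",
           1 + n + n * n, length(fields), value)
  labels <- fields[2:(n + 1)]
  coefs <- suppressWarnings(as.numeric(fields[(n + 2):length(fields)]))
  if (anyNA(coefs))
    cgStop("cg_parse_error", "malformed spillover keyword (non-numeric entry): '%s'", value)
  SpilloverMatrix(matrix(coefs, n, n, byrow = TRUE), labels, normalize = TRUE)
}

#' Read an external spillover matrix file
#'
#' Tab-separated: first row the channel names, following rows the square
#' coefficient matrix.
#'
#' @param path File path.
#' @return A [SpilloverMatrix-class].
#' @export
readSpilloverFile <- function(path) {
  if (!file.exists(path))
    cgStop("cg_validation_error", "spillover file does not exist: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(labels)
  if (length(lines) != n + 1)
    cgStop("cg_parse_error",
           "spillover file %s: expected %d matrix rows, found %d",
           path, n, length(lines) - 1)
  rows <- lapply(lines[-1], function(l)
    suppressWarnings(as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  if (any(vapply(rows, length, 0L) != n) || anyNA(unlist(rows)))
    cgStop("cg_parse_error", "spillover file %s is not a square numeric matrix", path)
  SpilloverMatrix(do.call(rbind, rows), labels, normalize = TRUE)
}

#' Apply compensation to an event table
#'
#' Un-mixes fluorescence spillover: the block of labelled channels `X` is
#' replaced by `X %*% solve(S)`. Channels not named by the spillover matrix
#' (scatter, time) pass through unchanged; row order is preserved.
#'
#' @param table An [EventTable-class].
#' @param spill A [SpilloverMatrix-class] whose labels are all present among
#'   the table's channels.
#' @param maxCondition Condition-number bound above which the matrix is
#'   rejected as numerically unusable. Default `1e8`.
#' @return A compensated [EventTable-class].
#' @export
applyCompensation <- function(table, spill, maxCondition = 1e8) {
  stopifnot(is(table, "EventTable"), is(spill, "SpilloverMatrix"))
  missing <- setdiff(spill@labels, table@channels)
  if (length(missing))
    cgStop("cg_validation_error",
           "spillover channels absent from the event table: %s",
           paste(missing, collapse = ", "))
  S <- spill@coefficients
  cond <- kappa(S, exact = TRUE)
  if (!is.finite(cond) || cond > maxCondition)
    cgStop("cg_numerical_error",
           "spillover matrix is ill-conditioned (condition number %.3g > %.3g)",
           cond, maxCondition)
  values <- table@values
  values[, spill@labels] <- values[, spill@labels, drop = FALSE] %*% solve(S)
  EventTable(values, table@channels)
}
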