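#' Construct FCS metadata
#'
#' Usually produced by [readFCS()]; a minimal metadata object can also be
#' built directly, e.g. before [writeFCS()].
#'
#' @param channelNames Ordered `$PnN` channel short names.
#' @param nEvents Number of events.
#' @param channelLabels Optional `$PnS` stain labels.
#' @param keywords Named list of extra TEXT keywords (e.g. `$SPILLOVER`).
#' @param version,datatype,byteOrder Encoding description; the writer always
#'   emits FCS3.1 float32 little-endian regardless.
#' @return An [FCSMetadata-class].
#' @export
FCSMetadata <- function(channelNames, nEvents,
                        channelLabels = rep("", length(channelNames)),
                        keywords = list(), version = "FCS3.1",
                        datatype = "float32", byteOrder = "little") {
  new("FCSMetadata", version = version, keywords = keywords,
      channelNames = as.character(channelNames),
      channelLabels = as.character(channelLabels),
      nEvents = asCount(nEvents, "nEvents"),
      datatype = datatype, byteOrder = byteOrder)
}

#' @describeIn FCSMetadata Channel names.
#' @param x An `FCSMetadata`.
#' @export
setMethod("channels", "FCSMetadata", function(x) x@channelNames)

#' @describeIn FCSMetadata Declared event count (`$TOT`).
#' @export
setMethod("nEvents", "FCSMetadata", function(x) x@nEvents)

setMethod("show", "FCSMetadata", function(object) {
  cat(sprintf("%s metadata: %d events, %d channels (%s, %s-endian)\n",
              object@version, object@nEvents, length(object@channelNames),
              object@datatype, object@byteOrder))
})

# keyword lookup, case-insensitive per the FCS convention
fcsKeyword <- function(keywords, name) {
  hit <- match(toupper(name), toupper(names(keywords)))
  if (is.na(hit)) NULL else keywords[[hit]]
}

HEADER_LEN <- 58L

#' Read an FCS file
#'
#' Parses FCS 2.0/3.0/3.1 list-mode files: HEADER offsets, verbatim TEXT
#' keywords, and the DATA segment decoded per `$DATATYPE` (`F`, `D` or `I`),
#' `$PnB` and `$BYTEORD`. Of chained multi-data-set files (`$NEXTDATA`) only
#' the first data set is read, with a warning.
#'
#' @param path Path to an FCS file.
#' @param what `"all"` to decode events, `"metadata"` to parse and validate
#'   the header/TEXT only (the declared DATA extent is still checked against
#'   the file size).
#' @return A list with elements `table` ([EventTable-class]; a 0-row table
#'   when `what = "metadata"`) and `metadata` ([FCSMetadata-class]).
#' @seealso [writeFCS()], [extractSpillover()]
#' @export
readFCS <- function(path, what = c("all", "metadata")) {
  what <- match.arg(what)
  if (!file.exists(path))
    cgStop("cg_validation_error", "file does not exist: %s", path)
  fsize <- file.size(path)
  raw <- readBin(path, "raw", n = fsize)
  if (length(raw) < HEADER_LEN)
    cgStop("cg_integrity_error", "file too short for an FCS header: %s", path)

  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1"))
    cgStop("cg_unsupported_format",
           "unsupported FCS version '%s' (HEADER)", trimws(version))

  offs <- vapply(0:5, function(i) {
    s <- trimws(rawToChar(raw[(11 + 8 * i):(18 + 8 * i)]))
    if (!nzchar(s)) 0 else suppressWarnings(as.numeric(s))
  }, 0)
  if (anyNA(offs))
    cgStop("cg_integrity_error", "malformed HEADER offsets in %s", path)
  textBeg <- offs[1]; textEnd <- offs[2]
  dataBeg <- offs[3]; dataEnd <- offs[4]

  if (textBeg <= 0 || textEnd <= textBeg || textEnd >= length(raw))
    cgStop("cg_integrity_error", "TEXT segment offsets out of range in %s", path)
  text <- rawToChar(raw[(textBeg + 1):(textEnd + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  # drop a possible empty tail from the trailing delimiter
  if (length(parts) %% 2 == 1 && !nzchar(parts[length(parts)]))
    parts <- parts[-length(parts)]
  if (length(parts) %% 2 == 1)
    cgStop("cg_integrity_error", "unbalanced TEXT keyword/value pairs in %s", path)
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  keywords <- as.list(vals)
  names(keywords) <- keys

  kw <- function(name) fcsKeyword(keywords, name)
  need <- function(name) {
    v <- kw(name)
    if (is.null(v)) cgStop("cg_integrity_error",
                           "required keyword %s missing in %s", name, path)
    v
  }

  mode <- need("$MODE")
  if (toupper(mode) != "L")
    cgStop("cg_unsupported_format",
           "unsupported $MODE '%s' (only list mode is supported)", mode)
  dt <- toupper(need("$DATATYPE"))
  if (!dt %in% c("F", "D", "I"))
    cgStop("cg_unsupported_format", "unsupported $DATATYPE '%s'", dt)
  byteord <- need("$BYTEORD")
  endian <- switch(byteord,
    "1,2,3,4" = "little", "1,2" = "little",
    "4,3,2,1" = "big", "2,1" = "big",
    cgStop("cg_unsupported_format", "unsupported $BYTEORD '%s'", byteord))

  par <- asCount(need("$PAR"), "$PAR")
  tot <- asCount(need("$TOT"), "$TOT")
  chn <- vapply(seq_len(par), function(i) need(sprintf("$P%dN", i)), "")
  if (anyDuplicated(chn))
    cgStop("cg_integrity_error", "duplicate $PnN channel names in %s", path)
  lab <- vapply(seq_len(par), function(i) {
    v <- kw(sprintf("$P%dS", i)); if (is.null(v)) "" else v
  }, "")
  bits <- vapply(seq_len(par), function(i) asCount(need(sprintf("$P%dB", i)), "$PnB"), 0L)

  if (dt == "F" && any(bits != 32L))
    cgStop("cg_unsupported_format", "$DATATYPE F requires $PnB=32 (got %d)", bits[bits != 32L][1])
  if (dt == "D" && any(bits != 64L))
    cgStop("cg_unsupported_format", "$DATATYPE D requires $PnB=64 (got %d)", bits[bits != 64L][1])
  if (dt == "I" && !all(bits %in% c(8L, 16L, 32L)))
    cgStop("cg_unsupported_format",
           "$DATATYPE I supports $PnB in {8,16,32} (got %d)", bits[!bits %in% c(8L, 16L, 32L)][1])

  nd <- kw("$NEXTDATA")
  if (!is.null(nd) && suppressWarnings(as.numeric(nd)) > 0)
    cgWarn("cg_multi_dataset",
           "file %s chains additional data sets ($NEXTDATA=%s); only the first is read",
           path, nd)

  if (dataBeg <= 0) dataBeg <- as.numeric(need("$BEGINDATA"))
  if (dataEnd <= 0) dataEnd <- as.numeric(need("$ENDDATA"))

  bytesPerEvent <- sum(bits) / 8
  expected <- bytesPerEvent * tot
  if (tot > 0L) {
    if (dataBeg <= 0 || dataBeg + expected > length(raw) ||
        (dataEnd > 0 && dataEnd - dataBeg + 1 < expected))
      cgStop("cg_integrity_error",
             "DATA segment truncated in %s: need %d bytes for $TOT=%d events",
             path, expected, tot)
  }

  meta <- FCSMetadata(channelNames = chn, nEvents = tot, channelLabels = lab,
                      keywords = keywords,
                      version = version,
                      datatype = c(F = "float32", D = "float64", I = "integer")[[dt]],
                      byteOrder = endian)

  if (what == "metadata" || tot == 0L) {
    values <- matrix(numeric(0), nrow = 0, ncol = par)
    return(list(table = EventTable(values, chn), metadata = meta))
  }

  dataRaw <- raw[(dataBeg + 1):(dataBeg + expected)]
  values <- decodeFCSData(dataRaw, tot, par, dt, bits, endian)
  list(table = EventTable(matrix(values, nrow = tot, ncol = par, byrow = TRUE,
                                 dimnames = list(NULL, chn)), chn),
       metadata = meta)
}

# returns values in file (event-major) order
decodeFCSData <- function(dataRaw, tot, par, dt, bits, endian) {
  n <- tot * par
  if (dt == "F") return(readBin(dataRaw, "numeric", n = n, size = 4, endian = endian))
  if (dt == "D") return(readBin(dataRaw, "numeric", n = n, size = 8, endian = endian))
  # integer data, possibly mixed per-channel widths
  widths <- bits / 8L
  if (length(unique(widths)) == 1L) {
    w <- widths[1]
    if (w <= 2) return(readBin(dataRaw, "integer", n = n, size = w,
                               signed = FALSE, endian = endian))
    v <- readBin(dataRaw, "integer", n = n, size = 4, endian = endian)
    v <- as.numeric(v)
    return(ifelse(v < 0, v + 2^32, v))
  }
  bytesPerEvent <- sum(widths)
  bytes <- matrix(as.integer(dataRaw), nrow = bytesPerEvent)  # cols = events
  out <- matrix(0, nrow = tot, ncol = par)
  off <- 0L
  for (j in seq_len(par)) {
    w <- widths[j]
    v <- numeric(tot)
    for (k in seq_len(w)) {
      shift <- if (endian == "little") k - 1L else w - k
      v <- v + bytes[off + k, ] * 256^shift
    }
    out[, j] <- v
    off <- off + w
  }
  as.vector(t(out))  # event-major, matching the F/D branches
}

#' Write an FCS 3.1 file
#'
#' Emits one list-mode data set, float32 little-endian — a single dialect so
#' that the write-then-read round trip is checkable exactly at float32
#' precision. Channel `$PnS` labels and any `$SPILLOVER` keyword present in
#' the metadata are carried through; structural keywords are regenerated.
#'
#' @param table An [EventTable-class].
#' @param path Output path.
#' @param metadata Optional [FCSMetadata-class] consistent with `table`;
#'   derived from the table when omitted.
#' @return `path`, invisibly.
#' @seealso [readFCS()]
#' @export
writeFCS <- function(table, path, metadata = NULL) {
  stopifnot(is(table, "EventTable"))
  if (is.null(metadata))
    metadata <- FCSMetadata(channels(table), nEvents(table))
  if (length(metadata@channelNames) != length(table@channels) ||
      !all(metadata@channelNames == table@channels))
    cgStop("cg_validation_error",
           "metadata channel names do not match the event table")
  if (metadata@nEvents != nEvents(table))
    cgStop("cg_validation_error",
           "metadata nEvents (%d) does not match the event table (%d)",
           metadata@nEvents, nEvents(table))

  n <- nEvents(table); p <- length(table@channels)
  delim <- "/"

  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%010d", "$ENDDATA" = "%010d",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(p), "$TOT" = as.character(n)
  )
  for (j in seq_len(p)) {
    kv[sprintf("$P%dN", j)] <- table@channels[j]
    kv[sprintf("$P%dB", j)] <- "32"
    kv[sprintf("$P%dE", j)] <- "0,0"
    rng <- if (n > 0) max(1, ceiling(max(abs(table@values[, j])))) else 262144
    kv[sprintf("$P%dR", j)] <- as.character(rng)
    if (nzchar(metadata@channelLabels[j]))
      kv[sprintf("$P%dS", j)] <- metadata@channelLabels[j]
  }
  spill <- fcsKeyword(metadata@keywords, "$SPILLOVER")
  if (!is.null(spill)) kv["$SPILLOVER"] <- spill

  if (any(grepl(delim, c(names(kv), kv), fixed = TRUE)))
    cgStop("cg_validation_error",
           "keyword names/values must not contain the TEXT delimiter '%s'", delim)

  textFor <- function(beg, end) {
    body <- kv
    body["$BEGINDATA"] <- sprintf("%010d", beg)
    body["$ENDDATA"] <- sprintf("%010d", end)
    paste0(delim, paste(rbind(names(body), body), collapse = delim), delim)
  }
  textLen <- nchar(textFor(0, 0))
  textBeg <- HEADER_LEN
  textEnd <- textBeg + textLen - 1L
  nbytes <- 4 * n * p
  dataBeg <- if (nbytes > 0) textEnd + 1L else 0L
  dataEnd <- if (nbytes > 0) dataBeg + nbytes - 1L else 0L
  text <- textFor(dataBeg, dataEnd)

  hdrField <- function(x) {
    if (x > 99999999) x <- 0  # too large for HEADER; TEXT keywords carry it
    formatC(x, width = 8, flag = " ", format = "d")
  }
  header <- paste0("FCS3.1    ",
                   hdrField(textBeg), hdrField(textEnd),
                   hdrField(dataBeg), hdrField(dataEnd),
                   hdrField(0), hdrField(0))
  stopifnot(nchar(header) == HEADER_LEN)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (nbytes > 0)
    writeBin(as.vector(t(table@values)), con, size = 4, endian = "little")
  invisible(path)
}
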