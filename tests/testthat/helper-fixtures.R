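# Shared fixtures and independent oracles, all built in code.

# quick sample around a value matrix
makeSample <- function(values, channels = colnames(values), id = "fixture") {
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  CytoSample(id, EventTable(as.matrix(values), channels))
}

# 1D/2D view on raw (linear) values
makeView <- function(x, y = NULL) {
  vals <- if (is.null(y)) cbind(a = x) else cbind(a = x, b = y)
  gateView(makeSample(vals), colnames(vals))
}

# Write a raw FCS file with full control over TEXT keywords and DATA bytes;
# the byte-level oracle for reader tests.
writeRawFCS <- function(path, keywords, dataRaw = raw()) {
  text <- paste0("/", paste(rbind(names(keywords), unlist(keywords)),
                            collapse = "/"), "/")
  textBeg <- 58
  textEnd <- textBeg + nchar(text) - 1
  dataBeg <- if (length(dataRaw)) textEnd + 1 else 0
  dataEnd <- if (length(dataRaw)) dataBeg + length(dataRaw) - 1 else 0
  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                 textBeg, textEnd, dataBeg, dataEnd, 0, 0)
  con <- file(path, "wb")
  writeChar(hdr, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (length(dataRaw)) writeBin(dataRaw, con)
  close(con)
  path
}

baseKeywords <- function(par, tot, datatype, byteord, bits) {
  kw <- list("$MODE" = "L", "$DATATYPE" = datatype, "$BYTEORD" = byteord,
             "$PAR" = as.character(par), "$TOT" = as.character(tot),
             "$NEXTDATA" = "0")
  for (j in seq_len(par)) {
    kw[[sprintf("$P%dN", j)]] <- paste0("ch", j)
    kw[[sprintf("$P%dB", j)]] <- as.character(bits[j])
    kw[[sprintf("$P%dE", j)]] <- "0,0"
    kw[[sprintf("$P%dR", j)]] <- "65536"
  }
  kw
}

# round a vector through float32 storage (the writer's precision)
asFloat32 <- function(x) {
  readBin(writeBin(as.vector(x), raw(), size = 4), "numeric",
          n = length(x), size = 4)
}

# exhaustive enumeration of all x-monotone 3-neighbour paths: the
# shortest-path oracle (feasible for grids up to ~7x7)
enumBestPathCost <- function(costs, penalty) {
  nx <- nrow(costs); ny <- ncol(costs)
  best <- Inf
  rec <- function(x, y, acc) {
    acc <- acc + costs[x, y]
    if (acc >= best) {
      if (x == nx && acc < best) best <<- acc
      if (x == nx) return()
    }
    if (x == nx) { best <<- min(best, acc); return() }
    for (dy in c(-1L, 0L, 1L)) {
      y2 <- y + dy
      if (y2 >= 1 && y2 <= ny) rec(x + 1L, y2, acc + penalty * abs(dy))
    }
  }
  for (y0 in seq_len(ny)) rec(1L, y0, 0)
  best
}

# pure-bisection inversion of the closed-form bi-exponential: the
# independent oracle for the logicle forward direction
bisectLogicle <- function(spec, x, iters = 90) {
  span <- 4 * (spec@M + spec@A)
  lo <- rep(-span, length(x))
  hi <- rep(span, length(x))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    below <- transformInverse(spec, mid) < x
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  (lo + hi) / 2
}

# small clean two-population 2D cloud with labels (for agreement checks)
twoBandCloud <- function(n, sep, seed) {
  set.seed(seed)
  x <- runif(n, 0, 10)
  lab <- rep(c(0L, 1L), length.out = n)
  y <- rnorm(n, mean = ifelse(lab == 1L, sep, 0), sd = 1)
  list(x = x, y = y, labels = lab)
}
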