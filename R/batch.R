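# Batch execution: run a gating strategy over every sample of an experiment
# with optional parallel workers. The contract is scheduling invariance:
# per-sample seeds are derived from the global seed and the sample id, rows
# are ordered by sample id, and outputs are written atomically at the end,
# so results are byte-identical for any worker count.

#' Run a gating strategy across an experiment
#'
#' Each sample is processed independently: load (with compensation per the
#' configuration), apply the strategy, collect per-gate counts and
#' fractions, render QC images of every 2D-view gate. A failure in one
#' sample yields a `failed` row and never touches the others; samples that
#' only warn (e.g. missing spillover) are marked `flagged`.
#'
#' @param experiment A [CytoExperiment-class].
#' @param strategy A function `function(sample, config)` returning the gated
#'   sample, or the name of a strategy registered with
#'   [registerStrategy()].
#' @param workers Parallel worker count; defaults to the configuration's.
#' @param renderImages Render per-gate QC images. Default `TRUE`.
#' @param writeOutputs Write `results.tsv` to the configured output
#'   directory. Default `TRUE`.
#' @return A list with `results` (one row per sample: `sample_id`, `status`,
#'   `error`, then `<gate>_count` and `<gate>_fraction_of_parent` columns),
#'   `images` (per gate, a list of [QCImage-class]) and `flagged` (the
#'   experiment's flag table extended with run-time flags).
#' @export
runExperiment <- function(experiment, strategy, workers = NULL,
                          renderImages = TRUE, writeOutputs = TRUE) {
  stopifnot(is(experiment, "CytoExperiment"))
  if (is.character(strategy)) strategy <- getStrategy(strategy)
  config <- experiment@config
  workers <- workers %||% config@workers
  ids <- sort(setdiff(experiment@sampleIds, experiment@flagged$sample_id),
              method = "radix")
  if (!length(ids))
    cgStop("cg_config_error", "no readable samples to run")

  processOne <- function(id) {
    warnings <- character()
    res <- withCallingHandlers(
      tryCatch({
        sample <- loadSample(experiment, id)
        set.seed(deriveSeed(config@seed, id))
        sample <- strategy(sample, config)
        gates <- sample@gates
        stats <- lapply(gates, function(g) {
          parentN <- length(gateIndices(sample, g@parent))
          list(count = length(g@indices),
               fraction = if (parentN > 0) length(g@indices) / parentN
                          else NA_real_)
        })
        images <- list()
        if (renderImages) {
          for (g in gates) {
            if (length(g@view) != 2) next
            v <- gateView(sample, g@view, parent = g@parent,
                          transforms = config)
            lims <- lapply(g@view, function(ch)
              displayRange(configTransform(config, ch)))
            images[[g@name]] <- renderGateImage(
              v, g@name, id, resolution = config@imageResolution,
              xlim = lims[[1]], ylim = lims[[2]])
          }
        }
        list(status = "ok", error = NA_character_, stats = stats,
             images = images)
      }, error = function(e)
        list(status = "failed", error = conditionMessage(e),
             stats = list(), images = list())),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (res$status == "ok" && length(warnings)) res$status <- "flagged"
    res$warnings <- warnings
    res$id <- id
    res
  }

  records <- if (workers > 1)
    parallel::mclapply(ids, processOne, mc.cores = workers)
  else lapply(ids, processOne)
  names(records) <- ids

  ok <- vapply(records, function(r) r$status %in% c("ok", "flagged"), TRUE)
  if (!any(ok))
    cgStop("cg_run_error", "all %d samples failed", length(ids))

  gateNames <- names(records[[which(ok)[1]]]$stats)
  rows <- lapply(records, function(r) {
    row <- list(sample_id = r$id, status = r$status, error = r$error)
    for (g in gateNames) {
      s <- r$stats[[g]]
      row[[paste0(g, "_count")]] <- if (is.null(s)) NA_integer_ else s$count
      row[[paste0(g, "_fraction_of_parent")]] <-
        if (is.null(s)) NA_real_ else s$fraction
    }
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  images <- list()
  for (g in gateNames) {
    imgs <- lapply(records[ok], function(r) r$images[[g]])
    imgs <- imgs[!vapply(imgs, is.null, TRUE)]
    if (length(imgs)) images[[g]] <- imgs
  }

  flagged <- experiment@flagged
  for (r in records)
    if (length(r$warnings) || r$status == "failed") {
      reason <- if (r$status == "failed") "strategy_failure"
                else if (any(grepl("spillover", r$warnings))) "no_spillover"
                else "warning"
      flagged <- rbind(flagged,
                       data.frame(sample_id = r$id, reason = reason,
                                  stringsAsFactors = FALSE))
    }

  if (writeOutputs) {
    dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
    tmp <- file.path(config@outputDir, ".results.tsv.tmp")
    utils::write.table(results, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    file.rename(tmp, file.path(config@outputDir, "results.tsv"))
  }
  list(results = results, images = images, flagged = flagged)
}

# --- strategy registry ------------------------------------------------------

.strategyRegistry <- new.env(parent = emptyenv())

#' Register a named gating strategy
#'
#' Strategies are user code by design: a function taking a
#' [CytoSample-class] and an [ExperimentConfig-class] and returning the
#' sample with gates attached. Registration makes the strategy addressable
#' from [runExperiment()] and the command line.
#'
#' @param name Strategy name.
#' @param fun The strategy function.
#' @return `name`, invisibly.
#' @export
registerStrategy <- function(name, fun) {
  stopifnot(is.function(fun))
  assign(name, fun, envir = .strategyRegistry)
  invisible(name)
}

#' @rdname registerStrategy
#' @export
listStrategies <- function() sort(ls(.strategyRegistry))

#' @rdname registerStrategy
#' @export
getStrategy <- function(name) {
  if (!exists(name, envir = .strategyRegistry))
    cgStop("cg_lookup_error", "unknown strategy '%s'; registered: %s",
           name, paste(listStrategies(), collapse = ", "))
  get(name, envir = .strategyRegistry)
}
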