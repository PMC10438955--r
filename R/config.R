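#' Construct an experiment configuration
#'
#' @param compensationMode `"from_file"` (use the `$SPILLOVER` keyword when
#'   present), `"external"` (read `externalSpilloverPath`), or `"none"`.
#' @param externalSpilloverPath Path to a tab-separated spillover file;
#'   required when `compensationMode == "external"`.
#' @param transforms Named list of [TransformSpec-class] per channel.
#'   Channels without an entry are viewed on the linear scale.
#' @param outputDir Directory for results and diagnostic output; created on
#'   demand by the batch runner.
#' @param imageResolution QC image side length in pixels (>= 8). Default 32.
#' @param workers Default parallel worker count. Default 1.
#' @param seed Global seed for all stochastic steps. Default 1.
#' @return An [ExperimentConfig-class].
#' @export
experimentConfig <- function(compensationMode = c("from_file", "external", "none"),
                             externalSpilloverPath = NA_character_,
                             transforms = list(),
                             outputDir = tempfile("cytogate_run_"),
                             imageResolution = 32L,
                             workers = 1L,
                             seed = 1L) {
  compensationMode <- match.arg(compensationMode)
  if (compensationMode == "external" &&
      (is.na(externalSpilloverPath) || !file.exists(externalSpilloverPath)))
    cgStop("cg_config_error",
           "compensationMode 'external' requires an existing externalSpilloverPath")
  new("ExperimentConfig",
      compensationMode = compensationMode,
      externalSpilloverPath = as.character(externalSpilloverPath),
      transforms = transforms,
      outputDir = outputDir,
      imageResolution = asCount(imageResolution, "imageResolution"),
      workers = asCount(workers, "workers"),
      seed = asCount(seed, "seed"))
}

#' Read an experiment configuration file
#'
#' YAML or JSON with keys `compensation_mode`, `external_spillover_path`,
#' `transforms` (channel name to `{kind, ...}` lists, see
#' [transformFromList()]), `output_dir`, `image_resolution`, `workers`,
#' `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [ExperimentConfig-class].
#' @export
readExperimentConfig <- function(path) {
  if (!file.exists(path))
    cgStop("cg_config_error", "configuration file does not exist: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  tf <- lapply(raw$transforms %||% list(), transformFromList)
  experimentConfig(
    compensationMode = raw$compensation_mode %||% "from_file",
    externalSpilloverPath = raw$external_spillover_path %||% NA_character_,
    transforms = tf,
    outputDir = raw$output_dir %||% tempfile("cytogate_run_"),
    imageResolution = raw$image_resolution %||% 32L,
    workers = raw$workers %||% 1L,
    seed = raw$seed %||% 1L)
}

#' Write an experiment configuration file
#' @param config An [ExperimentConfig-class].
#' @param path Output `.yaml` or `.json` path.
#' @return `path`, invisibly.
#' @export
writeExperimentConfig <- function(config, path) {
  x <- list(
    compensation_mode = config@compensationMode,
    external_spillover_path = if (is.na(config@externalSpilloverPath)) NULL
                              else config@externalSpilloverPath,
    transforms = lapply(config@transforms, transformToList),
    output_dir = config@outputDir,
    image_resolution = config@imageResolution,
    workers = config@workers,
    seed = config@seed)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

# transform lookup with linear fallback
configTransform <- function(config, channel) {
  config@transforms[[channel]] %||% linearTransform()
}

#' Default per-channel display transforms
#'
#' Scatter (`FSC*`, `SSC*`) and `Time` channels are viewed linearly;
#' fluorescence channels on a Bilog scale. `decades` should match the
#' instrument's dynamic range above `linBound` — the default (3, i.e. top of
#' scale `linBound * 10^3`) suits the reference panel; stretching axes far
#' beyond the data wastes display area and QC image contrast.
#'
#' @param channels Channel names.
#' @param linBound,decades Bilog parameters for fluorescence channels.
#' @return Named list of [TransformSpec-class].
#' @export
defaultTransforms <- function(channels, linBound = 500, decades = 3) {
  out <- lapply(channels, function(ch) {
    if (grepl("^(FSC|SSC)", ch) || identical(ch, "Time")) linearTransform()
    else bilogTransform(linBound, decades)
  })
  names(out) <- channels
  out
}
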