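#' Pipeline configuration
#'
#' Bundles the analysis parameters shared by all pipeline stages. Defaults
#' are the standard analysis settings: 20 ms windows, 90% overlap, 5 Hz
#' bins, a 200--700 Hz female search band, 10,000 bootstrap trials of 60
#' windows each.
#'
#' @param spectrogram A \code{\link{spectrogram_params}} object.
#' @param bin_width,range Distribution binning (Hz).
#' @param epsilon Reference-library smoothing floor (default 0).
#' @param subset_size,n_trials Bootstrap parameters.
#' @param detection_threshold_db,gap_tolerance_s Peak-tracking parameters.
#' @param seed RNG seed; mandatory for the stochastic subcommands so every
#'   run is reproducible (no wall-clock seeding).
#' @param library_path,location_matrix_path Optional file paths used by the
#'   command-line subcommands.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(spectrogram = spectrogram_params(),
                            bin_width = 5, range = c(200, 700),
                            epsilon = 0, subset_size = 60, n_trials = 10000,
                            detection_threshold_db = 6,
                            gap_tolerance_s = 0.25, seed = 1,
                            library_path = NULL,
                            location_matrix_path = NULL) {
  stopifnot(inherits(spectrogram, "spectrogram_params"))
  structure(
    list(spectrogram = spectrogram, bin_width = bin_width, range = range,
         epsilon = epsilon, subset_size = subset_size, n_trials = n_trials,
         detection_threshold_db = detection_threshold_db,
         gap_tolerance_s = gap_tolerance_s, seed = seed,
         library_path = library_path,
         location_matrix_path = location_matrix_path),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field omitted from the file keeps its default. Spectrogram settings
#' live under a \code{spectrogram:} key.
#'
#' @param path YAML file path.
#' @return A \code{\link{pipeline_config}}.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sp_args <- y$spectrogram
  sp <- if (is.null(sp_args)) spectrogram_params()
        else do.call(spectrogram_params, lapply(sp_args, unlist))
  y$spectrogram <- NULL
  y <- lapply(y, unlist)
  do.call(pipeline_config, c(list(spectrogram = sp), y))
}

#' Analyze a recording into flight traces
#'
#' The standard front half of the pipeline: resample to 44.1 kHz if below,
#' compute the zero-padded spectrogram, subtract stationary background, and
#' track per-window peak frequencies into flight traces.
#'
#' @param rec An \code{\link{audio_recording}} or a WAV file path.
#' @param config A \code{\link{pipeline_config}}.
#' @return A list with \code{traces} (list of \code{flight_trace}),
#'   \code{spectrogram} (denoised), \code{noise} (profile) and \code{snr_db}
#'   (per-trace SNR estimates).
#' @export
analyze_recording <- function(rec, config = pipeline_config()) {
  if (is.character(rec)) rec <- read_wav(rec)
  stopifnot(inherits(rec, "audio_recording"))
  rec <- resample_to_standard(rec, max(rec$sample_rate, 44100))
  spec <- compute_spectrogram(rec, config$spectrogram)
  den <- subtract_background(spec)
  traces <- extract_flight_traces(
    den$spectrogram, config$spectrogram,
    detection_threshold_db = config$detection_threshold_db,
    gap_tolerance_s = config$gap_tolerance_s,
    noise = den$noise, source = rec$source)
  snr <- vapply(traces, function(tr) estimate_snr(spec, tr, den$noise),
                numeric(1))
  list(traces = traces, spectrogram = den$spectrogram, noise = den$noise,
       snr_db = snr)
}

#' Run a pipeline subcommand
#'
#' The programmatic core behind the \code{wingbeatr} command-line script
#' (\code{system.file("cli", "wingbeatr.R", package = "wingbeatr")}). Each
#' subcommand maps a stage of the pipeline onto files:
#' \describe{
#'   \item{analyze}{WAV file(s) -> flight-trace CSV.}
#'   \item{build-reference}{trace CSVs (one species per file, named
#'     \code{<species>.csv}) -> reference distribution CSV.}
#'   \item{classify}{WAV or trace CSV + library (+ optional location
#'     matrix) -> classification JSON.}
#'   \item{validate}{library distribution CSV + raw trace CSVs ->
#'     bootstrap (and optionally K-fold) confusion CSV.}
#'   \item{simulate}{species spec YAML -> WAV files + manifest CSV.}
#'   \item{map}{classification results CSV -> GeoJSON + CSV summary.}
#' }
#'
#' @param name Subcommand name.
#' @param config A \code{\link{pipeline_config}}.
#' @param inputs Character vector of input paths (interpretation depends on
#'   the subcommand).
#' @param output Output path (file or stem, depending on the subcommand).
#' @param country Optional ISO country code for \code{classify}.
#' @return Exit status, invisibly: 0 ok, 1 input error, 2 processing error.
#' @export
run_subcommand <- function(name, config = pipeline_config(), inputs,
                           output, country = NULL) {
  name <- match.arg(name, c("analyze", "build-reference", "classify",
                            "validate", "simulate", "map"))
  status <- tryCatch({
    switch(name,
      "analyze" = cmd_analyze(config, inputs, output),
      "build-reference" = cmd_build_reference(config, inputs, output),
      "classify" = cmd_classify(config, inputs, output, country),
      "validate" = cmd_validate(config, inputs, output),
      "simulate" = cmd_simulate(config, inputs, output),
      "map" = cmd_map(config, inputs, output))
    0L
  }, error = function(e) {
    message("error [", name, "]: ", conditionMessage(e))
    if (grepl("not found|missing|needs|no such", conditionMessage(e),
              ignore.case = TRUE)) 1L else 2L
  })
  invisible(status)
}

cmd_analyze <- function(config, inputs, output) {
  all_traces <- list(); all_snr <- numeric(0)
  for (p in inputs) {
    res <- analyze_recording(p, config)
    message(sprintf("analyze: %s -> %d trace(s)", p, length(res$traces)))
    all_traces <- c(all_traces, res$traces)
    all_snr <- c(all_snr, res$snr_db)
  }
  write_traces_csv(all_traces, output,
                   snr_db = if (length(all_snr)) all_snr else NA_real_)
}

cmd_build_reference <- function(config, inputs, output) {
  dists <- lapply(inputs, function(p) {
    traces <- read_traces_csv(p)
    freqs <- unlist(lapply(traces, function(tr) tr$frequencies))
    build_distribution(freqs, bin_width = config$bin_width,
                       range = config$range,
                       label = sub("\\.csv$", "", basename(p)))
  })
  write_distribution_csv(dists, output)
}

cmd_classify <- function(config, inputs, output, country) {
  if (is.null(config$library_path))
    stop("classify needs config$library_path", call. = FALSE)
  lib <- reference_library(read_distribution_csv(config$library_path),
                           epsilon = config$epsilon)
  locmat <- if (!is.null(config$location_matrix_path))
    read_location_csv(config$location_matrix_path) else NULL
  results <- lapply(inputs, function(p) {
    traces <- if (grepl("\\.csv$", p)) read_traces_csv(p)
              else analyze_recording(p, config)$traces
    lapply(traces, function(tr) {
      r <- classify_trace(tr, lib, matrix = locmat, country = country)
      list(file = p, trace_id = tr$trace_id, predicted = r$predicted_species,
           confidence = unname(r$confidence[r$predicted_species]),
           tie = r$tie, candidates = r$candidates_after_filter,
           filter_applied = r$filter_applied, country = r$country)
    })
  })
  jsonlite::write_json(do.call(c, results), output, auto_unbox = TRUE,
                       digits = NA)
}

cmd_validate <- function(config, inputs, output) {
  raw <- lapply(inputs, function(p) {
    traces <- read_traces_csv(p)
    unlist(lapply(traces, function(tr) tr$frequencies))
  })
  names(raw) <- sub("\\.csv$", "", basename(inputs))
  dists <- lapply(names(raw), function(s)
    build_distribution(raw[[s]], bin_width = config$bin_width,
                       range = config$range, label = s))
  lib <- reference_library(dists, epsilon = config$epsilon)
  cm <- bootstrap_confusion_matrix(lib, raw, n_trials = config$n_trials,
                                   subset_size = config$subset_size,
                                   seed = config$seed)
  write_confusion_csv(cm, output)
}

cmd_simulate <- function(config, inputs, output) {
  y <- yaml::read_yaml(inputs[1])
  specs <- lapply(y$species, function(s) do.call(synthetic_species, s))
  area <- unlist(y$area %||% c(37.15, 37.20, -122.25, -122.20))
  ds <- generate_survey_dataset(
    specs, n_recordings = y$n_recordings %||% 10, area = area,
    date = y$date %||% "2016-08-17", seed = config$seed,
    audio = TRUE, duration_s = y$duration_s %||% 2,
    sample_rate = y$sample_rate %||% 8000, snr_db = y$snr_db)
  write_survey_dataset(ds, output)
}

cmd_map <- function(config, inputs, output) {
  df <- utils::read.csv(inputs[1])
  if (!"species" %in% names(df) && "predicted" %in% names(df))
    df$species <- df$predicted
  map <- aggregate_survey(df)
  export_map(map, output)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
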