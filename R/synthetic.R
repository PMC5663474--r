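#' Specification of a synthetic mosquito species
#'
#' Parameterizes the generator that emulates species-specific flight tones:
#' a harmonic stack on a wandering fundamental. Between-individual
#' variation (\code{population_sd}) and within-trace wander
#' (\code{intra_trace_wander_sd}, an AR(1) mean-reverting walk per 20 ms
#' window) are separate knobs, mirroring the observation that a
#' population's frequency spread exceeds any single trace's. Every trace is
#' guaranteed a minimum relative spread (default 2% of its mean), the
#' natural floor observed in free flight.
#'
#' @param name Species label.
#' @param base_center Population-mean fundamental in Hz (200--700 for
#'   females).
#' @param population_sd Between-individual SD of the fundamental, Hz
#'   (default 15).
#' @param intra_trace_wander_sd Innovation SD of the per-window AR(1)
#'   frequency walk, Hz (default 3).
#' @param mean_reversion AR(1) pull toward the individual's mean per
#'   window, in (0, 1] (default 0.15; the AR coefficient is
#'   \code{1 - mean_reversion}).
#' @param min_relative_spread Minimum (q95 - q5) spread of a trace as a
#'   fraction of its mean frequency (default 0.02).
#' @param n_overtones Number of harmonics above the fundamental (default 3).
#' @param overtone_decay_db Level drop per successive harmonic, dB
#'   (default 10).
#' @param amplitude_dbfs Fundamental amplitude in dB full scale
#'   (default -20).
#' @param activity_profile 24 non-negative hourly activity weights
#'   (default: dusk-biased, peaking 18:00--20:00).
#' @param countries_present ISO-3166 codes where the species occurs.
#' @return An object of class \code{synthetic_species}.
#' @export
synthetic_species <- function(name, base_center,
                              population_sd = 15,
                              intra_trace_wander_sd = 3,
                              mean_reversion = 0.15,
                              min_relative_spread = 0.02,
                              n_overtones = 3,
                              overtone_decay_db = 10,
                              amplitude_dbfs = -20,
                              activity_profile = NULL,
                              countries_present = "MG") {
  if (is.null(activity_profile)) {
    activity_profile <- rep(0.2, 24)
    activity_profile[18:21] <- c(1, 2, 2, 1)   # crepuscular peak
  }
  stopifnot(base_center > 0, population_sd >= 0, intra_trace_wander_sd >= 0,
            mean_reversion > 0, mean_reversion <= 1,
            min_relative_spread >= 0, n_overtones >= 0,
            length(activity_profile) == 24, all(activity_profile >= 0),
            sum(activity_profile) > 0, amplitude_dbfs <= 0)
  structure(
    list(name = name, base_center = base_center,
         population_sd = population_sd,
         intra_trace_wander_sd = intra_trace_wander_sd,
         mean_reversion = mean_reversion,
         min_relative_spread = min_relative_spread,
         n_overtones = n_overtones, overtone_decay_db = overtone_decay_db,
         amplitude_dbfs = amplitude_dbfs,
         activity_profile = activity_profile,
         countries_present = toupper(countries_present)),
    class = "synthetic_species")
}

# Mean-reverting AR(1) frequency track, one value per 20 ms window, with a
# deterministic rescale that enforces the species' minimum relative spread.
wander_track <- function(spec, n_windows, center = spec$base_center) {
  phi <- 1 - spec$mean_reversion
  f <- numeric(n_windows)
  # start at the stationary distribution so short traces are unbiased
  sd_stat <- spec$intra_trace_wander_sd / sqrt(max(1e-12, 1 - phi^2))
  f[1] <- center + stats::rnorm(1, 0, sd_stat)
  if (n_windows > 1) {
    innov <- stats::rnorm(n_windows - 1, 0, spec$intra_trace_wander_sd)
    for (w in 2:n_windows)
      f[w] <- center + phi * (f[w - 1] - center) + innov[w - 1]
  }
  min_spread <- spec$min_relative_spread * center
  if (n_windows >= 2 && min_spread > 0) {
    q <- stats::quantile(f, c(0.05, 0.95), names = FALSE, type = 1)
    spread <- q[2] - q[1]
    if (spread < min_spread) {
      scale <- if (spread > 0) min_spread / spread else 1
      f <- mean(f) + (f - mean(f)) * scale
      if (spread == 0) f <- f + seq(-min_spread / 2, min_spread / 2,
                                    length.out = n_windows)
    }
  }
  f
}

#' Synthesize a wingbeat recording
#'
#' Generates a phase-continuous harmonic stack whose instantaneous
#' fundamental follows the species' mean-reverting frequency walk, with
#' 10 ms cosine onset/offset ramps to avoid clicks that would confound peak
#' finding. Deterministic under \code{seed}.
#'
#' @param spec A \code{\link{synthetic_species}}.
#' @param duration_s Duration in seconds (>= 0.1).
#' @param sample_rate Sampling rate in Hz (>= 8000; default 8000, which
#'   keeps four harmonics of any female fundamental below Nyquist).
#' @param seed RNG seed (optional).
#' @param individual_center Fundamental mean for this individual (Hz);
#'   default draws one from the species' population distribution.
#' @param metadata Optional \code{\link{recording_metadata}}.
#' @return An \code{\link{audio_recording}} with attribute
#'   \code{true_frequencies}, the per-window ground-truth fundamental.
#' @export
synthesize_recording <- function(spec, duration_s, sample_rate = 8000,
                                 seed = NULL, individual_center = NULL,
                                 metadata = NULL) {
  stopifnot(inherits(spec, "synthetic_species"), duration_s >= 0.1,
            sample_rate >= 8000)
  if (spec$base_center * (spec$n_overtones + 1) >= sample_rate / 2)
    stop("harmonic stack exceeds Nyquist: lower n_overtones or raise ",
         "sample_rate", call. = FALSE)
  with_seed(seed, {
    center <- if (is.null(individual_center))
      stats::rnorm(1, spec$base_center, spec$population_sd)
    else individual_center
    window_s <- 0.020
    n_windows <- max(2L, ceiling(duration_s / window_s))
    f_win <- wander_track(spec, n_windows, center)
    n <- round(duration_s * sample_rate)
    t_win <- (seq_len(n_windows) - 0.5) * window_s
    f_inst <- stats::approx(t_win, f_win, xout = (seq_len(n) - 0.5) / sample_rate,
                            rule = 2)$y
    phase <- 2 * pi * cumsum(f_inst) / sample_rate
    amp <- 10^(spec$amplitude_dbfs / 20)
    harm_amp <- amp * 10^(-(0:spec$n_overtones) * spec$overtone_decay_db / 20)
    x <- numeric(n)
    for (k in 0:spec$n_overtones)
      x <- x + harm_amp[k + 1] * sin((k + 1) * phase)
    peak <- sum(harm_amp)
    if (peak > 1) x <- x / peak
    ramp_n <- min(round(0.010 * sample_rate), n %/% 2)
    if (ramp_n > 0) {
      ramp <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
      x[seq_len(ramp_n)] <- x[seq_len(ramp_n)] * ramp
      x[n - ramp_n + seq_len(ramp_n)] <- x[n - ramp_n + seq_len(ramp_n)] * rev(ramp)
    }
    rec <- audio_recording(x, sample_rate, metadata = metadata,
                           source = paste0("synthetic:", spec$name))
    attr(rec, "true_frequencies") <- f_win
    attr(rec, "species") <- spec$name
    rec
  })
}

#' Background-noise specification
#'
#' @param broadband_level_dbfs White-noise RMS level in dB full scale
#'   (default -40); used when no target SNR is requested.
#' @param hum_bands List of \code{c(frequency_hz, level_dbfs)} pairs for
#'   constant hum tones (default a single 60 Hz mains hum at -30 dBFS).
#' @param transient_rate Short broadband click events per second
#'   (default 0).
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(broadband_level_dbfs = -40,
                       hum_bands = list(c(60, -30)),
                       transient_rate = 0) {
  stopifnot(broadband_level_dbfs <= 0, transient_rate >= 0)
  for (h in hum_bands) stopifnot(length(h) == 2, h[2] <= 0)
  structure(list(broadband_level_dbfs = broadband_level_dbfs,
                 hum_bands = hum_bands, transient_rate = transient_rate),
            class = "noise_spec")
}

#' Add background noise to a recording
#'
#' Mixes white noise and constant hum tones into a recording. When
#' \code{target_snr_db} is given, the broadband level is chosen so the
#' spectrogram-domain SNR -- the ratio of the signal's fundamental-bin
#' power to the mean per-bin noise power in the search band, the same
#' quantity \code{\link{estimate_snr}} reports -- hits the target.
#' Deterministic under \code{seed}.
#'
#' @param rec A clean \code{\link{audio_recording}}.
#' @param noise A \code{\link{noise_spec}}.
#' @param target_snr_db Desired in-band SNR in dB (optional; otherwise the
#'   spec's absolute broadband level is used).
#' @param seed RNG seed (optional).
#' @param params \code{\link{spectrogram_params}} defining the window and
#'   band the SNR target refers to.
#' @return The noisy \code{\link{audio_recording}} (attributes preserved).
#' @export
add_noise <- function(rec, noise = noise_spec(), target_snr_db = NULL,
                      seed = NULL, params = spectrogram_params()) {
  stopifnot(inherits(rec, "audio_recording"), inherits(noise, "noise_spec"))
  n <- length(rec$samples)
  fs <- rec$sample_rate
  with_seed(seed, {
    if (!is.null(target_snr_db)) {
      # peak fundamental power of the clean signal, in spectrogram units
      sp <- compute_spectrogram(rec, params)
      band <- sp$freqs >= params$search_band[1] &
        sp$freqs <= params$search_band[2]
      p_sig <- stats::median(apply(sp$magnitude[band, , drop = FALSE], 2, max))
      if (p_sig <= 0) stop("cannot set SNR: no in-band signal", call. = FALSE)
      # white noise of variance v has expected per-bin power
      # v * sum(w^2) / (sum(w)/2)^2 / 4 under the spectrogram normalization
      win_n <- round(params$window_s * fs)
      w <- hann_window(win_n)
      bin_gain <- sum(w^2) / (sum(w) / 2)^2 / 4
      v <- p_sig / 10^(target_snr_db / 10) / bin_gain
      sigma <- sqrt(v)
    } else {
      sigma <- 10^(noise$broadband_level_dbfs / 20)
    }
    mix <- stats::rnorm(n, 0, sigma)
    tt <- (seq_len(n) - 1) / fs
    for (h in noise$hum_bands)
      mix <- mix + 10^(h[2] / 20) * sin(2 * pi * h[1] * tt)
    if (noise$transient_rate > 0) {
      n_ev <- stats::rpois(1, noise$transient_rate * n / fs)
      for (e in seq_len(n_ev)) {
        at <- sample.int(n - 40L, 1)
        mix[at:(at + 39L)] <- mix[at:(at + 39L)] +
          stats::rnorm(40, 0, 10 * sigma)
      }
    }
    y <- rec$samples + mix
    if (max(abs(y)) > 1)
      stop("target SNR unreachable without clipping", call. = FALSE)
    out <- audio_recording(y, fs, metadata = rec$metadata, source = rec$source)
    attr(out, "true_frequencies") <- attr(rec, "true_frequencies")
    attr(out, "species") <- attr(rec, "species")
    out
  })
}

#' Generate a synthetic reference population
#'
#' Draws \code{n_individuals} individual mean frequencies from the species'
#' population distribution, runs the per-window wander process for each,
#' and pools all windows into a reference frequency distribution --
#' emulating how real references are built from minutes of caged-population
#' recordings.
#'
#' @param spec A \code{\link{synthetic_species}}.
#' @param n_individuals Number of individuals (>= 1).
#' @param windows_per_individual 20 ms windows recorded per individual.
#' @param seed RNG seed (optional).
#' @param bin_width,range Binning for the pooled distribution.
#' @return A list with \code{frequencies} (pooled raw values),
#'   \code{individual} (integer index per value), and \code{distribution}
#'   (a \code{freq_distribution} labelled with the species name).
#' @export
generate_reference_population <- function(spec, n_individuals,
                                          windows_per_individual,
                                          seed = NULL, bin_width = 5,
                                          range = c(200, 700)) {
  stopifnot(inherits(spec, "synthetic_species"), n_individuals >= 1,
            windows_per_individual >= 1)
  with_seed(seed, {
    centers <- stats::rnorm(n_individuals, spec$base_center,
                            spec$population_sd)
    per <- lapply(centers, function(cc)
      wander_track(spec, windows_per_individual, cc))
    freqs <- unlist(per)
    list(frequencies = freqs,
         individual = rep(seq_len(n_individuals),
                          each = windows_per_individual),
         distribution = build_distribution(freqs, bin_width = bin_width,
                                           range = range, label = spec$name))
  })
}

#' Generate a synthetic crowdsourced survey dataset
#'
#' Emulates a field exercise: volunteers distributed over a bounding box
#' record mosquitoes over a day, with species drawn by relative abundance,
#' timestamps by each species' hourly activity profile, and locations by
#' optional per-cell spatial weights. Ground truth is retained for every
#' recording. With \code{audio = TRUE} each recording carries synthesized
#' (optionally noisy) audio; otherwise only the ground-truth per-window
#' frequency trace is stored, which is much faster for large n.
#'
#' @param specs List of \code{\link{synthetic_species}}.
#' @param n_recordings Number of recordings (>= 1).
#' @param area Bounding box \code{c(lat_min, lat_max, lon_min, lon_max)}.
#' @param date Date of the exercise (\code{Date} or "YYYY-MM-DD" string).
#' @param seed RNG seed (optional).
#' @param abundance Relative abundance weights per species (default equal).
#' @param spatial_weights Optional numeric matrix of relative sampling
#'   weights over a grid of cells tiling the box (rows = latitude bands,
#'   south to north; columns = longitude bands, west to east).
#' @param audio Synthesize audio for each recording (default \code{FALSE}).
#' @param duration_s,sample_rate,snr_db Audio parameters when
#'   \code{audio = TRUE}; \code{snr_db = NULL} leaves recordings clean.
#' @param zero_encounter_fraction Fraction of additional "no mosquito here"
#'   reports to include (default 0.1), mirroring hikers reporting sites
#'   without encounters.
#' @return An object of class \code{survey_dataset}: \code{manifest} (a
#'   data.frame with file, species_truth, timestamp, lat, lon, country,
#'   is_zero_encounter), \code{recordings} (list of audio recordings or
#'   \code{NULL}s), \code{traces} (ground-truth frequency vectors), and
#'   \code{area}.
#' @export
generate_survey_dataset <- function(specs, n_recordings, area,
                                    date = "2016-08-17", seed = NULL,
                                    abundance = NULL, spatial_weights = NULL,
                                    audio = FALSE, duration_s = 2,
                                    sample_rate = 8000, snr_db = NULL,
                                    zero_encounter_fraction = 0.1) {
  stopifnot(length(specs) >= 1, n_recordings >= 1, length(area) == 4)
  if (area[1] >= area[2] || area[3] >= area[4])
    stop("empty bounding box", call. = FALSE)
  for (s in specs) stopifnot(inherits(s, "synthetic_species"))
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  if (is.null(abundance)) abundance <- rep(1, length(specs))
  date <- as.Date(date)
  with_seed(seed, {
    which_sp <- sample(seq_along(specs), n_recordings, replace = TRUE,
                       prob = abundance)
    hours <- vapply(which_sp, function(i)
      sample(0:23, 1, prob = specs[[i]]$activity_profile), numeric(1))
    ts <- as.POSIXct(date, tz = "UTC") + hours * 3600 +
      stats::runif(n_recordings, 0, 3600)
    pos <- sample_positions(n_recordings, area, spatial_weights)
    country <- vapply(which_sp, function(i) specs[[i]]$countries_present[1],
                      character(1))
    traces <- vector("list", n_recordings)
    recs <- vector("list", n_recordings)
    n_windows <- max(2L, ceiling(duration_s / 0.020))
    for (r in seq_len(n_recordings)) {
      sp <- specs[[which_sp[r]]]
      if (audio) {
        rec <- synthesize_recording(sp, duration_s, sample_rate)
        if (!is.null(snr_db))
          rec <- add_noise(rec, noise_spec(hum_bands = list(c(60, -30))),
                           target_snr_db = snr_db)
        md <- recording_metadata(timestamp = ts[r], latitude = pos$lat[r],
                                 longitude = pos$lon[r],
                                 country = country[r],
                                 capture_mode = "free_flight")
        rec$metadata <- validate_metadata(md)
        recs[[r]] <- rec
        traces[[r]] <- attr(rec, "true_frequencies")
      } else {
        center <- stats::rnorm(1, sp$base_center, sp$population_sd)
        traces[[r]] <- wander_track(sp, n_windows, center)
      }
    }
    n_zero <- round(zero_encounter_fraction * n_recordings)
    zero_pos <- sample_positions(n_zero, area, spatial_weights)
    manifest <- data.frame(
      file = c(sprintf("rec_%04d.wav", seq_len(n_recordings)),
               rep(NA_character_, n_zero)),
      species_truth = c(names(specs)[which_sp], rep(NA_character_, n_zero)),
      timestamp = c(ts, as.POSIXct(date, tz = "UTC") +
                      stats::runif(n_zero, 0, 86400)),
      lat = c(pos$lat, zero_pos$lat),
      lon = c(pos$lon, zero_pos$lon),
      country = c(country, rep(specs[[1]]$countries_present[1], n_zero)),
      is_zero_encounter = c(rep(FALSE, n_recordings), rep(TRUE, n_zero)),
      stringsAsFactors = FALSE)
    structure(list(manifest = manifest, recordings = recs, traces = traces,
                   area = area, specs = specs),
              class = "survey_dataset")
  })
}

sample_positions <- function(n, area, weights = NULL) {
  if (n == 0) return(list(lat = numeric(0), lon = numeric(0)))
  if (is.null(weights)) {
    return(list(lat = stats::runif(n, area[1], area[2]),
                lon = stats::runif(n, area[3], area[4])))
  }
  nr <- nrow(weights); nc <- ncol(weights)
  cell <- sample.int(nr * nc, n, replace = TRUE, prob = as.numeric(weights))
  ri <- (cell - 1L) %% nr + 1L
  ci <- (cell - 1L) %/% nr + 1L
  lat_w <- (area[2] - area[1]) / nr
  lon_w <- (area[4] - area[3]) / nc
  list(lat = area[1] + (ri - 1) * lat_w + stats::runif(n, 0, lat_w),
       lon = area[3] + (ci - 1) * lon_w + stats::runif(n, 0, lon_w))
}

#' Write a survey dataset to disk
#'
#' WAV files (when audio was synthesized) plus a manifest CSV with columns
#' file, species_truth, timestamp, lat, lon, country, is_zero_encounter.
#'
#' @param dataset A \code{survey_dataset}.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_survey_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(dataset$recordings)) {
    if (!is.null(dataset$recordings[[r]]))
      write_wav(dataset$recordings[[r]],
                file.path(dir, dataset$manifest$file[r]))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(dataset$manifest, path, row.names = FALSE)
  invisible(path)
}
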