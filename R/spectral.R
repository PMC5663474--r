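#' Spectrogram analysis parameters
#'
#' Defaults follow the pipeline's standard analysis settings: 20 ms Hann
#' windows with 90% overlap, 5 Hz frequency bins (achieved by zero-padding
#' each frame), and a 200--700 Hz search band covering female wingbeat
#' fundamentals.
#'
#' @param window_s Analysis window length in seconds (default 0.020).
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in \code{[0, 1)} (default 0.90, i.e. a 2 ms hop).
#' @param freq_bin_hz Frequency bin spacing in Hz (default 5). A 20 ms frame
#'   natively resolves 50 Hz; the finer spacing is obtained by zero-padding
#'   each frame to \code{sample_rate / freq_bin_hz} points, which
#'   interpolates the spectrum without lengthening the analysis window.
#' @param window_function Analysis taper; only \code{"hann"} is provided.
#' @param search_band Two-element numeric, the fundamental-frequency search
#'   band in Hz (default \code{c(200, 700)} for females).
#' @param max_freq_hz Highest frequency bin retained in the spectrogram
#'   (default 2200 Hz: room for the third overtone of a 700 Hz fundamental
#'   without storing bins up to Nyquist).
#' @return An object of class \code{spectrogram_params}.
#' @export
spectrogram_params <- function(window_s = 0.020, overlap_fraction = 0.90,
                               freq_bin_hz = 5, window_function = "hann",
                               search_band = c(200, 700),
                               max_freq_hz = 2200) {
  stopifnot(window_s > 0, overlap_fraction >= 0, overlap_fraction < 1,
            freq_bin_hz > 0, length(search_band) == 2,
            search_band[1] < search_band[2], max_freq_hz > search_band[2])
  window_function <- match.arg(window_function, "hann")
  structure(list(window_s = window_s, overlap_fraction = overlap_fraction,
                 freq_bin_hz = freq_bin_hz, window_function = window_function,
                 search_band = search_band, max_freq_hz = max_freq_hz),
            class = "spectrogram_params")
}

#' Compute a zero-padded short-time Fourier spectrogram
#'
#' Frames the recording into overlapping Hann-tapered windows, zero-pads
#' each frame so the FFT bin spacing equals \code{params$freq_bin_hz}, and
#' returns linear power magnitudes. Power is normalized so a unit-amplitude
#' sinusoid at a bin center has peak bin power 0.25 (i.e. \code{(A/2)^2}),
#' independent of window length.
#'
#' @param rec An \code{\link{audio_recording}}.
#' @param params A \code{\link{spectrogram_params}} object.
#' @return An object of class \code{spectrogram} with fields \code{times}
#'   (window-center seconds), \code{freqs} (bin-center Hz), \code{magnitude}
#'   (freq x time power matrix), plus the generating parameters.
#' @export
compute_spectrogram <- function(rec, params = spectrogram_params()) {
  stopifnot(inherits(rec, "audio_recording"),
            inherits(params, "spectrogram_params"))
  fs <- rec$sample_rate
  win_n <- round(params$window_s * fs)
  if (length(rec$samples) < win_n)
    stop("recording shorter than one analysis window", call. = FALSE)
  hop <- max(1L, round(win_n * (1 - params$overlap_fraction)))
  nfft <- max(win_n, round(fs / params$freq_bin_hz))
  w <- hann_window(win_n)
  starts <- seq(1L, length(rec$samples) - win_n + 1L, by = hop)
  frames <- matrix(0, nrow = nfft, ncol = length(starts))
  idx <- 0:(win_n - 1L)
  for (j in seq_along(starts))
    frames[seq_len(win_n), j] <- rec$samples[starts[j] + idx] * w
  spec <- stats::mvfft(frames)
  keep <- seq_len(min(floor(params$max_freq_hz / (fs / nfft)) + 1L,
                      floor(nfft / 2) + 1L))
  # scaled so a tone of amplitude A at a bin center peaks at (A/2)^2,
  # independent of window length
  mag <- Mod(spec[keep, , drop = FALSE])^2 / (sum(w) / 2)^2 / 4
  structure(
    list(times = (starts - 1 + win_n / 2) / fs,
         freqs = (keep - 1L) * fs / nfft,
         magnitude = mag,
         params = params, sample_rate = fs,
         hop_s = hop / fs, stride_factor = max(1L, round(win_n / hop))),
    class = "spectrogram")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freq bins x %d windows, %.1f Hz x %.1f ms\n",
              nrow(x$magnitude), ncol(x$magnitude),
              x$freqs[2] - x$freqs[1], 1000 * x$hop_s))
  invisible(x)
}

#' Spectral subtraction of stationary background
#'
#' Identifies spectral bands that are essentially constant in amplitude over
#' the whole clip (temporal coefficient of variation below
#' \code{cv_threshold} while persistently above the broadband floor) and
#' subtracts each such bin's median magnitude across all windows. A
#' broadband floor (the global median magnitude) is additionally subtracted
#' from every bin. Output magnitudes are floored at zero. A wandering
#' wingbeat tone, whose frequency spreads by at least ~2% of its mean, never
#' satisfies the constancy test and so is left intact.
#'
#' @param spec A \code{\link{spectrogram}} with at least 10 time windows.
#' @param cv_threshold Temporal coefficient-of-variation bound below which a
#'   persistent bin is treated as constant background (default 0.1).
#' @param persistence_fraction Fraction of windows a bin must stay above the
#'   broadband floor to count as persistent (default 0.9).
#' @param oversubtraction Multiple of the background bin's median magnitude
#'   subtracted (default 2, the classic spectral-subtraction over-subtraction
#'   factor): window-phase interference between the positive- and
#'   negative-frequency lobes of a low-frequency hum leaves ~10% temporal
#'   ripple around the median, which plain median subtraction would retain.
#' @return A list with components \code{spectrogram} (denoised) and
#'   \code{noise} (a \code{noise_profile}: per-bin background magnitude,
#'   temporal variance, per-bin mean, and logical \code{is_background}).
#' @export
subtract_background <- function(spec, cv_threshold = 0.1,
                                persistence_fraction = 0.9,
                                oversubtraction = 2) {
  stopifnot(inherits(spec, "spectrogram"))
  mag <- spec$magnitude
  if (ncol(mag) < 10L)
    stop("insufficient data: need >= 10 time windows to estimate background",
         call. = FALSE)
  bin_median <- apply(mag, 1, stats::median)
  bin_mean <- rowMeans(mag)
  bin_var <- apply(mag, 1, stats::var)
  cv <- ifelse(bin_mean > 0, sqrt(bin_var) / bin_mean, Inf)
  floor_mag <- stats::median(mag)
  active_level <- 4 * max(floor_mag, 1e-300)   # ~6 dB above the global floor
  persistence <- rowMeans(mag > active_level)
  candidate <- cv < cv_threshold & persistence > persistence_fraction
  # Amplitude constancy alone cannot separate a hum from a wandering tone:
  # a 20 ms window's spectral lobe is ~2/window_s wide, so a tone wandering
  # by a few bins keeps a broad band of zero-padded bins near-constant in
  # amplitude. Background additionally requires the band's per-window peak
  # position to stay put (within one bin between the 5th and 95th
  # percentile of its location).
  is_bg <- rep(FALSE, length(candidate))
  bin_hz <- spec$freqs[2] - spec$freqs[1]
  if (any(candidate)) {
    r <- rle(candidate)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      bins <- starts[b]:ends[b]
      pk <- if (length(bins) == 1L) rep(1L, ncol(mag))
            else apply(mag[bins, , drop = FALSE], 2, which.max)
      q <- stats::quantile(spec$freqs[bins][pk], c(0.05, 0.95), names = FALSE)
      is_bg[bins] <- (q[2] - q[1]) <= bin_hz
    }
  }
  out <- mag - floor_mag
  if (any(is_bg))
    out[is_bg, ] <- mag[is_bg, ] - oversubtraction * bin_median[is_bg]
  out[out < 0] <- 0
  den <- spec
  den$magnitude <- out
  noise <- structure(
    list(freqs = spec$freqs,
         background_magnitude = bin_median,
         background_mean = bin_mean,
         temporal_variance = bin_var,
         is_background = is_bg,
         broadband_floor = floor_mag),
    class = "noise_profile")
  list(spectrogram = den, noise = noise)
}

#' Extract flight traces by per-window peak tracking
#'
#' Decimates the overlapped spectrogram to non-overlapping 20 ms strides
#' (one frequency instance per stride, so histogram counts are not inflated
#' by correlated windows), then in each stride locates local spectral maxima
#' inside the search band that rise at least \code{detection_threshold_db}
#' above the local noise floor. Candidates lying within one bin of an
#' integer multiple of a louder concurrent candidate are rejected as
#' overtones; among the surviving candidate fundamentals the loudest wins
#' (so when two mosquitoes overlap, the louder one is followed), with
#' magnitude ties broken toward the lower frequency. Runs of detections
#' separated by more than \code{gap_tolerance_s} of silence become separate
#' traces, so sequentially recorded mosquitoes count as separate instances.
#'
#' @param spec A (preferably denoised) \code{\link{spectrogram}}.
#' @param params \code{\link{spectrogram_params}}; defaults to the ones the
#'   spectrogram was built with.
#' @param detection_threshold_db Required prominence in dB of a peak above
#'   the local noise floor (default 6).
#' @param gap_tolerance_s Gap length in seconds that terminates a trace
#'   (default 0.25).
#' @param noise Optional \code{noise_profile} from
#'   \code{\link{subtract_background}}; when supplied, the in-band mean
#'   background level also enters the detection floor.
#' @param source Optional source label stored on each trace.
#' @return A list of \code{flight_trace} objects (possibly empty), each with
#'   \code{trace_id}, \code{sample_times}, \code{frequencies},
#'   \code{magnitudes} and \code{source}.
#' @export
extract_flight_traces <- function(spec, params = spec$params,
                                  detection_threshold_db = 6,
                                  gap_tolerance_s = 0.25,
                                  noise = NULL, source = NA_character_) {
  stopifnot(inherits(spec, "spectrogram"), detection_threshold_db >= 0)
  cols <- seq(1L, ncol(spec$magnitude), by = spec$stride_factor)
  band <- which(spec$freqs >= params$search_band[1] &
                spec$freqs <= params$search_band[2])
  if (length(band) < 3L) stop("search band too narrow for the spectrogram",
                              call. = FALSE)
  bg_floor <- if (!is.null(noise))
    mean(noise$background_mean[band]) else 0
  thr_lin <- 10^(detection_threshold_db / 10)
  bin_hz <- spec$freqs[2] - spec$freqs[1]

  freq_at <- rep(NA_real_, length(cols))
  mag_at <- rep(NA_real_, length(cols))
  for (j in seq_along(cols)) {
    m <- spec$magnitude[band, cols[j]]
    floor_j <- max(stats::median(m), bg_floor, 1e-300)
    pk <- which(diff(sign(diff(c(-Inf, m, -Inf)))) < 0)
    pk <- pk[m[pk] >= floor_j * thr_lin & m[pk] > 0]
    if (length(pk) == 0L) next
    f <- spec$freqs[band[pk]]
    a <- m[pk]
    keep <- rep(TRUE, length(pk))
    if (length(pk) > 1L) {
      for (i in seq_along(pk)) {
        ratio <- f[i] / f
        near_harm <- abs(ratio - round(ratio)) * f < 1.5 * bin_hz &
          round(ratio) >= 2
        if (any(near_harm & a > a[i])) keep[i] <- FALSE
      }
    }
    if (!any(keep)) next
    f <- f[keep]; a <- a[keep]
    best <- which(a == max(a))
    best <- best[which.min(f[best])]   # tie toward lower frequency
    # refine the peak by a power-weighted centroid over the window's
    # spectral lobe (half-width 1/window_s), averaged across every
    # overlapped hop inside the stride: the zero-padded lobe is flat-topped
    # over several bins, so a raw argmax jitters by whole bins under noise,
    # while hop-averaged centroids recover the tone to well under one bin
    ctr <- band[pk[keep][best]]
    half <- max(1L, round(1 / (params$window_s * bin_hz)))
    stride_start <- min(cols[j],
                        max(1L, ncol(spec$magnitude) - spec$stride_factor + 1L))
    stride_cols <- stride_start:min(ncol(spec$magnitude),
                                    stride_start + spec$stride_factor - 1L)
    fc <- vapply(stride_cols, function(cc) {
      lo <- max(1L, ctr - half); hi <- min(nrow(spec$magnitude), ctr + half)
      pkc <- lo - 1L + which.max(spec$magnitude[lo:hi, cc])
      nb <- max(1L, pkc - half):min(nrow(spec$magnitude), pkc + half)
      wts <- spec$magnitude[nb, cc]
      if (sum(wts) <= 0) return(spec$freqs[ctr])
      sum(spec$freqs[nb] * wts) / sum(wts)
    }, numeric(1))
    freq_at[j] <- min(params$search_band[2],
                      max(params$search_band[1], mean(fc)))
    mag_at[j] <- a[best]
  }

  detected <- !is.na(freq_at)
  if (!any(detected)) return(list())
  stride_s <- spec$hop_s * spec$stride_factor
  gap_windows <- max(1L, floor(gap_tolerance_s / stride_s))
  d_idx <- which(detected)
  breaks <- which(diff(d_idx) > gap_windows)
  seg_start <- c(1L, breaks + 1L)
  seg_end <- c(breaks, length(d_idx))
  lapply(seq_along(seg_start), function(k) {
    sel <- d_idx[seg_start[k]:seg_end[k]]
    f_sel <- freq_at[sel]
    # 3-point running median: standard pitch-track de-glitching, removes
    # isolated single-window outliers without smearing the slow wander
    if (length(f_sel) >= 3L) f_sel <- as.numeric(stats::runmed(f_sel, 3))
    structure(
      list(trace_id = k,
           sample_times = spec$times[cols[sel]],
           frequencies = f_sel,
           magnitudes = mag_at[sel],
           stride_s = stride_s,
           source = source),
      class = "flight_trace")
  })
}

#' @export
print.flight_trace <- function(x, ...) {
  cat(sprintf("<flight_trace #%s> %d windows, %.2f-%.2f s, median %.0f Hz\n",
              x$trace_id, length(x$frequencies), min(x$sample_times),
              max(x$sample_times), stats::median(x$frequencies)))
  invisible(x)
}

#' Estimate the signal-to-noise ratio of a flight trace
#'
#' The ratio, in dB, of the mean spectral power at the trace's fundamental
#' bins to the mean background power across the search band, clipped below
#' at 0 dB. Band bins within one native lobe width of the trace's own
#' frequency range are excluded from the background estimate, since the
#' tone's spectral lobe would otherwise contaminate it.
#'
#' @param spec The \code{\link{spectrogram}} the trace was extracted from
#'   (pre-subtraction magnitudes give the most honest numerator; either
#'   works for well-separated tones).
#' @param trace A \code{flight_trace}.
#' @param noise A \code{noise_profile} from \code{\link{subtract_background}}.
#' @return SNR in dB (non-negative scalar).
#' @export
estimate_snr <- function(spec, trace, noise) {
  stopifnot(inherits(spec, "spectrogram"), inherits(noise, "noise_profile"))
  if (!inherits(trace, "flight_trace") || length(trace$frequencies) == 0L)
    stop("undefined SNR: empty flight trace", call. = FALSE)
  band <- which(spec$freqs >= spec$params$search_band[1] &
                spec$freqs <= spec$params$search_band[2])
  ti <- vapply(trace$sample_times,
               function(t) which.min(abs(spec$times - t)), integer(1))
  fi <- vapply(trace$frequencies,
               function(f) which.min(abs(spec$freqs - f)), integer(1))
  sig <- mean(spec$magnitude[cbind(fi, ti)])
  lobe_hz <- 2 / spec$params$window_s          # native main-lobe half width
  clear <- band[spec$freqs[band] < min(trace$frequencies) - lobe_hz |
                spec$freqs[band] > max(trace$frequencies) + lobe_hz]
  if (length(clear) == 0L) clear <- band
  # spatial median across clear bins: robust to residual sidelobe peaks
  bg <- stats::median(noise$background_mean[clear])
  if (bg <= 0) bg <- 1e-300
  max(0, 10 * log10(sig / bg))
}

#' Doppler shift fraction for a moving sound source
#'
#' Mosquitoes rarely exceed 0.5 m/s in free flight, so the fractional
#' Doppler shift \code{1 - (c - v) / (c + v)} stays near 0.3% -- under 2 Hz
#' at a 500 Hz wingbeat, small against natural per-trace spreads of tens of
#' Hz.
#'
#' @param speed_mps Source speed in m/s (non-negative, below the speed of
#'   sound).
#' @param sound_speed_mps Speed of sound in m/s (default 330).
#' @return Dimensionless fractional frequency shift.
#' @export
doppler_shift_fraction <- function(speed_mps, sound_speed_mps = 330) {
  if (speed_mps < 0) stop("speed must be non-negative", call. = FALSE)
  if (speed_mps >= sound_speed_mps)
    stop("speed must be below the speed of sound", call. = FALSE)
  1 - (sound_speed_mps - speed_mps) / (sound_speed_mps + speed_mps)
}

#' Write flight traces to CSV
#'
#' One row per 20 ms instance, columns \code{trace_id}, \code{t_s},
#' \code{freq_hz}, \code{snr_db}, \code{source_file}.
#'
#' @param traces List of \code{flight_trace} objects.
#' @param path Output CSV path.
#' @param snr_db Optional per-trace SNR values (recycled along traces).
#' @return \code{path}, invisibly.
#' @export
write_traces_csv <- function(traces, path, snr_db = NA_real_) {
  snr_db <- rep_len(snr_db, max(1L, length(traces)))
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(trace_id = tr$trace_id, t_s = tr$sample_times,
               freq_hz = tr$frequencies, snr_db = snr_db[i],
               source_file = tr$source)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trace_id = integer(), t_s = numeric(), freq_hz = numeric(),
               snr_db = numeric(), source_file = character())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read flight traces back from CSV
#'
#' @param path CSV written by \code{\link{write_traces_csv}}.
#' @return A list of \code{flight_trace} objects.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) return(list())
  lapply(split(df, df$trace_id), function(d) {
    structure(
      list(trace_id = d$trace_id[1], sample_times = d$t_s,
           frequencies = d$freq_hz, magnitudes = NULL,
           stride_s = if (nrow(d) > 1) stats::median(diff(d$t_s)) else NA_real_,
           source = d$source_file[1]),
      class = "flight_trace")
  })
}
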