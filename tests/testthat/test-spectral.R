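test_that("spectrogram has 5 Hz bins, 2 ms hop, and locates a known tone", {
  rec <- tone_recording(500, 0.5, duration_s = 1, fs = 44100)
  spec <- compute_spectrogram(rec)
  expect_equal(spec$freqs[2] - spec$freqs[1], 5)
  expect_equal(spec$hop_s, 0.002, tolerance = 0.05)
  expect_true(all(spec$magnitude >= 0))
  band <- spec$freqs >= 200 & spec$freqs <= 700
  peaks <- spec$freqs[band][apply(spec$magnitude[band, ], 2, which.max)]
  expect_true(all(abs(peaks - 500) <= 2.5))
})

test_that("all-zero input yields an all-zero spectrogram; short input errors", {
  rec <- audio_recording(rep(0, 8000), 8000)
  spec <- compute_spectrogram(rec)
  expect_true(all(spec$magnitude == 0))
  expect_error(compute_spectrogram(audio_recording(rep(0, 50), 8000)),
               "shorter than one")
})

test_that("spectral subtraction removes a constant hum but spares a wandering tone", {
  fs <- 8000
  t <- (0:(2 * fs - 1)) / fs
  # frequency-modulated tone 380-420 Hz plus constant 60 Hz hum
  f_inst <- 400 + 20 * sin(2 * pi * 0.7 * t)
  tone <- 0.3 * sin(2 * pi * cumsum(f_inst) / fs)
  hum <- 0.2 * sin(2 * pi * 60 * t)
  spec <- compute_spectrogram(audio_recording(tone + hum, fs))
  den <- subtract_background(spec)
  hum_bin <- which.min(abs(spec$freqs - 60))
  expect_true(den$noise$is_background[hum_bin])
  before <- mean(spec$magnitude[hum_bin, ])
  after <- mean(den$spectrogram$magnitude[hum_bin, ])
  expect_gt(10 * log10(before / max(after, 1e-300)), 20)
  # the modulated tone's peak path is unchanged within one bin
  band <- spec$freqs >= 200 & spec$freqs <= 700
  pk_before <- spec$freqs[band][apply(spec$magnitude[band, ], 2, which.max)]
  pk_after <- den$spectrogram$freqs[band][
    apply(den$spectrogram$magnitude[band, ], 2, which.max)]
  expect_lt(mean(abs(pk_after - pk_before)), 5)
  expect_true(all(den$spectrogram$magnitude >= 0))
})

test_that("spectral subtraction is nearly idempotent and near-identity on a clean wingbeat tone", {
  # a wandering tone, as every real wingbeat is (>= 2% spread)
  fs <- 8000
  t <- (0:(fs - 1)) / fs
  f_inst <- 400 + 15 * sin(2 * pi * 1.1 * t)
  rec <- audio_recording(0.3 * sin(2 * pi * cumsum(f_inst) / fs), fs)
  spec <- compute_spectrogram(rec)
  den1 <- subtract_background(spec)
  den2 <- subtract_background(den1$spectrogram)
  ref <- mean(den1$spectrogram$magnitude)
  expect_lt(mean(abs(den2$spectrogram$magnitude - den1$spectrogram$magnitude)),
            0.01 * ref)
  # noiseless wandering tone: magnitudes essentially unchanged
  expect_lt(max(abs(den1$spectrogram$magnitude - spec$magnitude)),
            1e-6 * max(spec$magnitude))
  expect_error(
    subtract_background(compute_spectrogram(
      tone_recording(400, 0.3, duration_s = 0.025, fs = 8000))),
    "insufficient")
})

test_that("peak tracking takes the fundamental of a harmonic stack, not an overtone", {
  fs <- 8000
  t <- (0:(fs - 1)) / fs
  x <- 0.3 * sin(2 * pi * 400 * t) + 0.15 * sin(2 * pi * 800 * t) +
    0.08 * sin(2 * pi * 1200 * t)
  spec <- compute_spectrogram(audio_recording(x, fs))
  traces <- extract_flight_traces(spec)
  expect_length(traces, 1)
  expect_true(all(abs(traces[[1]]$frequencies - 400) <= 5))
})

test_that("the louder of two simultaneous tones is followed", {
  rec <- tone_recording(c(300, 500), c(10^(-20 / 20), 10^(-40 / 20)),
                        duration_s = 1, fs = 8000)
  traces <- extract_flight_traces(compute_spectrogram(rec))
  expect_length(traces, 1)
  expect_true(all(abs(traces[[1]]$frequencies - 300) <= 5))
})

test_that("temporal segmentation: gaps split traces, single bursts stay whole", {
  fs <- 8000
  seg <- function(f, dur) 0.3 * sin(2 * pi * f * (0:(round(dur * fs) - 1)) / fs)
  # tone only during 0.5-1.5 s of a 2 s clip -> one trace of ~1 s
  x <- c(rep(0, fs / 2), seg(400, 1), rep(0, fs / 2))
  traces <- extract_flight_traces(compute_spectrogram(audio_recording(x, fs)))
  expect_length(traces, 1)
  dur <- diff(range(traces[[1]]$sample_times)) + traces[[1]]$stride_s
  expect_lt(abs(dur - 1), 0.04)
  # two tones separated by 1 s of silence -> two instances
  x2 <- c(seg(350, 0.8), rep(0, fs), seg(520, 0.8))
  traces2 <- extract_flight_traces(compute_spectrogram(audio_recording(x2, fs)))
  expect_length(traces2, 2)
  expect_lt(abs(median(traces2[[1]]$frequencies) - 350), 5)
  expect_lt(abs(median(traces2[[2]]$frequencies) - 520), 5)
  # silence -> no traces, not an error
  expect_length(
    extract_flight_traces(compute_spectrogram(audio_recording(rep(0, fs), fs))),
    0)
})

test_that("peak tracking recovers single tones across the band at >= 99% of windows", {
  fs <- 8000
  for (f0 in c(210, 333, 467, 581, 692)) {
    rec <- tone_recording(f0, 0.3, duration_s = 1, fs = fs)
    noisy <- add_noise(rec, noise_spec(hum_bands = list()),
                       target_snr_db = 20, seed = round(f0))
    traces <- extract_flight_traces(compute_spectrogram(noisy))
    freqs <- unlist(lapply(traces, `[[`, "frequencies"))
    expect_gte(length(freqs), 45)
    expect_gte(mean(abs(freqs - f0) <= 2.5), 0.99)
  }
})

test_that("full pipeline recovers a wandering wingbeat tone within one bin", {
  sp <- synthetic_species("t", 480)
  rec <- synthesize_recording(sp, 2, 8000, seed = 9, individual_center = 480)
  truth <- attr(rec, "true_frequencies")
  noisy <- add_noise(rec, noise_spec(), target_snr_db = 20, seed = 10)
  res <- analyze_recording(noisy)
  freqs <- unlist(lapply(res$traces, `[[`, "frequencies"))
  expect_gte(length(freqs), 80)
  expect_lte(abs(median(freqs) - median(truth)), 5)
  d_rec <- build_distribution(freqs, label = "rec")
  d_true <- build_distribution(truth, label = "true")
  s <- distribution_summary(d_rec)
  st <- distribution_summary(d_true)
  expect_lte(abs(s$mean - st$mean), 5)
})

test_that("SNR estimate matches a constructed amplitude ratio and 6 dB doubling", {
  fs <- 8000
  base <- tone_recording(450, 0.1, duration_s = 2, fs = fs)
  snr_of <- function(rec, seed) {
    noisy <- add_noise(rec, noise_spec(hum_bands = list()),
                       target_snr_db = 40, seed = seed)
    spec <- compute_spectrogram(noisy)
    den <- subtract_background(spec)
    tr <- extract_flight_traces(spec)[[1]]
    estimate_snr(spec, tr, den$noise)
  }
  s1 <- snr_of(base, 21)
  expect_lt(abs(s1 - 40), 3)
  # doubling the tone amplitude against the SAME noise floor adds ~6 dB:
  # reuse the noise realization implied by a 25 dB target on the base tone
  # (moderate SNR keeps window sidelobes below the noise floor, where the
  # background estimate is unbiased)
  s1 <- snr_of_at <- function(rec, seed, target) {
    noisy <- add_noise(rec, noise_spec(hum_bands = list()),
                       target_snr_db = target, seed = seed)
    spec <- compute_spectrogram(noisy)
    den <- subtract_background(spec)
    tr <- extract_flight_traces(spec)[[1]]
    estimate_snr(spec, tr, den$noise)
  }
  s1 <- snr_of_at(base, 21, 25)
  noisy1 <- add_noise(base, noise_spec(hum_bands = list()),
                      target_snr_db = 25, seed = 21)
  noise_only <- noisy1$samples - base$samples
  louder <- audio_recording(2 * base$samples + noise_only, fs)
  spec2 <- compute_spectrogram(louder)
  den2 <- subtract_background(spec2)
  tr2 <- extract_flight_traces(spec2)[[1]]
  s2 <- estimate_snr(spec2, tr2, den2$noise)
  expect_lt(abs((s2 - s1) - 20 * log10(2)), 1)
  # a forced dummy trace on pure noise reports ~0 dB
  pure <- audio_recording(rnorm(2 * fs, 0, 0.01), fs)
  specp <- compute_spectrogram(pure)
  denp <- subtract_background(specp)
  dummy <- structure(list(trace_id = 1L, sample_times = specp$times[c(10, 20)],
                          frequencies = c(400, 400), magnitudes = NULL,
                          stride_s = 0.02, source = NA),
                     class = "flight_trace")
  expect_lt(estimate_snr(specp, dummy, denp$noise), 3)
  expect_error(estimate_snr(specp, structure(list(frequencies = numeric(0)),
                                             class = "flight_trace"),
                            denp$noise), "empty")
})

test_that("Doppler shift fraction matches the analytic bound", {
  expect_equal(doppler_shift_fraction(0.5), 1 - (330 - 0.5) / (330 + 0.5))
  expect_equal(doppler_shift_fraction(0.5), 0.003, tolerance = 0.01)
  expect_identical(doppler_shift_fraction(0), 0)
  expect_lt(doppler_shift_fraction(0.5) * 500, 2)
  expect_error(doppler_shift_fraction(340), "speed of sound")
  expect_error(doppler_shift_fraction(-1), "non-negative")
})

test_that("trace CSV round-trips", {
  rec <- tone_recording(400, 0.3, duration_s = 1, fs = 8000)
  traces <- extract_flight_traces(compute_spectrogram(rec))
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(traces, path, snr_db = 12)
  back <- read_traces_csv(path)
  expect_length(back, length(traces))
  expect_equal(back[[1]]$frequencies, traces[[1]]$frequencies)
  # empty trace list -> valid empty CSV
  write_traces_csv(list(), path)
  expect_length(read_traces_csv(path), 0)
})
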