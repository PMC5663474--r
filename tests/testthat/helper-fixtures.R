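# Shared generators for test fixtures; everything is built in code.

# A pure (possibly multi-)tone recording.
tone_recording <- function(freqs, amps, duration_s = 1, fs = 8000) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  x <- numeric(length(t))
  for (i in seq_along(freqs)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  audio_recording(x, fs)
}

# A uniform-mass distribution over [lo, hi) on standard 5 Hz bins.
uniform_dist <- function(lo, hi, n = 1000, label = "u",
                         range = c(200, 700)) {
  centers <- seq(lo + 2.5, hi - 2.5, by = 5)
  build_distribution(rep(centers, length.out = n), range = range,
                     label = label)
}

# Small synthetic reference populations for classification tests.
toy_library <- function(centers = c(A = 250, B = 450, C = 620),
                        n_ind = 10, windows = 100, seed = 101, ...) {
  pops <- lapply(seq_along(centers), function(i) {
    generate_reference_population(
      synthetic_species(names(centers)[i], centers[i], ...),
      n_ind, windows, seed = seed + i)
  })
  names(pops) <- names(centers)
  list(library = reference_library(lapply(pops, `[[`, "distribution")),
       raw = lapply(pops, `[[`, "frequencies"))
}
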