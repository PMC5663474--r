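---
title: "Methods: wingbeat-frequency analysis and maximum-likelihood species identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wingbeat-frequency analysis and maximum-likelihood species identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingbeatr)
```

## The model

A flying mosquito radiates a tone at its wingbeat frequency together with
overtones at integer multiples. For females of medically relevant species
the fundamental lies between roughly 200 and 700 Hz. The frequency is not
constant: within one flight trace it wanders over tens of Hz (never less
than about 2% of its mean), and individuals of a population differ in
their mean frequency. A species is therefore represented by a
**wingbeat frequency distribution**: the histogram, on 5 Hz bins, of the
instantaneous fundamental measured in every 20 ms window of every
recording of that species, normalized to unit total mass. No parametric
form is assumed — the histogram itself is the model.

Classification is maximum-likelihood over a discrete species parameter.
A query trace is a set of per-window frequencies $f_1, \dots, f_W$,
treated as independent samples. For each candidate species $s$ with
reference masses $p_s(\cdot)$, the score is the **summed** per-window
likelihood
$$\mathrm{score}_s = \sum_{w=1}^{W} p_s(\mathrm{bin}(f_w)),$$
and the trace is assigned to the species with the largest score. Summing
(rather than multiplying, which would be the exact likelihood under
independence) is deliberate: with raw histograms a single outlier window
falling in a zero-mass bin would otherwise veto a species outright. The
reported "confidence" is the score normalized over the candidate set; it
is a relative likelihood, not a calibrated posterior probability, and is
documented as such.

When a recording carries a country (directly, or via coordinates the user
has resolved to a country offline), the candidate set is first restricted
to species marked present in that country in a species-by-country
presence table. This location filter can only remove confounders, never
add them, so the diagonal of a confusion matrix for a species present in
the query country never decreases.

### Comparing distributions

Two metrics are computed on probability masses over shared bins:

* Bhattacharyya coefficient $BC(p,q) = \sum_i \sqrt{p_i q_i}$, an overlap
  measure: 1 iff the distributions agree on every bin, 0 iff their
  supports are disjoint.
* Jensen–Shannon divergence in its bounded square-root, base-2 form,
  $JSD(p,q) = \sqrt{\tfrac12 KL(p\|m) + \tfrac12 KL(q\|m)}$ with
  $m = (p+q)/2$: 0 for identical distributions, 1 for disjoint supports.
  The symmetrized-KL variant ("mean of the two KL divergences of each
  distribution with respect to the other") diverges for disjoint supports
  and cannot reach the documented upper bound of 1, so this package uses
  the bounded form throughout. Zero-mass bins contribute nothing, by the
  $0 \log 0 = 0$ convention.

Both are computed on masses (summing to 1), not on densities: with
densities the bounds would depend on the bin width, and the documented
0/1 bounds would not hold. The density normalization matters only for
plotting and is not used in any metric.

## Signal processing

**Spectrogram.** 20 ms Hann windows with 90% overlap (2 ms hop). A 20 ms
frame natively resolves 50 Hz; the 5 Hz bin spacing is obtained by
zero-padding each frame to `sample_rate / 5` points, which interpolates
the spectrum without lengthening the window. Power is normalized so a
tone of amplitude $A$ at a bin center peaks at $(A/2)^2$ regardless of
window length. Bins are stored up to 2200 Hz by default — enough for the
third overtone of the highest female fundamental — rather than to
Nyquist, purely to bound memory. Recordings sampled below 44.1 kHz are
upsampled (polyphase band-limited interpolation) before analysis;
downsampling is refused because it would discard spectral content.

**Background subtraction.** The background estimator looks for spectral
bands that are constant *in amplitude and in frequency* over the whole
clip. A candidate bin must have temporal coefficient of variation of
power below 0.1 while staying above the broadband floor in more than 90%
of windows. Amplitude constancy alone is not sufficient: the 20 ms
window's main lobe is $4/T = 200$ Hz wide, so a wingbeat tone wandering
by a few bins keeps a broad band of zero-padded bins near-constant in
amplitude, and would be wrongly flagged. Each contiguous candidate band
is therefore also required to keep its per-window peak position fixed to
within one bin (5th–95th percentile of the peak location); a mosquito
tone, whose minimum 2% wander moves the peak by 8 Hz or more at 400 Hz,
always fails this test, while mains hum passes. Flagged bins have twice
their temporal median subtracted (the classic over-subtraction factor:
window-phase interference between the positive- and negative-frequency
lobes of a low-frequency hum leaves ~10% ripple around the median, which
plain median subtraction would retain); all bins have the global median
floor subtracted; results are clipped at zero. A consequence worth
knowing: a perfectly constant synthetic sine is, by this definition,
indistinguishable from a hum and will be subtracted. Real wingbeats are
never constant, which is precisely what the frequency-stability test
exploits.

**Peak tracking.** Frequency instances are taken at non-overlapping 20 ms
strides — not at the 2 ms hop — so one second of tone contributes 50
instances, not 500 correlated ones. Within each stride, local spectral
maxima inside the search band whose prominence over the local noise floor
exceeds 6 dB are candidates; a candidate within one bin of an integer
multiple of a louder concurrent candidate is discarded as an overtone;
among the surviving fundamentals the loudest wins (so when two mosquitoes
overlap, the louder is followed), with ties broken toward the lower
frequency. The selected peak is then refined by a power-weighted centroid
over the window's spectral lobe, averaged across all ten overlapped hops
in the stride: a raw argmax on the flat-topped zero-padded lobe jitters
by whole bins under noise (about 3 Hz r.m.s. at 20 dB bin-SNR), while the
hop-averaged centroid recovers the tone to well under one bin. Each
trace's frequency series finally passes a 3-point running median, the
standard pitch-track de-glitch, which removes isolated single-window
errors without smearing the slow wander. Runs of detections separated by
more than 0.25 s of silence become separate traces (separate instances);
the window function, the 6 dB prominence threshold and the 0.25 s gap
tolerance are this package's choices, stated here because no canonical
values exist.

**SNR.** The quality metric for a trace is the ratio (dB) of mean power
at its fundamental bins to the background level across the search band,
estimated as the spatial median over band bins of each bin's temporal
mean, excluding bins within one native lobe width (100 Hz) of the trace's
own frequency range — otherwise the tone's lobe contaminates its own
denominator and caps the estimate near 8 dB regardless of the true SNR.
The estimate is accurate to within ~1 dB up to roughly 35 dB; beyond
that, window sidelobes rise above the noise floor and bias it low by a
few dB.

## The synthetic generator

The generator exists so that every pipeline stage can be exercised
against known ground truth. It emulates:

* a harmonic stack (fundamental plus 3 overtones decaying 10 dB per
  harmonic) with phase-continuous synthesis and 10 ms cosine ramps;
* intra-trace frequency wander as a mean-reverting AR(1) process per
  20 ms window (innovation SD 3 Hz, reversion 0.15 per window by
  default), started at its stationary distribution; per-window
  autocorrelation is not documented anywhere we know of, so AR(1) is a
  modeling choice. Each trace is rescaled, if necessary, so its 5th–95th
  percentile spread is at least 2% of its mean — the natural floor
  observed in free flight;
* between-individual variation as a normal distribution of individual
  mean frequencies (SD 15 Hz by default), so a pooled population
  distribution (default 10 individuals × 100 windows = 1000 samples,
  within the realistic 300–50,000 range for references) is wider than any
  single trace;
* background noise as white broadband noise plus constant hum tones, with
  the broadband level optionally calibrated so the spectrogram-domain SNR
  (the same quantity `estimate_snr()` reports) hits a requested target;
* survey metadata: species drawn by relative abundance, timestamps by
  24-hour activity profiles (crepuscular by default), locations uniform
  or by per-cell spatial weights in a bounding box, plus a configurable
  fraction of zero-encounter reports.

What it does **not** emulate: biophysically detailed wing kinematics
(clap-and-fling harmonics beyond a decaying overtone stack), amplitude
modulation from varying phone–mosquito distance, reverberation, speech or
traffic backgrounds, temperature dependence of wingbeat frequency, or
male–female duetting. Passing closed-loop tests therefore demonstrates
the internal consistency of the pipeline under controlled conditions, not
field performance.

Doppler shift is negligible by construction: at the ≤0.5 m/s speeds of
free flight the fractional shift $1-(c-v)/(c+v) \approx 0.3\%$ is under
2 Hz at 500 Hz (`doppler_shift_fraction()`), far below natural per-trace
spreads; the generator can apply it but does not by default.

## Validation machinery

**Bootstrap.** For each species, 10,000 random subsets (without
replacement) of its raw window frequencies are classified against the
full library; subset size defaults to 60 windows, the size at which
subset distributions have converged onto their parents (60 windows = 1.2 s
of recording at the 20 ms stride; convergence is verified empirically by
`subsample_convergence()`, which reports the smallest subset whose mean
BC to the parent exceeds 0.9 — typically well under 20% of the sample
count). The resulting confusion matrix is column-stochastic (true species
in columns).

**K-fold.** Each species' samples are partitioned into K disjoint,
stratified folds; queries are subsets drawn from the held-out fold and
scored against references rebuilt from the other K−1 folds, pooled over
folds. Unlike the bootstrap, queries never overlap the data behind the
reference they are scored against; on synthetic libraries the two
matrices agree within a few hundredths.

**Tie-breaking.** `classify_trace()` breaks score ties
lexicographically by species name and sets a flag — user-facing results
must be deterministic. The validation simulations instead break ties
uniformly at random (still reproducible under their seed): with two
identical reference distributions every trial ties, and any deterministic
rule would report a 1.0/0.0 split where the statistically meaningful
answer is the symmetric 0.5/0.5.

**Smoothing.** Reference histograms are used raw (epsilon = 0) by
default, as collected references are. An optional per-bin floor mass is
exposed because raw zero bins make summed scores brittle for references
built from very few samples.

## Survey mapping

Classified recordings with coordinates are aggregated on an
equirectangular grid of fixed metric cell size (default 100 m — field
maps in this domain resolve structure at tens of metres; the cell size is
configurable since no canonical value exists). Cell extents are computed
at the box's mean latitude; over the few-kilometre extent of a field
exercise the metric distortion is negligible. Zero-encounter reports
("no mosquitoes here") are first-class records, carried through
aggregation and export as point markers alongside the cell polygons.
Timestamps are histogrammed by hour as a proxy for activity. Counts are
conserved exactly through aggregation and GeoJSON/CSV export.

## Numerical choices and degenerate inputs

* Bin edges are anchored at the range floor (multiples of 5 Hz from
  200 Hz by default); frequencies outside the range are counted and
  reported, never silently binned.
* Quantiles of a binned distribution are discrete weighted quantiles on
  bin centers, so a single-occupied-bin distribution has zero spread.
* Integer PCM is rescaled by the type's full-scale value; recordings are
  never peak-normalized, which would destroy relative level estimates.
* Empty inputs fail loudly (empty WAV, trace, or distribution; too few
  windows to estimate a background; subset larger than the sample), with
  one deliberate exception: silence analyzed for traces returns an empty
  list, because "no mosquito present" is a result, not an error.
* Stereo files are averaged to mono; how multi-channel field recordings
  ought to be combined is genuinely open, and averaging is the
  deterministic choice.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state; identical seeds give bit-identical audio, datasets, and
  downstream results.

## Problem sizes

The test-suite and acceptance computations use synthetic libraries of 2–5
species at 1000 reference samples each (10 individuals × 100 windows),
10,000-trial bootstraps, 200-replicate convergence curves, 1–2 s
recordings at 8 kHz (where four harmonics of any female fundamental stay
below Nyquist), and survey exercises of 60–1000 recordings. These sizes
are where the quantities of interest have visibly converged; all scale
linearly if larger studies are wanted.

## Known limitations

* Frequency precision per 20 ms stride is noise-limited to roughly 1 Hz
  at 20 dB bin-SNR even with hop averaging; below ~10 dB the tracker
  increasingly picks noise maxima.
* A tone that is genuinely constant over a whole clip is classified as
  background by design; this cannot affect real wingbeats but surprises
  synthetic-sine users (disable `subtract_background()` for such
  material).
* The location filter is country-grained and offline: coordinates are
  not geocoded; users supply the country or their own boundary lookup.
* Confidence values are relative likelihoods over the candidate set and
  must not be read as calibrated probabilities.
* Classification quality degrades intrinsically with the number of
  overlapping species in the library; the bootstrap confusion matrix is
  the honest statement of those limits for a given library.
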