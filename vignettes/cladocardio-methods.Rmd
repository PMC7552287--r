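---
title: "Methods: video-based cardiovascular measurement in water fleas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: video-based cardiovascular measurement in water fleas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladocardio)
```

`cladocardio` measures the cardiovascular phenotype of cladocerans (water
fleas) from high-speed microscopy video. This vignette is the package's own
account of the underlying models, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the validation
suite does and does not demonstrate.

## The measurement model

### Heartbeat from dynamic pixel change

The daphnid heart is a single transparent chamber. As it contracts, the
amount of absorbing tissue and hemolymph under any fixed rectangular ROI
changes, so the mean ROI intensity oscillates at the beat frequency. We
treat that trace, sampled at the camera's frame rate, as the heartbeat
signal; no segmentation is needed for rate and rhythm endpoints.

Beat detection proceeds as: (1) linear detrend (photobleaching and slow
illumination drift are well approximated as linear over a 10 s record);
(2) polarity normalisation — systole may be brighter or darker than diastole
depending on optics, so if the detrended trace's third central moment is
negative (sharp troughs), the trace is negated; (3) local maxima with a
topographic prominence of at least `prominence_frac` (default 0.25) of the
robust signal range (5th–95th percentile), which rejects diastolic ripple
and noise without assuming a noise model; (4) a refractory period of
`60 / max_rate_bpm` seconds, keeping the most prominent peak in any
conflict; (5) sub-frame timing by a parabolic fit through the three samples
around each peak. At 200 fps a frame period is 5 ms — 5 % of a 0.1 s beat
cycle — so without interpolation the interval series would be quantised
badly enough to corrupt variability statistics; with it, timing residuals
are a fraction of a millisecond on clean traces.

The rate band defaults (`min_rate_bpm = 60`, `max_rate_bpm = 1200`) bracket
every rate reported for these species (roughly 260–600 bpm across species,
temperatures and doses) with a factor-two margin on both sides. A detected
mean rate outside the band attaches a warning rather than failing: slowed,
arrhythmic hearts are exactly what a toxicology user wants to see.

Two heart-rate estimators are exposed because published per-animal numbers
are ambiguous about which is meant. `mean(60 / I_k)` (per-beat mean, the
default) and `60 / mean(I_k)` differ by Jensen's inequality whenever
intervals vary; reported cladoceran values in the literature (a ~600 bpm
animal alongside a ~0.105 s mean interval, whose reciprocal is only
~571 bpm) are consistent with the per-beat mean, so that is the default,
and both are in `glance()`.

### Rhythm regularity

The Poincaré plot scatters `I_n` against `I_{n+1}`. With population (1/N)
variance estimators we report `sd1` (dispersion across the identity line:
beat-to-beat, short-term variability), `sd2` (dispersion along it), and
`sdnn`. Because different figures in the literature label any of these as
"the SD of the Poincaré plot", all three are reported.

One definitional subtlety: the identity `sd1² + sd2² = 2·sdnn²` holds
exactly only when `sdnn²` is defined as the mean of the variances of the two
pair coordinates (first and last intervals enter the pair set once, interior
intervals twice). `poincare()` uses that definition so the identity is exact
to machine precision and is asserted at 1e-9 in the tests. The
`regularity_report()` bundle instead reports `sdnn` as the population SD of
the full interval sequence, which is invariant under reordering of the
intervals (an order-free dispersion, the usual SDNN of HRV practice). The
two differ by edge terms of order 1/n — negligible at ~100 beats, but the
package keeps both definitions explicit rather than blurring them.

The spectrogram (`beat_stft()`) is a Hann-windowed, mean-subtracted
short-time Fourier transform with 1 s windows and 75 % overlap by default:
1 Hz frequency resolution resolves the 4–10 Hz beat band at 200 fps, and
the overlap gives smooth time coverage of a 10 s record. Power is stored as
one-sided `|FFT|²` without doubling; an internal helper reconstructs the
two-sided sum so Parseval's identity can be checked exactly (it is, at 1e-6
relative, in the tests). The dominant frequency is the non-DC bin with the
largest total power over windows; a trace with essentially no AC power
(relative threshold 1e-12 of the DC term) is flagged `dc_only` and the
dominant frequency is `NA` rather than a meaningless argmax.

By default the STFT operates on the intensity trace, whose dominant
frequency is the beat frequency. Published spectrogram figures for these
animals sometimes show "time interval frequency" bands an order of
magnitude below the beat frequency implied by the same animals' bpm; which
signal those figures transformed is not recoverable. Rather than guess, the
package also provides `interval_series()`, which resamples the tachogram
(interval duration vs. time) onto a uniform grid for STFT of interval
dynamics — both modes exist, the trace mode is the default, and they answer
different questions.

### Blood flow from hemocyte tracking

Hemocytes in transmitted light are small dark blobs. Detection uses the
scale-normalised Laplacian of Gaussian `σ²∇²(G_σ∗I)`, whose response is
maximal at the centre of a blob of matched scale; the default
`sigma_px = 2.5` corresponds to cells of ~3.5 px radius (`radius = √2·σ`),
about right for hemocytes at 1–2 µm/px. The detection threshold defaults to
5× the robust noise SD (`mad`) of the response — a pure noise floor — with
a small relative floor (1e-6 of the response range) so numerically flat
synthetic backgrounds do not admit round-off ripples. Sub-pixel positions
come from a 2-D quadratic fit to the 3×3 response neighbourhood, with the
offset clamped to one pixel and dropped if the local Hessian is not
negative definite.

Linking is optimal per frame pair: candidate links between open track ends
and current spots within the gate `max_disp_px · (gap + 1)` are assigned by
the Hungarian algorithm on the standard augmented cost matrix (real costs =
squared displacement; diagonal alternatives price leaving a track unlinked
or starting a new one just above the worst admissible link). This is
deterministic, independent of spot ordering, and jointly optimal — when two
trajectories compete for spots the assignment minimises total squared
displacement rather than linking greedily, and when a displacement exceeds
the gate the track terminates instead of jumping. A track may bridge up to
`max_gap` (default 1) missed frames. Tracks shorter than `min_track_len = 3`
spots are discarded as spurious. The default gate of 15 px/frame at 200 fps
covers flows up to ~2800 µm/s (the fastest reported for these species) at
1–2 µm/px calibration. No spatial calibration is ever guessed: `µm/px` and
fps are required inputs, and velocities scale linearly in both.

Velocity summaries pool per-step speeds across all tracks of a recording
(one max/mean/min per animal, matching how per-animal flow endpoints are
reported); `per_track = TRUE` gives per-track rows instead. The pooled
minimum is sensitive to localisation noise at near-zero instantaneous
speeds — at a stationary point of pulsatile flow, a 0.05 px residual over a
frame is a ~20 µm/s apparent speed — which is why validation bounds the
mean and max tightly but treats the minimum as indicative.

### Cardiac geometry

The chamber is modelled as a prolate spheroid: volume `(π/6)·D_L·D_S²`.
Three conventions in the source literature for these endpoints are
ambiguous, and the package resolves each explicitly rather than silently:

- **Fractional shortening denominator.** The protocol literature prints
  `FS = (D_SD − D_SS)/D_SS` — systolic denominator — whereas
  echocardiographic convention divides by the diastolic diameter. The
  default follows the systolic form (`convention = "paper"`), and
  `"standard"` switches. The two differ by the factor `D_SD/D_SS` (~25 % at
  typical geometry), so the choice is surfaced as an argument, never
  inferred.
- **The ellipsoid constant.** The printed volume formula uses `1/6` without
  π. The true spheroid volume carries `π/6`, and that is the default;
  `include_pi = FALSE` reproduces the literal printed constant. The
  constant cancels in ejection fraction, so only absolute volumes (SV, CO)
  are affected.
- **Ejection fraction.** Text descriptions sometimes invert the ratio
  ("dividing EDV with SV"); the equation form `EF = SV/EDV × 100` is the
  only one bounded by 100 % and is what the package computes.

Volumes are reported in µm³ and nL (1 nL = 1e6 µm³); the nanolitre scale is
the natural one for a ~1.4 nL stroke volume.

Automated diameter measurement selects systolic frames at detected beat
peaks and diastolic frames at the midpoints between consecutive peaks (the
maximally relaxed phase, without requiring a second segmentation pass).
Each ROI frame is Otsu-thresholded; a bimodality gate requires the two
intensity classes to separate by at least 3× their pooled within-class SD
(splitting pure Gaussian noise at its mean yields ~2.7 SD, so a noise-only
ROI is rejected as "heart not segmentable" rather than measured). The
foreground class is chosen as the largest connected component with the
least ROI-border contact — the heart lies inside the ROI, the background
always reaches its border — with the component's fill of its own moment
ellipse as tie-break. Full axes come from second moments (for a solid
ellipse the coordinate covariance eigenvalues are `(axis/4)²`). Because the
intensity trace fixes the two phase sets only up to a half-cycle shift, the
set with the larger chamber volume is labelled diastole, with a message
when a swap occurs. At most 12 frames per phase are segmented (evenly
subsampled): averaging a dozen frames per phase is ample for a stable mean
and keeps long recordings fast. Manual measurements are supported as a CSV
fallback (`read_diameters()`).

## The synthetic generators

`simulate_heart()` renders a dark ellipse on a bright 16-bit background
whose axes oscillate between the programmed diastolic and systolic values.
Defaults mirror the targeted acquisition conditions: 200 fps, 10 s, a
300 × 150 µm diastolic chamber contracting to 280 × 120 µm at 600 bpm,
2 µm/px. Beat-to-beat intervals are truncated Gaussian
(`max(0.02, N(60/rate, interval_sd_s))`) — the simplest model that
reproduces realistic Poincaré dispersion patterns. The contraction follows
a Gaussian pulse of SD 12 % of the cycle around each beat time, so systole
occupies roughly a fifth of the cycle as in the animal, and the trace has
the sharp-systole asymmetry the polarity heuristic relies on. Edges are
rendered with a Gaussian profile about 1.5 px wide (band-limited), so
segmentation and sub-pixel localisation are meaningful; frames are then
quantised to integer counts like a CCD. `heart_noise_for_snr()` converts a
trace-level SNR into the corresponding per-pixel noise SD (pixel noise
averages down by the square root of the ROI area).

`simulate_flow()` advects Gaussian-blob cells along a corridor with a
shared, optionally pulsatile speed
`s(t) = mean·(1 + p·sin(2π f_beat t))`; positions are integrated
analytically, so truth tracks are exact. Cells are placed on a jittered
staggered grid whose spacing exceeds twice the per-frame displacement, the
regime in which identity-correct tracking is well posed.

All randomness flows through one `seed` argument and the caller's RNG state
is restored afterwards; identical parameters and seed give bit-identical
frames and truth.

What the generators deliberately do **not** emulate: limb and antenna
motion crossing the ROI, occlusion by the carapace or eggs, focus drift,
mounting-medium artefacts, non-elliptical chamber shapes, and cell-density
crowding in the flow corridor. Passing the validation suite therefore
demonstrates correctness of the measurement chain under clean conditions —
detection parameters on real recordings may need adjustment, and a
motion-contaminated ROI will degrade gracefully (warnings, failed
segmentation) rather than being rescued.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: FFT
periodograms for dominant frequencies, full permutation enumeration for the
rank-sum test, a 0.5 µm voxel-counting oracle for ellipsoid volumes,
rendered blobs at known sub-pixel positions for localisation, and the
generators' exact truth records for everything end-to-end. Rate recovery is
checked at 264, 546 and 600 bpm on 10 s, 200 fps recordings (noiseless:
within 1 %; trace SNR 10: within 3 %); SDNN recovery at programmed 0/5/20 ms
jitter over ~100 beats (within 20 % for the nonzero levels; the zero-jitter
case is bounded at 1 ms absolute, since a relative bound is undefined at
zero and sub-frame interpolation residuals set the floor); tracking on a
20-cell, pulsatility-1 corridor at mean 1000 µm/s (identity-correct
bijection onto the programmed cells, pooled mean and max speeds within 5 %);
and the full video-to-cardiac-output pipeline on a 3 s recording (within
10 % of programmed SV × rate; observed error ~0.5 %). `scripts/acceptance.R`
recomputes these quantities from scratch at any seed.

## Known limitations

- ROI placement is manual (or scripted), as in the underlying protocol;
  there is no automatic heart finding.
- The geometry model assumes a prolate spheroid with the short axis
  axisymmetric; a strongly tilted or non-ellipsoidal chamber biases
  volumes.
- AVI input is not supported; recordings should be exported as multi-page
  TIFF (8/16-bit integer, or 32-bit float scaled to [0, 1]).
- The minimum of pooled step speeds is noise-sensitive near zero flow (see
  above); prefer the mean and max for dose–response endpoints.
- Group comparison implements the Mann–Whitney test only; it is a
  descriptive convenience, not a substitute for a pre-registered analysis
  plan.
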