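# cladocardio

Cardiovascular videography analysis for water fleas (*Daphnia*, *Moina*)
and other transparent invertebrates with a single-chambered myogenic heart.

Cladocerans are standard ecotoxicology models: their bodies are transparent,
their hearts are large and fast (roughly 260–600 beats/min depending on
species and temperature), and their hemocytes can be watched flowing through
the open circulatory system. High-speed video (typically 200 frames/s for
10 s) therefore carries a complete cardiovascular phenotype — but extracting
it by hand is slow and error-prone. `cladocardio` automates the whole chain:

- **Heartbeat** — the mean pixel intensity of a rectangular ROI over the
  heart oscillates at the beat frequency ("dynamic pixel change"). Beats are
  the prominent local maxima of the detrended trace, timed to sub-frame
  resolution by parabolic interpolation. Heart rate is reported both as
  `mean(60 / I_k)` over the inter-beat intervals `I_k` (default) and as
  `60 / mean(I_k)`.
- **Rhythm regularity (HRV)** — Poincaré descriptors of the interval
  sequence, `SD1 = SD((I_{n+1} − I_n)/√2)` (short-axis, beat-to-beat) and
  `SD2 = SD((I_{n+1} + I_n)/√2)` (long-axis), plus SDNN and the coefficient
  of variation; and a Hann-windowed short-time Fourier transform of the
  intensity trace whose dominant frequency is the beat frequency.
- **Blood flow** — hemocytes are detected per frame by scale-normalised
  Laplacian-of-Gaussian filtering (`σ²∇²(G_σ∗I)`), localised to sub-pixel
  accuracy, and linked into trajectories by optimal (LAP/Hungarian)
  frame-to-frame assignment with gap closing. Per-step speeds
  `|Δr| · pixel_size · fps` are pooled into per-animal max/mean/min
  velocities (µm/s).
- **Cardiac geometry** — from long (`D_L`) and short (`D_S`) heart diameters
  at diastole and systole: fractional shortening
  `FS = (D_SD − D_SS)/D_SS × 100 %`, prolate-spheroid chamber volumes
  `V = (π/6) D_L D_S²` (a literal `1/6` mode is available), stroke volume
  `SV = EDV − ESV`, ejection fraction `EF = SV/EDV × 100 %`, and cardiac
  output `CO = SV × HR`. Diameters are either supplied manually (CSV) or
  measured automatically by beat-synchronised Otsu segmentation and
  second-moment ellipse fitting.
- **Synthetic ground truth** — generators render beating-heart and
  pulsatile-flow videos with exactly known beat times, diameters and cell
  trajectories, so every analysis step is validated against programmed truth.
- **Reporting** — per-group mean ± SEM summaries, control-normalised values,
  and exact/approximate Mann–Whitney comparisons for temperature or dose
  series.

## Worked example

Simulate a 3 s, 200 fps recording of a 600 bpm heart (diastole 300 × 150 µm,
systole 280 × 120 µm, 5 ms beat jitter) and run the full analysis:

```r
library(cladocardio)

sim   <- simulate_heart(duration_s = 3, rate_bpm = 600, interval_sd_s = 0.005, seed = 5)
trace <- extract_trace(sim$stack)
beats <- detect_beats(trace)
glance(beats)
#>   n_beats bpm_per_beat_mean bpm_reciprocal_mean interval_mean_s interval_sd_s
#> 1      30              600.                599.           0.100       0.00499

regularity_report(beats)
#>    sdnn_s   sd1_s   sd2_s     cv n_intervals
#> 1 0.00490 0.00474 0.00511 0.0489          29

geom <- measure_diameters(sim$stack, sim$truth$roi, beats)
geom
#> <heart_geometry> diastole 300.2 x 150.1 um, systole 280.2 x 120.3 um

cardiac_metrics(geom, heart_rate(beats))[, c("fs_pct", "ef_pct", "sv_nl", "co_nl_min")]
#>   fs_pct ef_pct sv_nl co_nl_min
#> 1   24.8   40.1  1.42      852.
```

The detector finds all 30 programmed beats and recovers the rate (600 bpm)
and the programmed 5 ms interval jitter (`sdnn` 4.9 ms). The automated
diameters land within a pixel of the programmed axes, giving FS 24.8 %
(programmed 25 %), EF 40.1 %, stroke volume 1.42 nL, and cardiac output
852 nL/min against a programmed 854 nL/min — a 0.2 % end-to-end error.

Blood flow works the same way:

```r
flow   <- simulate_flow(n_cells = 20, mean_speed_um_s = 1000, pulsatility_frac = 1)
spots  <- detect_spots(flow$stack, sigma_px = 2.5)
tracks <- link_tracks(spots, max_disp_px = 8)
summarize_velocity(tracks, pixel_size_um = 2, fps = 200)
```

Every result type has `tidy()` / `glance()` tidiers and an `autoplot()`
method (trace, Poincaré scatter, spectrogram raster, track paths). A thin
command-line front end over the same functions lives at
`inst/cli/cladocardio.R` with subcommands `heartbeat`, `hrv`, `flow`,
`cardiac`, `simulate` and `report`.

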