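# mycospike

Analysis of slow electrical spike trains in fungus-colonised substrate,
recorded with a linear array of differential electrode pairs.

Fungal mycelium produces spontaneous extracellular electrical events that
look nothing like neuronal action potentials: millivolt-scale excursions
lasting tens of seconds to tens of minutes, recurring irregularly on time
scales of minutes to hours. The scientific question this package addresses
is whether such events are independent local fluctuations or *propagating
signals* — and if they propagate, how fast. It is aimed at
electrophysiologists and biophysicists working with long multichannel
logger recordings (hours to weeks at ~1 Hz) from fungi, plants, or other
slow excitable media.

## What it computes

For a recording of C ordered channels, the pipeline:

1. **Detects spikes** per channel as maximal runs of samples with
   `V(t) > V_baseline + k·σ`, where `V_baseline` is the channel median and
   `σ` its full-series standard deviation, kept if the run lasts at least
   `W_min` seconds (defaults `k = 2.0`, `W_min = 60 s`; no upper duration
   limit, no filtering or detrending anywhere).
2. **Summarises morphology**: width and amplitude distributions, and the
   onset-aligned, peak-normalised mean waveform with its interquartile
   band.
3. **Analyses spike trains**: inter-spike intervals
   `ISI_i = t_{i+1} − t_i`, their mean/median/sd and coefficient of
   variation `CV = σ_ISI/μ_ISI`, and bursts (≥2 spikes separated by ISIs
   below 30% of that channel's median ISI).
4. **Quantifies propagation**: onsets on different channels are associated
   within a window (base `Δt_max = 300 s`, scaled with channel
   separation), giving a lead–lag matrix of median signed delays
   `Δt_cd = t_j^(d) − t_i^(c)`; median delay versus physical distance
   `L(s) = spacing × s` is fit with a Theil–Sen robust line, and a
   positive slope `b` (s/cm) yields the propagation velocity `60/b`
   cm/min.
5. **Controls the result** with count-preserving permutation surrogates
   (timing destroyed, per-channel spike counts kept) and a threshold
   sensitivity analysis at `k ∈ {1.5, 2.0, 2.5}`.

A seeded synthetic generator (`synthetic_config()`,
`simulate_recording()`) produces 8-channel recordings with known
asymmetric spike waveforms, heavy-tailed bursty trains, and an injected
propagation velocity, so every stage can be validated against ground truth
without the original data.

## Worked example

Simulate a default recording (8 channels, 2×10⁵ s at 1 Hz, 2 cm spacing,
true velocity 0.7 cm/min) and run the full analysis:

```r
library(mycospike)

sim <- simulate_recording(synthetic_config(seed = 1))
rep <- run_pipeline(sim$recording, n_surrogates = 100, seed = 1)
print(rep)
#> <analysis_report> 8 channels, 2e+05 s, k = 2, w_min = 60 s
#>   spikes: 166 (median width 360 s, median amplitude 0.74 mV)
#>   ISI: median 6.74e+03 s, CV 0.81; burst fraction 0.33
#>   adjacent median delay: 167.0 s over 119 pairs
#>   velocity: 0.702 cm/min (42.1 cm/h), Theil-Sen fit
#>   surrogates: 100, pooled adjacent median 14.2 s, monotone fraction 0.00
```

Reading the output: 166 slow spikes were detected (median width 360 s,
median amplitude 0.74 mV — detected amplitudes sit above the generating
median of 0.6 mV because the 2σ threshold misses the weakest events).
Trains are irregular (CV 0.81) with a third of spikes in bursts. Adjacent
channels show a median onset delay of 167 s over 2 cm, every channel leads
its right-hand neighbour, and the Theil–Sen fit of median delay against
distance gives 0.702 cm/min — recovering the injected 0.7 cm/min. The 100
timing-destroyed surrogates collapse the pooled adjacent median to 14 s
and never retain the monotone lead–lag ordering, so the delay structure
comes from spike timing, not rates or drift.

The single-separation arithmetic matches the field's back-of-envelope
estimate — a 180 s adjacent delay across 2 cm is

```r
velocity_from_adjacent(180, 2)
#> # A tibble: 1 × 4
#>   median_delay_s spacing_cm velocity_cm_per_min velocity_cm_per_h
#> 1            180          2               0.667                40
```

`autoplot()` methods exist for the spike shape, the delay matrix, the
velocity fit, and the surrogate ensemble; `tidy()`/`glance()` return the
fitted quantities as tibbles.

## Reading recordings

`read_recording()` accepts delimited text in two dialects: `"plain"`
(seconds + one mV column per channel) and `"timestamped"` (ISO-like
datetime first column, converted to seconds by time-delta). Units are
declared at read time and converted to mV. Sampling gaps are reported and
treated as segment boundaries — never interpolated. `write_recording()`
emits the plain dialect at full precision (bit-exact round trip).
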