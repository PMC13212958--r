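---
title: "Detecting and tracking slow electrical spikes along a fungal electrode array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracking slow electrical spikes along a fungal electrode array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycospike)
```

## The measurement problem

Fungal mycelium colonising a moist substrate produces spontaneous
extracellular electrical activity: slow, millivolt-scale excursions of the
differential potential lasting from tens of seconds to tens of minutes,
recurring at intervals of minutes to hours. When such activity is recorded
on a *linear* array of differential electrode pairs (channels ordered along
a physical axis, typically 2 cm apart, sampled at 1 Hz), two questions
arise that this package answers quantitatively:

1. What are the events — their widths, amplitudes, waveform, and temporal
   statistics on each channel?
2. Do events *propagate* along the array — do onsets on one channel
   systematically precede onsets on the next, with delay growing linearly
   with distance, at a finite velocity — or are they independent local
   fluctuations or common-mode artefacts?

Everything in the package is time-domain, threshold-based, and
deterministic given its parameters. No filtering, detrending, or spectral
method is applied anywhere: the signals of interest live at periods of
minutes to hours, and the analysis deliberately works on the raw trace.

## Spike detection model

For each channel the baseline potential is the **median** of the full
recording — the median rather than the mean so that the large, rare
excursions we are trying to detect do not drag their own reference level —
and variability is the standard deviation $\sigma$ of the full unfiltered
series. A spike is a maximal run of consecutive samples with

$$V(t) > V_{\mathrm{baseline}} + k\,\sigma,$$

kept only if the run lasts at least $W_{\min}$ seconds. Defaults are
$k = 2.0$ and $W_{\min} = 60$ s: $k = 2$ is the conventional conservative
compromise for slow biological potentials (high enough to suppress baseline
chatter, low enough to keep clearly supra-baseline events), and 60 s
excludes anything faster than the phenomenon of interest. There is no upper
duration limit. Onset is the first supra-threshold sample, termination the
last, amplitude the maximum deviation from baseline within the run.

Two conventions worth making explicit:

* **Width** is the number of supra-threshold samples times the sampling
  interval, so a 60-sample run at 1 Hz has width exactly 60 s and the
  minimum-duration rule is sharp at `w_min` samples. (Each logged sample
  represents a 1 s averaging window, so a sample "owns" its interval;
  `termination - onset` would be one sample short.)
* **Polarity**: only positive-going excursions are detected by default,
  exactly as the threshold condition is written. A mirrored
  `polarity = "negative"` mode exists for exploring hyperpolarising events
  but is off by default.

A sampling gap (successive timestamps more than 1.5× the sampling interval
apart) terminates any open run. Gaps are never interpolated; they are
reported by `validate_recording()` and act as segment boundaries.

Note one self-referential property of the threshold: $\sigma$ is computed
over the *full* series, spikes included, so channels with many strong
spikes have higher thresholds. In consequence the weakest events on an
active channel can legitimately sit below $2\sigma$ and go undetected, and
detected amplitude distributions are biased upward relative to the
generating distribution. This is inherent to the fixed-parameter design,
not a defect, and it is why the threshold-sensitivity analysis
($k \in \{1.5, 2.0, 2.5\}$) is part of the standard pipeline.

## Spike shape

`average_spike_shape()` aligns each event at its detected onset, subtracts
the channel baseline, divides by the event amplitude (so each contributing
waveform peaks at 1), and returns the pointwise mean with the 25th–75th
percentile band on a common grid. The default window, −60 s to +1200 s,
covers the full range of observed widths (~10² to 1.2×10³ s). Events whose
window would run off a recording edge are dropped and counted rather than
padded. The diagnostic of interest is asymmetry: a rise to peak faster than
the relaxation back to half-maximum, the signature of transport-limited
rather than impulse-like dynamics.

## Trains, intervals, bursts

Each channel's onsets form a point process. Inter-spike intervals are
onset-to-onset differences; the summary reports mean, median, standard
deviation, and the coefficient of variation $CV = \sigma_{ISI}/\mu_{ISI}$
per channel and pooled (the pooled row uses pooled intervals, not an
average of per-channel values). $CV \approx 0$ indicates clock-like
regularity, $CV \approx 1$ Poisson-like irregularity; a median below the
mean flags the heavy right tail typical of these recordings.

A **burst** is a run of two or more spikes whose separating intervals are
each below 30% of *that channel's own* median ISI — never a pooled median,
so a slow channel's bursts are judged against its own rhythm. Both
endpoints of every qualifying interval count as burst members, and the
burst fraction is members over total spikes. A channel needs at least three
onsets before its median interval (hence the threshold) means anything;
below that it contributes no bursts. No stationarity assumption or
windowing is applied anywhere in the train statistics.

## Propagation analysis

Onsets on channels $c$ and $d$ are *associated* when they fall within an
effective window of each other. The base window is
$\Delta t_{\max} = 300$ s. Two policies exist:

* `"fixed"`: the window is 300 s for every pair, the literal rule.
* `"scaled"` (default): the window for separation $s = |d - c|$ is
  $s \cdot \Delta t_{\max}$.

The scaled default resolves an internal tension in the fixed rule: a signal
crossing 2 cm-spaced electrodes at ~0.7 cm/min accumulates roughly 170–180 s
per step, so at separations $s \ge 2$ the expected delay itself exceeds a
fixed 300 s window and the literal rule could never associate the pairs
whose delays it is supposed to measure. Scaling the window with separation
keeps the per-step tolerance constant.

Matching is `"one_to_one_nearest"` by default: candidate pairs are accepted
greedily in increasing absolute delay, each spike used at most once (ties
broken by smaller lead onset, then smaller lag onset). This prevents a
single spike from being counted into many pairs; an `"all_pairs"` mode is
retained for comparison. With one-to-one matching the delay set is exactly
antisymmetric under exchanging lead and lag, so the lead–lag matrix is
computed on ordered pairs $c < d$ and mirrored with negation; its diagonal
is 0 by convention and entries with no pairs are `NA`.

The sign convention is that a positive delay means the lower-indexed
channel leads. "Monotone lead–lag ordering" is operationalised as: every
adjacent ordered pair $(c, c+1)$ has a defined, strictly positive median
delay.

**Velocity.** Median delays pooled by separation are converted to physical
distance $L(s) = s \times \text{spacing}$ and a Theil–Sen line (median of
pairwise slopes, free intercept) is fit to delay versus distance. Theil–Sen
was chosen because the fit has at most seven points, each itself a median
with very different pair counts, and a single noisy long-range bin should
not leverage the slope; the estimator is exact on exact lines and resistant
to one or two outlying bins. A positive slope $b$ (s/cm) gives velocity
$60/b$ cm/min; a non-positive slope leaves the velocity undefined rather
than reporting a negative speed. The single-separation estimate
`velocity_from_adjacent()` (spacing over adjacent median delay) is reported
alongside, and per-separation velocities $L(s)/\tilde{\Delta t}(s)$ provide
a constancy check.

**Surrogate control.** The null hypothesis — delay structure is an artefact
of rates, drift, or coincidence rather than timing — is tested by
destroying within-channel timing while preserving per-channel spike counts
and recomputing the whole matrix. Since permuting a channel's own onset
*set* onto itself changes nothing, count-preserving randomisation is
implemented as a uniform redraw of each channel's onsets over
$[0, \text{duration}]$ (default), with an ISI-shuffle alternative that also
preserves the interval distribution. The ensemble summary reports the
median of all adjacent-pair delays pooled across surrogates (which should
collapse to ~0) and the fraction of surrogates retaining monotone ordering
(which should be near the chance level, $2^{-(C-1)}$ for $C$ channels, i.e.
under 1% for 8 channels).

## The synthetic generator

Because the original recordings are external data, every stage is
validated against a generator whose defaults *are* the observed regime and
whose ground truth is exact:

| parameter | default | rationale |
|---|---|---|
| channels / rate / spacing | 8, 1 Hz, 2 cm | array geometry of the study system |
| duration | 2×10⁵ s | a multi-day segment holding ~200 spikes pooled |
| ISI model | lognormal, median 6.5×10³ s, `sdlog = sqrt(log 2)` | matches the observed median; shape gives CV = 1, the irregular (Poisson-like) regime |
| bursts | seed probability 0.1, 2–4 spikes, within-burst ISI ~10% of median | with mean burst size 3 this puts ~25% of spikes inside bursts (3p/(1+2p) at p = 0.1), the middle of the observed 15–35% range |
| waveform | difference of exponentials, τ_rise 80 s, τ_decay 320 s | simplest asymmetric kernel; FWHM ≈ 420 s matches the observed median width scale |
| amplitudes | lognormal, median 0.6 mV, `sdlog` 0.4, truncated to [0.2, 1.4] mV | the observed typical range |
| propagation | 0.7 cm/min (adjacent lag 171.4 s), Gaussian jitter sd 20 s | observed velocity; jitter ≈12% of the lag, comfortably inside the regime where median-based delay estimates stay unbiased |
| noise / baseline | sd 0.05 mV, per-channel offset ±0.25 mV, drift 5×10⁻⁷ mV/s | keeps total σ ≈ 0.1 mV so the 2σ threshold sits at ~0.2 mV, consistent with detectability of 0.2–1.4 mV events |

Mechanics worth knowing when interpreting recovery tests:

* Channel $c$ receives each source event at
  $t + (c-1)\cdot\text{lag} + \varepsilon$, with independent jitter per
  channel beyond the first; events shifted past either end of the
  recording, or lost to the optional failure probability, are dropped.
* Amplitudes are drawn independently per (channel, event); no
  amplitude–width correlation is imposed (none is known).
* Overlapping events superpose additively, and the detector then merges
  overlapping excursions into one longer event. Together with the
  σ-inflation effect above, this is why detected spike counts run ~15%
  below true event counts and detected widths/amplitudes are not identical
  to the generating distributions. The recovery tests therefore compare
  detected widths against a threshold-aware kernel oracle (time the
  noiseless kernel spends above the realised threshold), not against the
  raw kernel FWHM.

What the generator does **not** emulate: non-stationary rate changes over
days, electrode drift that is nonlinear in time, cross-channel amplitude
correlation, negative-polarity events, and any biophysics of the conducting
medium. Passing recovery tests therefore demonstrates that the analysis
correctly measures what the model injects — not that real recordings
satisfy the model.

## Numerical and degenerate-input choices

* Zero-variance channel → detection errors out ("threshold undefined")
  rather than returning an empty table; `validate_recording()` flags it
  beforehand.
* Empty spike tables, empty interval sets, and empty pair sets all produce
  explicit empty summaries (`n = 0`, `NA` statistics), never exceptions.
* Greedy-matching ties at equal |delay| are broken by smaller lead onset,
  then smaller lag onset, making the matching fully deterministic.
* A zero Theil–Sen slope reports `velocity = NA` with the slope intact.
* File round trips are exact: recordings are written with `%.17g`
  formatting and re-read through base R's correctly rounded parser, so a
  write/read cycle is bit-identical.
* Timestamp and value parsing fail loudly with the offending line number;
  non-monotone timestamps are an error, not silently reordered.

## Problem sizes used by the test suite

The shipped tests validate on: 10³-sample traces against a brute-force
scanner (100 replicates); 10⁵ exponential intervals for the CV → 1 limit;
4×10⁶ s single-channel trains for ISI-median and burst-fraction recovery;
and full 8-channel recordings of 2×10⁵–3.2×10⁵ s (seeds 1–10) for
end-to-end velocity recovery, 100-surrogate null collapse, and threshold
sensitivity. These sizes keep the whole suite under a couple of minutes on
one core while leaving every statistical tolerance comfortably wide
relative to sampling noise at that scale.

## Known limitations

* Onset timing is quantised at 1 s and biased late relative to the true
  event start (threshold crossing happens partway up the rise); the bias is
  common to all channels, so inter-channel delays are unaffected, but
  absolute onsets should not be over-interpreted.
* The delay analysis assumes one dominant propagation direction along a
  linear array; it does not reconstruct 2-D wavefronts or handle branching
  paths.
* With very sparse trains the lead–lag matrix develops undefined entries
  and the velocity fit loses separations; the functions degrade explicitly
  (`NA`, `n_pairs = 0`) rather than extrapolating.
* The fixed-threshold design means detection completeness varies with
  per-channel activity level; comparisons of spike *counts* across channels
  should be read with the sensitivity table in hand.
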