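---
title: "Methods: quantitative EEG staging of kainate-induced status epilepticus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative EEG staging of kainate-induced status epilepticus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizstage)
```

## The model

`seizstage` treats a seizure recording as a single-channel voltage trace
(µV) accompanied by a telemetry activity channel (counts/min). The analysis
unit is the 10-s epoch. Each epoch is described by eleven features: four
spike-train features (mean amplitude in µV, mean duration in ms, median
inter-spike interval in ms, rate per minute), six band powers (delta
0.5–4 Hz, theta 4–8, alpha 8–12, sigma 12–16, beta 16–24, gamma 24–80,
per 10-s epoch), and the activity count of the containing minute. A
versioned rule table (`inst/extdata/stage_rules.csv`) assigns each stage
label — 1, 2, HFT, 3A, 3B, 4, 5 — a range for every feature; an epoch's
stage score for a label is the fraction of its features inside that
label's ranges. This range-membership score is the package's formalization
of how an expert reads the same features off the trace; the table cells
themselves are published values and are covered by a golden-file test.

Three artifact classes are recognized before any stage scoring, and
artifact epochs are excluded from every downstream statistic:

* **electrical** — any event above 2 mV lasting under 20 ms;
* **grooming** — delta, theta and alpha elevated above the stage-free
  baseline (delta > 10, theta > 5, alpha > 3 power units) while sigma,
  beta and gamma stay below 5, with no supra-threshold spikes and no
  activity;
* **movement** — activity counts with all six band powers at baseline and
  a detected slow (> 0.6 s) deflection. Precedence is electrical >
  grooming > movement.

The `baseline` class is not part of the published stage table; it is
defined here as "no spikes above 200 µV and all band powers below 5
units", the published description of pre-treatment recordings.

## Units: reconciling µV spikes with the printed power unit

The published stage table prints spike amplitudes in µV (200–1500 µV) and
band powers in "mV²" per 10-s epoch (e.g. stage-2 delta 25–50). Taken
literally these are inconsistent, in both directions:

1. If band power is the periodogram integral of the trace *in mV*, a
   stage-2 background implies a noise standard deviation of several mV —
   more than an order of magnitude above the largest printed spike, which
   would then be undetectable. The same table states that baseline
   amplitude is below 0.2 mV while baseline total power is below
   30 "mV²" (sd > 2 mV), which no single trace can satisfy.
2. Conversely, the printed spike trains alone (e.g. stage 2: eight
   400-µV-scale, 250-ms spikes per epoch) carry a band-power integral
   orders of magnitude above the printed power ranges, so the printed
   powers cannot include spike energy at any scale that keeps spikes
   detectable.

The package therefore adopts one explicit convention, used consistently by
the generator and the analysis:

* the trace is in µV and the printed amplitudes are literal;
* one printed power unit corresponds to `power_scale = 10` µV² of
  one-sided periodogram band integral — a fixed acquisition-gain
  calibration constant (configurable in `sim_config()` and
  `band_power()`);
* band powers are measured on the trace with detected spike events
  excised, i.e. they describe the ongoing background activity. With no
  exclusions the estimate is the exact FFT periodogram (a bin on a shared
  band edge belongs to the lower band; the trailing partial epoch is
  discarded); with exclusions the same frequency grid is evaluated by a
  Lomb–Scargle least-squares periodogram over the remaining samples,
  normalized against the full grid length, which makes the estimate
  insensitive to the excised fraction (verified down to 30% retained; an
  epoch with less than 30% of its samples left reports NA).

The default `power_scale` is the value at which the printed power ranges,
the printed spike amplitudes, the 200-µV detection threshold and the
artifact rules are *simultaneously* realizable: backgrounds are then
40–70 µV sd at the strongest stages, leaving the smallest margin-shrunk
spikes at about five noise standard deviations.

## Spike detection

Detection operates on the absolute deflection from a 4-s running-median
baseline. The window length matters at the extremes of the published
ranges: stage-3B spikes recur with duration ≈ ISI, so a short window holds
too few spikes for the median to reject them; 4 s spans enough
alternating-polarity spikes that the median stays on the background. An
event is a run of samples above half the threshold containing at least one
sample above the threshold (hysteresis keeps complex multi-lobed spikes in
one event); runs closer than `min_separation_ms` (default 8 ms, two sample
periods at 250 Hz) are merged; runs wider than 600 ms are rejected as slow
deflections and handled by `detect_slow_deflections()` (20-s baseline,
≥ 0.6 s width), which feeds the movement-artifact rule and the slow-event
excision of the spectral estimate. Amplitude is the peak deflection;
duration is the width between linearly interpolated threshold crossings —
for the near-rectangular-shouldered waveforms the generator produces this
approximates the nominal duration, whereas for an ideal triangle it is
`(1 − threshold/amplitude)` of the base width; the measurement level is a
documented convention, not a claim about the underlying shape. The default
threshold of 200 µV is the published upper bound of baseline spike
amplitude.

## HFT detection and transition markers

High-frequency-trigger spikes arrive in bursts: the published within-burst
inter-spike interval is 25–60 ms while the published frequency is
120–200/min, which is only consistent if the per-minute count includes
inter-burst gaps. `detect_hft()` therefore finds maximal runs of at least
5 spikes whose amplitude (300–1000 µV), duration (20–40 ms) and
consecutive ISIs (25–60 ms, ±1.5 sample periods of quantization allowance,
measured between event-extent midpoints, which are more stable than peak
positions for 6-sample spikes) all qualify, merges runs separated by less
than 5 s, and keeps intervals whose epochs show the published HFT
signature: alpha and sigma above the baseline bound with no
convulsive-level activity (counts ≤ 8, the stage-3A bound — a brief HFT
shares its epoch with a neighboring stage, so requiring exactly zero
counts would veto genuine triggers). The minimum run length of 5 is a
design choice: at the slowest ISI a run lasts ≥ 0.24 s, shorter than the
briefest published trigger.

Two spectral markers are emitted by `detect_transitions()`: the NCS→CMS
transition at the first epoch where delta has fallen to half (default,
configurable) of its stage-2 peak while beta and gamma both exceed their
stage-2 epoch means, and the 3A→3B transition at the first subsequent
theta excursion above the stage-3A upper bound (12 units). The 50% drop
quantifies the published qualitative "reduction of peaked delta"; only the
first crossing is emitted, so one synthetic episode yields exactly one
marker, and the 3A→3B search starts at the NCS→CMS marker, which enforces
the marker ordering within an episode.

## The synthetic world

The generator's defaults are the published conditions; everything below is
sampled from the published ranges after shrinking each range toward its
midpoint by `margin` (default 0.2) so that classes are separable — the
published ranges overlap heavily, and the margin models the fact that a
typical epoch sits inside its stage's envelope rather than on the shared
boundary.

* **Spikes.** A near-rectangular-shouldered base waveform
  (`sin(πu)^(1/8)` with a small apex bump pinning the peak) with a shallow
  negative after-wave; complex stages (3A, 3B, 5) add within-spike
  sub-peak modulation, stage 4 adds a 100–140 Hz ripple burst at the peak
  (the "paint brush"), and spikes under 50 ms carry a reduced after-wave
  so tightly packed HFT spikes never fuse in the detector. Polarity is
  random. Spikes are placed in clusters whose within-cluster ISIs obey the
  ISI column while the per-segment count obeys the rate column (the two
  published columns are inconsistent for continuous spiking — e.g. stage
  1: ISI 400–1400 ms implies > 43/min against a printed rate of 20–35/min
  — and the burst structure is how the HFT row resolves the same tension
  explicitly). Durations are capped at `ISI_hi − 15 ms` and ISIs are drawn
  at least 12 ms beyond the mean of the adjacent durations so that
  consecutive spikes remain separable events; all values stay inside the
  printed ranges.
* **Background.** Per 10-s epoch (aligned to the recording grid),
  band-limited Gaussian noise is shaped in the frequency domain so that
  the *spike-excised* band-power measurement — the same estimator the
  analysis uses, with the mask obtained by running the detector on the
  spike-only trace — hits a per-epoch target sampled from the label's
  shrunk range. Treating the printed power ranges as per-epoch envelopes
  (rather than stage means) is a documented reading of an ambiguity in the
  source. Baseline epochs get per-band targets derived from
  `baseline_noise_sd` (default 10 µV total), below the 5-unit bound.
* **Activity.** Counts per minute drawn from the published per-stage
  ranges (0 for baseline/1/2/HFT; 0–8 for 3A; 20–120 for 3B; 20–80 for 4;
  30–60 for 5), by the stage occupying most of each minute, independent of
  the voltage trace (telemetry computes it separately).
* **Artifacts.** Electrical: 2.2–4 mV monophasic spikes of 6–15 ms.
  Grooming: three windowed oscillation components sized so that epoch
  delta ≤ 700, theta ≤ 100 and alpha ≤ 10 units while the other bands are
  untouched. Movement: smooth Gaussian deflections of 600–1000 µV with
  σ = 1.1–1.5 s — wide enough that essentially all their energy lies
  below the 0.5 Hz delta edge, which is the only way a "slow large spike"
  can leave the 0.5–80 Hz spectrum unchanged, as published — with paired
  activity counts of 20–80/min. Ground-truth artifact epochs are those
  containing an electrical spike, ≥ 2 s of a movement deflection's
  supra-300-µV extent, or ≥ 50% grooming overlap (an epoch brushed by an
  artifact tail is not identifiable as artifact by any power rule).
* **Baseline spikes.** Sparse sub-threshold spikes (30–80 µV, 20–50 ms,
  2–8/min). Their energy budget is what bounds them: a baseline epoch must
  stay below 5 power units per band even though sub-threshold spikes are
  not excised from the measurement.

What a green test does and does not establish: the generator is
phenomenological. It reproduces the published feature distributions, not
kainate pharmacology, neural dynamics, electrode drift, line noise, or
inter-animal variability in waveform shape; behavioral stage exists only
as a label. Recovery results on this world certify the pipeline's
internal consistency at the published operating point — they are not a
validation against animal recordings, which are not distributed.

## Severity scoring

Behavioral scoring collapses the EEG 3A/3B split to stage 3 (the A/B split
is an EEG refinement of a five-stage behavioral scale). A 5-min epoch
scores the highest stage it contains. The SE window is 2 h from the index
seizure — first stage-5 onset for RLD, first CMS (stage ≥ 3) for SHD; a
diary without the index seizure returns an explicit "SE not achieved"
value rather than a zero score. Time in CMS and time in stage 5 are
interval overlaps with the window, clipped at diazepam or death
(intervals straddling the window edge are clipped, not dropped; epochs
beyond the recorded diary score 0). The cumulative severity score is the
sum of the 24 epoch scores — the stage-sum reading of the published
"the more severe the seizures, the higher the score", adopted and
documented here because it is the only reading that is monotone in both
stage and time (the property the tests assert).

## Cohort simulation and statistics

The outcome model carries the published frequencies: RLD death given
stage 5 = 5/79, SHD death given stage 5 = 5/16, SHD stage-3 attainment
22/24, SHD stage-5 attainment 0.65 (the printed percentage; the figure
counts give 16/24 = 66.7% — the discrepancy is in the source and the
probability is exposed as a parameter, not resolved). The RLD per-dose
stage-5 hazard is a calibration, not a published law: piecewise constant
with stage 5 reachable from dose 3 (15 mg/kg), fit so that 76% of animals
reach stage 5 by 25 mg/kg, 95% by 35 mg/kg and 96% overall — the three
published cumulative attainment figures. Death is sampled only among
animals that reached stage 5 (all published deaths occurred during SE
after stage-5 onset); pre-SE death is a parameter defaulting to 0.
Simulated diaries spend a per-epoch Bernoulli fraction of the SE window in
CMS (0.55 RLD, 0.21 SHD, matching the published ≥ 60 vs ≥ 25 min of CMS
per 2-h window).

`binary_t_test()` is the pooled-variance unpaired t on 0/1-coded outcomes,
computed in closed form (the survival comparison 19/24 vs 77/82 gives
t = −2.20 on 104 df, p = 0.030, matching the printed p = 0.029). The
spike-rate comparison uses a two-way ANOVA with interaction on the
balanced group × epoch layout; for 2 groups × 9 animals × 24 five-min
epochs the residual degrees of freedom are 2·9·24 − 2·24 = 384, which
reproduces the published "1 and 384" exactly — the interaction model is
the only layout consistent with those numbers, resolving what the
published text leaves ambiguous. Reported percentages are rounded half-up
to integers as printed; raw fractions are always retained.

## Numerical choices and degenerate inputs

* Sampling rate: unstated in the source (proprietary telemetry); default
  250 Hz, must exceed 160 Hz or the gamma band is refused (NA with a
  warning), never silently truncated.
* Epochs are aligned to the recording start, contiguous, no overlap;
  rectangular windowing keeps the power convention comparable to the rule
  table.
* Classification ties break toward the temporally previous label, else
  toward the higher stage (temporal continuity mirrors expert reading);
  the non-artifact label sequence is median-smoothed over 3 epochs on the
  ordinal stage scale.
* The epoch ISI feature is the median ISI: between-cluster gaps inside an
  epoch would otherwise drag a mean outside every published range.
* Stage-3A vs movement (both low power, both with activity): movement
  requires a detected slow deflection and all-baseline powers; 3A requires
  spike-range membership. Epochs too occluded to measure power (< 30%
  samples left) are classified movement when a slow deflection and
  activity coincide, otherwise left unlabeled.
* Empty inputs: an empty record is an error; a flat trace is an empty
  spike train; an empty stage plan yields an empty activity channel; a
  zero-variance t-test is reported as undefined, not as p = 1.

## Known limitations

* The power/amplitude unit reconciliation is a modeling decision forced by
  an inconsistency in the source; `power_scale` is configurable but all
  published numbers are reproduced only at the documented default.
* The classifier is the published rule set, not a learned model; its
  accuracy guarantees hold on the synthetic world at margin 0.2 and say
  nothing about margin-0 boundary epochs, which overlapping published
  ranges make genuinely ambiguous.
* Stage-5 "baseline shoot" episodes are not modeled as a separate class.
* EDF output pads recordings with zeros to whole 10-s records and
  quantizes to 16 bits over ±8 mV.
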