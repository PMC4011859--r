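# seizstage

Quantitative video-EEG staging of chemoconvulsant-induced status
epilepticus (SE) in the mouse.

## The problem

Kainate (KA) is the standard chemoconvulsant for inducing SE in C57BL/6J
mice, but this strain responds inconsistently: a single high dose (SHD,
20 mg/kg i.p.) kills ~21% of animals while only ~65% ever reach the
generalized tonic-clonic (Racine stage-5) seizures that define a usable SE
model. Titrating repeated low doses (RLD, 5 mg/kg i.p. every 30 min until
stage-5 onset) drops mortality to ~6% and raises stage-5 attainment to
~96%. Quantifying that comparison — and reading the seizure stage off the
EEG at all — requires a reproducible pipeline from raw single-channel
telemetry EEG to stage labels, severity scores and cohort statistics.

`seizstage` implements that pipeline for R users:

* **synthetic recordings** with per-stage ground truth (no animal data are
  distributed; every downstream stage is testable against a generator that
  reproduces the published stage-specific spike morphology, band powers and
  activity counts);
* **feature extraction**: threshold spike detection (amplitude, duration,
  inter-spike interval, rate) and per-10-s-epoch band powers
  (delta 0.5–4, theta 4–8, alpha 8–12, sigma 12–16, beta 16–24,
  gamma 24–80 Hz) by periodogram integration, with spike events excised via
  a Lomb–Scargle estimate so the powers describe background activity;
* **rule-based staging** of each epoch into {baseline, 1, 2, HFT, 3A, 3B,
  4, 5} from an explicit published range table, plus artifact rejection
  (electrical, movement, grooming), high-frequency-trigger (HFT) interval
  detection and the two spectral transition markers (NCS→CMS delta
  collapse with beta/gamma rise; the transient theta rise at 3A→3B);
* **behavioral severity**: per-5-min-epoch Racine scores (highest stage in
  the epoch), the 2-h SE window from the protocol's index seizure, time in
  convulsive motor seizures (CMS, stage ≥ 3), time in stage 5, and the
  cumulative seizure severity score;
* **cohort simulation and statistics**: RLD titration vs SHD outcome
  simulation calibrated to the published frequencies, binary-coded pooled
  t-tests, the two-way ANOVA on 5-min spike rates (df 1 and 384 for the
  published 2 × 9 × 24 layout), and the animal-wastage arithmetic.

## Worked example

Synthesize a two-minute-style seizure progression (baseline → stage 2 →
brief HFT → 3A → 3B → 4 → 5), analyze it, and inspect the results:

```r
library(seizstage)
plan <- data.frame(label   = c("baseline","2","HFT","3A","3B","4","5"),
                   duration = c(30, 40, 5, 40, 40, 40, 40))
syn <- synthesize_recording(sim_config(plan, seed = 1))
ana <- analyze_record(syn$record)
print(syn$record)
#> <eeg_record> 58750 samples @ 250 Hz (235.0 s), 4 min activity
print(ana$train)
#> <spike_train> 196 spikes over 235.0 s (50.0 /min)
table(ana$epochs$label)
#>        2       3A       3B        4        5 baseline
#>        4        4        4        5        3        3
ana$hft
#>    start    end
#> 1 70.252 74.748
ana$transitions
#>   time        marker
#> 1   70    ncs_to_cms
#> 2  110 stage3a_to_3b
```

Every 10-s epoch is labeled with its seizure stage; the 5-s HFT burst at
70–75 s is recovered as one interval, and the delta-collapse marker for
the NCS→CMS transition lands exactly at the stage-2/CMS boundary, with
the theta marker at the 3A/3B boundary (115 s, within one epoch).

Cohort arithmetic from the published outcome counts:

```r
s_rld <- summarize_cohort(cohort_from_counts(82, 5, 79, 81, "RLD"))
s_shd <- summarize_cohort(cohort_from_counts(24, 5, 16, 22, "SHD"))
print(s_rld)
#> <cohort_summary> n = 82: mortality 6%, stage-5 96%, stage-3 99%
print(s_shd)
#> <cohort_summary> n = 24: mortality 21%, stage-5 67%, stage-3 92%
binary_t_test(c(rep(1, 19), rep(0, 5)), c(rep(1, 77), rep(0, 5)))$p
#> survival coding: t = -2.20 on 104 df, p = 0.030
wastage(list(mortality_pct = 21, stage5_pct = 65), s_rld)$total
#> 46  (15 mortality points + 31 attainment points)
```

The RLD protocol saves 46 percentage points of animal wastage: 15 from
mortality (21% → 6%) and 31 from stage-5 attainment (65% → 96%).

## Command line

```sh
exec/seizstage synth    --config cfg.json --seed 1 --out rec.edf
exec/seizstage features rec.edf --out feats.csv
exec/seizstage classify feats.csv --rules inst/extdata/stage_rules.csv
exec/seizstage severity diary.csv --protocol RLD
exec/seizstage cohort   --protocol RLD --n 82 --seed 7
exec/seizstage run      --config run.json --out-dir out/
```

Recordings are read and written as EDF (one EEG signal plus a 0.1 Hz
activity signal) or plain CSV; the stage rule table ships as
`inst/extdata/stage_rules.csv`.

## Further reading

The methods vignette (`vignettes/seizure-staging.Rmd`) documents the
model, the unit conventions (including why the printed power unit cannot
be a literal mV² alongside µV spike amplitudes, and how the package
reconciles the two), the synthetic-data generator's stated world and its
limits, and all numerical choices.
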