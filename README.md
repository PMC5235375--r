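# quero

Acoustic event detection and vocal-activity phenology for the Southern
Lapwing (*Vanellus chilensis*, the *quero-quero*), built for passive
soundscape monitoring in seasonally flooded wetlands.

A lapwing's calling rate tracks its life cycle: suppressed during flood,
climbing through incubation, stepping up ~64 % at hatching, decaying through
chick-rearing, and switching between a dawn/dusk ("two-peak") and an all-day
diel mode. `quero` turns year-long 24/7 recordings into that signal:

* **Detector** — a GMM-UBM architecture: 90 per-frame descriptors (35
  linear-frequency cepstral coefficients + Δ + first 20 Δ²) over an
  AGC → 24 kHz → order-10 Butterworth 1-kHz high-pass front end; a
  diagonal-covariance universal background model trained by EM; a target
  model by MAP means-only adaptation (relevance factor r); per-frame
  log-likelihood-ratio scoring `llr = log p(x|target) − log p(x|UBM)`
  against a calibrated threshold θ, with a −50 dBFS activity gate.
* **Events** — frame decisions smoothed by the two domain rules (calls
  ≥ 50 ms; gaps ≤ 0.6 s merge into one call series), timestamped
  absolutely from Song-Meter-style filenames.
* **Validation** — precision H/(H+I), accuracy (H−I)/N, correct H/N,
  missed (N−H)/N; double-hit and unconfirmed-event handling; random-sample
  sizing `max(150, 2 %)`; cumulative 5-dB amplitude tables.
* **Phenology** — day/night partition (sunrise −1 h to sunset +45 min,
  NOAA solar equations), false-positive-corrected period counts, daily and
  quarter-hour diel profiles, one-tailed exact Spearman test against water
  level, and a lunar-phase one-way ANOVA (log10(x+1), df 2,36) with Tukey
  HSD.
* **Synthetic world** — harmonic-stack call scenes with exact ground truth
  and a quarter-hour season simulator with the full phase structure, so the
  entire pipeline is testable offline.

## Worked example: correcting a season of detections

The bundled tallies of a 2013 Pantanal season (eight acoustic activity
periods, with the expert verdicts of the per-period random samples) feed the
correction arithmetic:

```r
library(quero)
rep <- activity_report(lapwing_periods())
rep[, c("id", "raw_day", "raw_night", "precision_pct",
        "corrected_day", "corrected_night", "corrected_total")]
```

```
    id raw_day raw_night precision_pct corrected_day corrected_night corrected_total
     1    2301       209          35.8           823              75             898
     2    4093       210          71.0          2905             149            3054
     3    4428      1281          77.2          3418             989            4407
     4    5796       607          87.7          5085             533            5618
     5   12355      1740          93.5         11548            1626           13175
     6    8899       468          97.0          8631             454            9085
     7    4078       619          92.6          3777             573            4350
     8    1642       153          68.7          1128             105            1233
 total   43592      5287          81.6         37315            4504           41819
```

Each period's detections are scaled by its sampled precision (e.g. period 1:
only 39 of 109 validly sampled detections were real lapwings, so 2301
daytime detections correct to 823). The total row pools the 1014/1242
verdicts (81.6 %) and rounds the *sum of unrounded* corrections — hence
41 819, one less than the sum of the rounded cells.

The validation library's amplitude table works the same way without audio:

```r
tail(bin_by_db(expand_db_bins(lapwing_validation_bins())), 3)
```

```
     range n_target n_unconfirmed n_total pct_unconfirmed
  0 to -45      603            38     641             5.9
  0 to -50      804           120     924            13.0
 0 to -Inf      898           454    1352            33.6
```

i.e. 13 % of events down to −50 dBFS were too ambiguous for an expert to
confirm, rising to a third when arbitrarily faint events are included.

## Worked example: a synthetic scene and season

```r
sc <- render_scene(scene_spec(8, sample_rate_hz = 24000,
  calls = list(call_spec(onset_s = 2, peak_dbfs = -25),
               call_spec(onset_s = 5, peak_dbfs = -30)), seed = 7))
sc$annotations
#>   start_s end_s  label peak_dbfs
#> 1       2  2.52 target       -25
#> 2       5  5.52 target       -30

spec <- season_spec(seed = 1)
daily <- aggregate(true_count ~ date, simulate_season(spec), sum)
names(daily)[2] <- "total"
estimate_hatch_date(daily)
#> [1] "2013-06-13"        # the injected hatch day

pw <- pair_water_activity(spec$water_level_curve[-1, ], daily)
spearman_one_tailed(pw$cm, pw$activity)[c("rho", "p")]
#> rho = -0.939, one-tailed p = 1.03e-04 (exact permutation)
```

The end-to-end detector study (`detector_study(seed = 1)`: 64-component UBM
on ~10 min of synthetic background, adaptation on ~2 min of calls, θ from a
development scene) reaches event-level precision 0.93 at miss rate 0.07 on a
held-out scene — the desk-scale stand-in for the field configuration
(512 components, 75 h of training audio).

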