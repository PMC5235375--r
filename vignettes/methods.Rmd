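---
title: "Methods: detecting lapwing calls and reading a breeding season from them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting lapwing calls and reading a breeding season from them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The Southern Lapwing (*Vanellus chilensis*) is a noisy, year-round-vocal
shorebird whose calling rate tracks its life cycle: suppressed while its
territory is flooded, climbing through incubation as parents defend the
clutch, jumping abruptly when chicks hatch, then decaying over the weeks of
parental care. A passive recorder that runs 24/7 therefore contains a
phenology signal — if the tens of thousands of call events can be found
automatically and the detector's error structure is accounted for.

`quero` implements that whole chain: a GMM-UBM call detector over an LFCC
front end, the temporal smoothing that turns frame decisions into call
events, the validation statistics used to quantify the detector, the
false-positive-corrected activity tables and diel profiles, and the two
inferential tests (water-level rank correlation, lunar-phase ANOVA). Because
no public recordings accompany the workflow, the package also contains a
first-class synthetic world — audio scenes with exact ground truth, and a
season simulator with the phase structure above — so every claim the test
suite makes is checked against a known truth.

## The detector

**Front end.** Each recording is amplitude-normalised to full scale (AGC),
down-sampled to 24 kHz (removing insect song at or above 12 kHz), high-pass
filtered with an order-10 Butterworth at 1 kHz (removing wind and engine
rumble), and cut into 20-ms frames every 5 ms. Per frame we compute 35
linear-frequency cepstral coefficients (40 triangular filters spanning
0-12 kHz, orthonormal DCT-II, coefficients c1..c35), their ±2-frame
regression first derivatives, and the first 20 second derivatives: 90
descriptors per frame. A frame participates in scoring only if its energy is
at least −50 dBFS *referenced to the raw input* (the AGC gain is subtracted
from frame energies), below which even an expert cannot annotate calls
confidently.

Numerical choices worth knowing:

* **c0 is dropped**, so features are exactly invariant to amplitude scaling
  (doubling the waveform shifts every log filter energy by the same constant,
  which lands entirely in c0). The filterbank size (40) is a conventional
  choice; the source architecture specifies only "35 LFCC".
* **0 dBFS is defined as RMS 1.0** (a full-scale square wave); a full-scale
  sine reads −3.01 dBFS. The convention is arbitrary but fixed and
  documented, and only shifts the gate threshold by a constant.
* **The high-pass is applied forward-backward** (zero phase), so event
  timestamps are not skewed by filter group delay; the per-pass magnitude at
  the cut-off is then −6.02 dB rather than −3.01 dB.
* **Standardisation** maps each of the 90 dimensions affinely to [−1, 1]
  using training-set min/max, clipping unseen values; a constant dimension
  maps to 0. Statistics are frozen at training time and stored with the
  model.
* The resampler is a Kaiser-windowed FIR (80 dB stopband); only band
  attenuation contracts are asserted, not sample values, since the exact
  kernel is a free implementation detail.

**Models.** The universal background model is a diagonal-covariance Gaussian
mixture trained by EM (k-means++ initialisation, variance floor at 1e-4 of
the global per-dimension variance, empty components re-seeded from the
widest component). The target model is derived by classical MAP means-only
adaptation with relevance factor r = 16: component means move toward the
posterior-weighted target-data means by a factor n_k/(n_k + r); weights and
variances stay shared with the UBM. Frames are scored by the log-likelihood
ratio of the two mixtures (log-sum-exp, exact) and thresholded at θ.

θ is a free parameter of this architecture — the source work never states
its value — so the package calibrates it on a development scene by
maximising event-level F1 and logs the full sweep.

**Events.** Two domain rules convert frame decisions to events: a call lasts
at least 50 ms, and calls separated by at most 0.6 s form one call series.
Implemented as: close gaps ≤ 50 ms (fragmentation repair), drop runs still
shorter than 50 ms (run duration counts the 20-ms window tail, so one
positive frame spans 20 ms), then merge events ≤ 0.6 s apart. Gaps are
measured frame-start to frame-start. The equivalence of this
morphological formulation with a naive run-length reference is property-
tested on 10 000 random decision vectors.

A consequence of series merging worth stating: **event-level ROC curves are
not monotone in θ.** At a very low threshold the entire scene fuses into one
event, which can credit only one annotation. The monotone-ROC property of
the detector is therefore asserted at frame level, where `llr ≥ θ` is
pointwise monotone by construction.

## Validation statistics

With H hits, I insertions, N confirmed target events:
precision = H/(H+I), accuracy = (H−I)/N, correct = H/N, missed = (N−H)/N
(all ×100). `correct + missed = 100` is an identity and is property-tested.
Matching follows the expert-validation protocol: the first detection
overlapping an annotated event is the hit, later ones are double hits
(excluded from H and I); detections overlapping only "unconfirmed"
annotations are excluded from the valid sample; a detection spanning two
annotations credits the earlier one. Any positive temporal overlap counts
(a minimum-overlap fraction is exposed but defaults to 0).

Percentages are rounded **half-up** to one decimal; corrected counts are
kept unrounded internally, displayed half-up, and **totals round the sum of
unrounded values** — this reproduces the printed grand total of 41 819,
which differs by 1 from the sum of the rounded cells (41 820). The bundled
example tables (`lapwing_periods()`, `lapwing_validation_bins()`) carry the
printed per-period tallies of a 2013 Pantanal season so this arithmetic is
exercised without audio.

The random-sample size rule is `min(D, max(150, round(0.02 D)))` per month;
it is a default, not a straitjacket — the historical samples occasionally
drew slightly more (e.g. 293 = 2.1 % of 14 095), so samplers take n
directly.

## Activity analysis

"Daytime" runs from one hour before sunrise to 45 minutes after sunset
(closed interval), computed by the NOAA solar-position equations at the
station coordinates (−16.50303, −56.74533, UTC−4). Lunar phase uses a
synodic-month approximation anchored at the 2000-01-06 new moon (checked
against the 23 June 2013 full moon); an exact phase table can be substituted.
The moonlight ANOVA takes three groups of 13 nights centred on new moon /
full moon / next new moon, transforms counts as log10(x + 1) — the +1 guards
zero-count nights, which a plain log cannot handle — and follows the one-way
F test (df 2, 36) with Tukey HSD at α = 0.01 via the studentized-range
distribution. The textbook sums-of-squares implementation is cross-checked
in the tests against `stats::aov`/`TukeyHSD`.

The water-level test is a one-tailed Spearman correlation (alternative:
activity falls as water rises... i.e. rho < 0), exact by full enumeration of
rank permutations for n ≤ 10 without ties (a C++ `next_permutation` loop over
at most 10! arrangements), t-approximate otherwise. Water readings pair with
activity averaged over a 5-day window centred on the reading date; the
centring convention is configurable because the historical description does
not fix it.

## The synthetic world, and what a green test proves

**Scenes.** Target calls are harmonic stacks: k·f0 partials with 1/k
amplitude roll-off, 5-ms raised-cosine note edges, ±2 % per-note f0 jitter,
peak level set exactly in dBFS. This reproduces the property the detector
exploits — energy spread across many harmonics of a ~1.3 kHz fundamental —
without claiming acoustic realism of the actual repertoire. Nontarget calls
are single-harmonic whistles at 2-4 kHz. Backgrounds are Gaussian broadband
noise plus a low-passed wind band (< 640 Hz) and a tonal insect cluster
(≥ 12.5 kHz), chosen to give the front end's filters something to remove.
Mixing that would clip full scale is an error, not a silent saturation.

**Seasons.** Daily intensity follows eight phases patterned on the 2013
season: 19 (flood) / 110 (territorial) / 90 (laying dip) / 467 (incubation)
/ 766 (hatch = 467 × 1.64) / 489 (tending) / 220 (decay) / 43
(post-breeding) events/day. Two transitions are linear ramps rather than
steps, following the source narrative: an 8-day climb into the territorial
level (birds resume patrolling while water recedes) and an 8-day build-up at
the start of incubation (defence reached ~470/day by day 12 of incubation).
Without those ramps the incubation onset would be the largest jump in the
series and no estimator could date hatching from counts alone; with them the
hatch day remains the only one-day step. Each day's intensity is spread over
96 quarter-hours by a two-peak profile (dawn/dusk Gaussians, σ = 45 min,
2 % floor) or an all-day profile (daytime floor at 44 % of peak) — the
tending phases use all-day, matching midday activity observed at ~45 % of
maximum — and night bins are multiplied by 2 on moonlit nights. False
positives are an independent uniform Poisson stream at each phase's
contamination fraction (taken from the printed period precisions).

What the simulator does **not** emulate: overlapping choruses of multiple
birds, amplitude-dependent miss rates, nonstationary noise floors, recorder
duty cycles, or weather. A green end-to-end test therefore establishes that
the pipeline is *internally correct* (it recovers what was injected, at the
stated operating point), not that the detector would achieve the same
precision on Pantanal audio.

**Hatch-date estimator.** The largest *sustained* jump: for each day,
compare the mean of the following five days with the mean of the preceding
five (equivalently, the 5-day smoothed series after vs before the day).
Block means rather than single-day differences are what separates the
one-day hatch step from the (smoothed) incubation ramp; the estimator
recovers the injected date exactly across seeds and is intended for
synthetic recovery, not as a formal change-point model.

## Scale choices and limitations

The desk-scale acceptance study uses K = 64 components on ~10 min of
background and ~2 min of target calls (the field configuration, K = 512 on
75 h, is available via arguments but not desk-reproducible); it reaches
event precision ≈ 0.93 at miss rate ≈ 0.07 in about three minutes on one
CPU. EM is capped at 100 iterations there (tolerance 1e-5 relative
log-likelihood; the cap is rarely reached). The exact Spearman path
enumerates up to 10! permutations (~0.5 s); ties always fall back to the t
approximation. Rational-ratio resampling with a large upsampling factor
materialises the zero-stuffed signal and is intended for short clips; the
field-relevant integer decimations (48 kHz → 24 kHz) take the fast path.
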