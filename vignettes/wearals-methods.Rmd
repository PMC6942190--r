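---
title: "Methods: multi-sensor remote monitoring analysis for ALS studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sensor remote monitoring analysis for ALS studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wearals` analyses three data modalities collected in remote-monitoring ALS
studies — tri-axial chest accelerometry, interbeat-interval (RR) series, and
in-clinic speech recordings — and aggregates them into longitudinal cohort
endpoints. This vignette is the package's account of the methods: the models
and their assumptions, the parameters that matter, what the synthetic cohort
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Study structure assumed

A cohort of ambulant ALS patients is followed for 48 weeks. Each month a
patient wears a chest sensor for about three consecutive days at home
("home-monitoring period"), setting aside two hours per 24-hour period to
recharge it; at quarterly clinic visits the patient performs a battery of
labelled reference tasks (postures, walking, stair climbing, transitions,
the nine-hole peg test) and four speech tests. The package represents this
as a patient × timepoint grid; missing cells are first-class citizens, never
silently dropped, because attrition and adherence are themselves endpoints.

## Physical activity

**Activity score.** Movement intensity per 1-minute epoch. Gravity is
removed with a 4th-order Butterworth high-pass at 0.5 Hz applied per axis
(forward–backward, so zero phase). Each contiguous recording run is demeaned
before filtering: a forward–backward IIR filter started on a ~1 g DC offset
produces edge transients that otherwise leak a few percent of a walking
epoch's score into motionless epochs. The score is the sum over epoch
samples of the filtered vector magnitude, scaled by `1000 / rate_hz` so that
the same movement sampled at 50 Hz or 100 Hz scores the same (tested to
within 5 %). Scores are reported in arbitrary "counts".

**Epoch features and 3-class classification.** Each fully labelled 1-min
epoch yields 14 features chosen so the three classes are separable by
orientation (per-axis means: lying vs upright), variance (per-axis and
vector-magnitude SDs: sedentary vs active), and periodicity (dominant
frequency of the gravity-removed magnitude in 0.5–5 Hz and its power share:
gait). Inter-axis correlations and the epoch score complete the set. Epochs
straddling a label boundary are discarded, not truncated: the feature
contract is a fixed 60-s window. The classifier is gradient-boosted decision
trees (xgboost, single thread, fixed seed, class-balanced weights) — a
strong deterministic tabular baseline with no feature-scaling sensitivity.
Postural transitions are mapped to *active* (they are movements, and the
label set has only three classes); the nine-hole peg test maps to *sedentary
but not lying* as low-intensity movement.

**Validation.** Leave-one-patient-out: for each patient, train on all
others and predict the held-out epochs; pool all held-out predictions into
one 3 × 3 confusion matrix and report per-class one-vs-rest accuracy,
sensitivity and specificity. Pooling (rather than averaging per-fold
metrics) is assumed because per-patient epoch counts are small. Healthy
volunteer reference sessions can be added as training-only patients: they
join every training fold but are never held out. Per-minute classification
of home data applies a 3-minute majority smoother and never labels nonwear
minutes.

**Endpoints.** All "per hour" and percentage endpoints are normalized to
wear time within a configurable daytime clock window, default 06:00–22:00
local (the studies this serves distinguish "daytime" from "24-hour"
endpoints without defining daytime; 06–22 is the conventional waking
window). Averages are per-valid-day means. Active periods are maximal runs
of active minutes, binned as >1–≤2, >2–≤5, >5–≤15 minutes; 1-minute runs are
excluded from ">1 min" statistics. Duplicating a day's data changes no
percentage or per-hour endpoint (tested invariant).

## Wear time

Nonwear is detected two ways: recording gaps (> 60 s without samples — the
device off or charging) and still-nonwear (every axis SD below 0.004 g for
at least 30 consecutive minutes — off-body but recording; both defaults are
conventional actigraphy heuristics and exposed as arguments). Intervals
separated by under 5 minutes merge. Each calendar day (local midnight
boundaries; day-quality accounting follows calendar days) is partitioned
minute-by-minute into wear / nonwear / no-data — the three always sum to
1440 — using a ≥ 30 s-in-minute rule so the partition is exact. A *valid
day* has ≥ 18 h of wear; a *partial day* has any data at all. The coverage
matrix counts valid and partial days per patient × timepoint and summarizes
the fraction of cells with ≥ 3 days, the fraction with no data, and the
per-timepoint percentage of patients providing any data.

## Heart-rate variability

**Cleaning.** Beats outside 300–2000 ms, or differing from the previous
retained beat by more than 25 %, are rejected with a logged reason. The
25 % rule is a standard ectopic/artefact screen.

**Windows and retention.** Tumbling 5-min windows (2-min RMSSD or 3–4-min
LF/HF windows are available via `window_s` but are not defaults). Retention
is *time coverage*: the summed RR intervals of the window's beats (clipped
to the window) divided by 300 s. A beat-count definition would read
bradycardic windows as under-covered; time coverage does not. Sufficiency
thresholds default to 0.88 (RMSSD) and 0.99 (LF/HF); a metric is only
computed where its flag holds, so "fraction of sufficient windows" is
reproducible from flags alone.

**RMSSD** is computed only over successive pairs of temporally adjacent
beats: pairs whose beat times are more than 2× the window-median RR apart
are excluded, because a deleted beat otherwise manufactures a large
successive difference and inflates RMSSD exactly when data are worst.

**LF/HF** uses the Lomb–Scargle periodogram of the mean-subtracted
(beat-time, RR) points — the estimator of choice for unevenly sampled
series, avoiding the resampling bias that interpolation+FFT introduces
under exactly the missingness this pipeline studies. Power is integrated
over 0.04–0.15 Hz (LF) and 0.15–0.40 Hz (HF) on a 0.002 Hz grid
(trapezoid); the periodogram is scaled so its integral approximates the
series variance (ms²). Zero HF power flags the window degenerate instead of
dividing by zero. On complete windows the band dominance agrees with an
independent interpolation+FFT cross-check (tested).

**Missing-data sensitivity.** Starting from complete windows, beats are
deleted i.i.d. to each retention level on a grid; the metric is recomputed
and compared with its complete-data value. The reliability criterion is
declared, not inherited: a retention level is *reliable* when ≥ 95 % of
replicate deletions stay within 5 % relative error, and the reported
threshold is the smallest grid level from which reliability holds onward
(monotonized, so a lucky isolated level cannot pass). Under these
conditions LF/HF consistently requires more data than RMSSD — the
frequency-domain metric loses phase coherence with every deleted beat,
while RMSSD simply loses pairs — and the estimated thresholds bracket the
0.88 / 0.99 defaults.

## Speech

Four tests: `AH_REPEATED` (7 short phonations), `AH_SUSTAINED` (one 10-s
phonation), `DOILY` (3 two-syllable words), `BAMBOO` (a read passage,
synthesized as abstract syllable bursts — only envelope, F0 and formant
features are extracted, so intelligible text is unnecessary).

Voiced segments are frames above an adaptive threshold (default 25 dB below
the recording's 95th-percentile frame energy — relative, so features are
amplitude-invariant); gaps under 150 ms merge (keeping the two syllables of
"doily" in one word-segment) and segments under 100 ms drop. Segment counts
against protocol expectations (7, 1, 3) set a protocol-deviation flag
rather than an error.

**F0** is per-frame autocorrelation with parabolic interpolation, searched
in 60–400 Hz. Two classical robustness devices matter on resonant voiced
signals: center clipping (at 40 % of the frame peak) whitens formant
ringing so the pitch peak dominates, and the chosen peak is the
smallest-lag local peak within 90 % of the global maximum, which prevents a
period-multiple (subharmonic octave error) from winning. The summary mean
and SD are taken over voiced frames within 20 % of the median track,
discarding isolated octave-error frames.

**F1/F2** come from LPC root angles. The segment is decimated to ~8 kHz and
lightly pre-emphasized (0.5). The LPC polynomial (order 6 = two poles per
sought formant + two for source tilt) is fit not to the raw waveform
autocorrelation but to the autocorrelation of the *harmonic-suppressed*
spectral envelope: the Hamming-windowed periodogram smoothed with a running
median wider than any expected pitch-harmonic spacing (380 Hz). On strongly
voiced vowels a waveform-domain fit locks poles onto individual pitch
harmonics — at F0 = 300 Hz the first formant can sit mid-way between two
harmonics and be pulled by ~8 % — whereas the median-smoothed envelope is
carried by the aspiration-noise floor and is unbiased; the classical
full-band order rule (~1 pole pair per kHz) is likewise inappropriate for a
band-limited two-formant analysis and is replaced by the band-limited order
above (`lpc_order` remains an argument). Poles with bandwidth ≥ 400 Hz are
discarded; remaining candidates are ranked by LPC-envelope height at the
pole frequency, and the two strongest are reported in ascending order.
Segments without a pitch-range autocorrelation peak ≥ 0.25 are flagged
unvoiced instead of analysed.

**Passage endpoints.** Pauses are inter-segment gaps > 300 ms
(conventional, configurable). Speaking rate divides syllable nuclei by
phonated time; nuclei are local maxima of the 80-ms-smoothed amplitude
envelope separated by a true inter-syllable valley (envelope dipping below
half the smaller neighbouring peak), which ignores within-syllable ripple
without a band-pass whose ringing would fabricate peaks.

## The synthetic cohort generator

The generator is the package's test bed: every sample, beat and burst
carries its ground truth.

* **Days** are bout sequences. Nights are lying; the charging gap
  (02:00–04:00 by default) has no data; daytime (06:00–22:00) interleaves
  active bouts (walking, occasionally stairs; gamma-distributed durations,
  mean ~2.6 min, capped at 15 min) with sedentary filler (sitting/standing,
  some daytime lying; mean ~25 min). The daytime active-minute target is
  `baseline_active_min_per_day` (default 34 min — an ambulant but impaired
  cohort at ~5 % daytime activity) scaled by the disease stage
  `1 − decline_fraction_48wk · week/48` (default decline 0.33, roughly a
  one-third relative reduction by week 48) with ±15 % day-to-day jitter.
* **Adherence and dropout.** Each protocol day is fully worn with
  probability 0.9, otherwise partial (a truncated recording) with
  probability 0.5, otherwise absent. Patients leave the study between
  timepoints with hazard 0.027 per transition, calibrated so that about 18
  of 25 patients remain after 12 transitions; dropped-out patients
  contribute nothing afterwards.
* **Accelerometer bouts** place gravity on the body axis appropriate to the
  posture (longitudinal when upright, anterior–posterior when supine), add
  a periodic gait component for walking (step frequency 1.8–2.2 Hz, with a
  first harmonic and lateral sway) with larger vertical amplitude for
  stairs, smooth 2–4 s orientation ramps for transitions, and white
  per-axis noise (0.01–0.03 g, jittered per patient along with step
  frequency and a few degrees of sensor tilt).
* **RR series** follow the beat-time recursion: each interval is the mean
  RR plus low-frequency (default 0.10 Hz) and high-frequency (default
  0.25 Hz, respiratory) sinusoidal modulation evaluated at the running beat
  time, plus white noise; beats then drop out i.i.d. and optionally in
  contiguous "patch-detachment" gaps, the two failure modes of a chest
  electrode.
* **Speech** is source-filter synthesis: an impulse train at F0 (fractional
  impulse placement — integer rounding would alias high F0 into
  subharmonics), per-cycle jitter, an aspiration-noise floor at 5 % of
  source amplitude (a breathy but realistic phonation that also keeps the
  spectral envelope observable between harmonics), through two resonators
  (130 Hz bandwidth) at F1 and F2.

What the generator does **not** emulate: biomechanically realistic gait
(only its spectral signature), ECG waveforms (beat level only), intelligible
speech, diary-reported context, and any correlation between modalities
within a patient. Passing tests therefore demonstrate that the pipeline
recovers what it claims to measure from data with the study's *structure*
(bouts, gaps, dropout, modulation, resonance) — not that classifier
accuracy or HRV quality would reach the same values on real patients, where
class boundaries blur and artefacts are not white.

## Problem sizes and determinism

Everything is deterministic given seeds: the cohort from `spec$seed`,
classifier training via a fixed xgboost seed on one thread, and every
simulation helper through an optional `seed` argument that restores the
caller's RNG state. The test suite and acceptance script use a 24-patient
reference corpus (~480 labelled epochs) for classifier validation, 3–8
complete 5-min windows × 10–30 replicate deletions per retention level for
the sensitivity analysis, a 15-point F0 × formant-preset grid for speech
recovery, and 100 replicate 20-patient cohorts (bout-level, via the
generator's ground-truth schedules) for progression recovery; these sizes
give stable Monte-Carlo margins for each check while keeping a full run in
minutes on one core.

## Known limitations

* The activity-score formula and feature set are declared replacements for
  device-proprietary definitions, not reconstructions of them; absolute
  "counts" are not comparable across implementations.
* One-vs-rest metrics on a pooled confusion matrix weight patients by their
  epoch counts; a patient-stratified analysis would need per-fold metrics.
* The Lomb–Scargle band powers are reported on a variance-normalized scale;
  they are internally consistent (and the ratio is scale-free) but not
  calibrated to a particular commercial HRV tool.
* Calendar-day wear accounting charges the charging gap as nonwear, not
  missing; a study that counts rolling 24-h days from donning would need a
  different day boundary.
* Formant estimation assumes at most two resonances below ~2.5 kHz, which
  matches the synthesizer and typical F1/F2 analysis but not a full vowel
  inventory with F3 tracking.
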