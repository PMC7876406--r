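---
title: "Methods: spatiotemporal ERP peak scoring and trial variability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal ERP peak scoring and trial variability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Children and adolescents with neurodevelopmental conditions such as the
15q13.3 microdeletion syndrome often cannot be assessed with standard
cognitive instruments, and clinical trials in these populations lack
objective outcome measures. Task-evoked EEG offers one: event-related
potentials (ERPs) recorded during an auditory oddball (AOB) task and an
auditory Go/NoGo (GNG) task index sensory processing (N100, P200),
inhibitory control (N2) and attention-driven orienting (P3a). `stepnet`
implements an automated assessment of these components built on three
score families:

1. **Normative percentile scores of spatiotemporal ERP peaks (STEPs).**
   A subject's band-filtered, scalp-interpolated condition-average ERP is
   segmented into local space-time extrema; each extremum is matched to a
   template peak derived from a healthy reference cohort, and its
   amplitude and latency are converted to percentiles of the reference
   distribution.
2. **ERP variability (ERPv).** The mean trial-by-trial standard error of
   the post-stimulus amplitude over all channels and time points, one
   scalar per task condition; its complement (1 − ERPv, on the normalized
   scale) is a neural-consistency score.
3. **Behavioral performance.** Percent correct and reaction-time mean/SD
   with a single-pass 2.5 SD outlier rule and a 65%-correct validity
   floor.

The clinical recordings behind this design are private, so the package
ships a synthetic cohort generator that reproduces the statistical
structure those analyses assume, and every stage is exercised end-to-end
on simulated data.

## Pipeline and model assumptions

### Synthetic task EEG

Each evoked component is a separable source: a Gaussian bump in time
(latency mean per subject, trial-to-trial latency jitter) times an
isotropic Gaussian patch on the 2-D projected scalp. An epoch is the sum
of the components evoked by its condition, plus channel-independent white
noise and optional stereotyped blink transients (a ~300 ms biphasic wave
radiating from a virtual ocular site above the anterior scalp edge).
Smooth unimodal bumps are exactly the morphology STEP extraction assumes;
the white-noise default is the simplest model that exercises averaging and
ERPv (a 1/f-shaped option was considered and rejected as adding nothing to
the contracts being tested). Sampling is 250 Hz on a 64-channel unit-disc
montage; AOB epochs span −200..1200 ms, GNG epochs −200..800 ms.

Key generator defaults and why:

* **Component kernels.** Temporal width 40 ms by default; the early
  components are sharpened (N100 25 ms, P200 25–30 ms) and the slow P3a
  broadened (50–60 ms) so each component's spectral energy sits in the
  band it is scored in (theta/alpha for the early components, delta for
  P3a). A 40 ms Gaussian has essentially no energy above ~8 Hz, so
  without this an "alpha-band P200" would vanish in filtering.
* **Between-subject variability.** Latency SDs of 10–25 ms and amplitude
  coefficients of variation of ~20% give reference distributions wide
  enough for meaningful percentiles — values in the range reported for
  adolescent auditory ERPs.
* **Trial-to-trial variability.** Latency jitter 20 ms, additive
  amplitude jitter 2 µV, background noise 5 µV (per-subject lognormal
  spread of 15%).
* **Patient group effect.** A delayed (+50 ms), attenuated (×0.7), more
  variable (×1.5 trial jitter) P3a; a global ×1.5 on trial-to-trial
  jitter and ×1.3 on background noise (the "neural noise" signature of
  inconsistent responses that the ERPv score targets); and slower, more
  variable, less accurate behavior parameterized directly from the
  published group summary statistics (reaction-time means/SDs and percent
  correct for Target, Go and NoGo).
* **Behavior.** Response-required trials are correct with probability
  1 − error rate and carry a positive-truncated-normal RT; NoGo trials
  show a commission (with an RT) at the error rate. The AOB inter-stimulus
  interval is fixed at 1.5 s; GNG ISIs are uniform in 1000–2000 ms. The
  task protocol also mentions a small separate ISI jitter whose relation
  to the uniform range is ambiguous; the configuration carries the field
  but only the uniform range is realized.
* **Two visits** re-simulate trials with a visit-specific sub-seed while
  keeping the subject-level parameters fixed, so test–retest reliability
  is positive by construction. One master seed drives everything through a
  documented counter scheme (`derive_seed`), allowing any subject × visit
  cell to be regenerated in isolation.

What the generator does **not** emulate: volume-conducted background EEG
(channels share only the evoked signal and blinks, not ongoing rhythms),
1/f spectra, muscle or line-noise artifacts, age/sex effects on the
signals (demographics are metadata only), and any head-model forward
physics. Passing tests therefore demonstrate that the pipeline recovers
what it assumes — smooth, unimodal, band-limited evoked sources in
additive noise — not that it is robust to every failure mode of real
recordings.

### Cleaning

Bad electrodes are channels with more than 5% of samples out of ±100 µV
("extensive" is unquantified in the underlying protocol; 5% is our
choice), or whose across-epoch average correlates below 0.25 with the mean
of their 4 nearest neighbors. The correlation is judged on the evoked
average, not raw samples, because with channel-independent background
noise raw-sample correlations are near zero for every channel; the evoked
average isolates the signal neighbors actually share. Flagged channels
are interpolated by inverse-distance weighting of good neighbors.

Blink removal decomposes the concatenated epochs with a compact symmetric
FastICA (tanh contrast, 10 components); components whose time course
correlates above 0.6 in absolute value with a frontal ocular proxy (mean
of the two most anterior channels — no dedicated EOG channel is
simulated) are subtracted, at most two. Only the identified components'
contribution is removed, so variance outside the estimated subspace is
untouched, and a decomposition that produces non-finite estimates passes
the data through with a warning. Noise-dominated components rotate
indefinitely without satisfying a formal convergence criterion; that is
expected and harmless, since the high-variance blink component stabilizes
within a few iterations.

Epoch rejection removes an epoch iff any sample exceeds ±100 µV or
deviates more than 7 per-channel SDs from the per-channel mean, with
statistics per channel per condition and the epoch judged on its worst
channel. The stage order is electrodes → blink ICA → rejection: the
protocol we follow does not state the order, and this one lets the ICA
see all epochs while rejection statistics are computed on blink-corrected
data.

### STEP extraction and scoring

The cleaned condition average is band-filtered (delta 0.5–4 Hz, theta
3–8 Hz, alpha 7–13 Hz) with a linear-phase FIR designed by discrete
least-squares over a dense frequency grid and applied forward and in
reverse, giving zero net phase — planted peak times move by at most one
sample. The default order is 80 taps (signals must be at least 3× the
order long, which both epoch lengths satisfy). At this order the
combined forward-reverse gain is within 5% of unity in the alpha and
delta passbands and a 20 Hz tone is attenuated far beyond 20 dB in
delta; the narrow theta band carries up to ~20% passband ripple near its
edges — an accepted resolution limit at epoch-compatible orders, and
immaterial for percentile scores, which are rank-based within a band.
A lower band edge of 0.5 Hz is not realizable at this order, so the delta
filter degenerates to a 4 Hz lowpass and DC is removed by baseline
correction instead.

Each time slice is interpolated onto a 32 × 32 grid over the unit disc
("high resolution" is unquantified; 32 × 32 makes the grid cell finer
than the inter-electrode spacing) with an exact thin-plate spline, chosen
precisely because its interpolating property gives testable contracts
(grid nodes at electrode positions equal the electrode values). A STEP is
a strict local extremum of the grid in its 3 × 3 × 3 space-time
neighborhood, post-stimulus, with |amplitude| ≥ 1 µV (suppressing noise
extrema; configurable), together with its same-sign 26-connected
half-amplitude surround. Extraction is property-tested against an
exhaustive brute-force scan.

Cross-subject clustering pools STEPs per band × condition and polarity
under a capped metric (Δt ≤ 100 ms, scalp distance ≤ 0.25 disc radii,
either cap = distance 1) with **average-linkage** agglomeration cut at
height 1. Average linkage is a deliberate choice: complete linkage splits
a single component population whose between-subject latency spread
approaches the cap (as the P3a's does), producing two sub-threshold
clusters where one true template exists. A cluster must contain STEPs
from ≥ 70% of subjects to become a template ("main STEP"); one STEP per
subject (nearest to the centroid) contributes.

Matching a subject's STEPs to templates requires equal polarity, |Δt| and
scalp distance within windows of 2× the cluster dispersion **floored at
the clustering caps (100 ms, 0.25 radii)**; candidates compete by the
dispersion-normalized distance, greedily, each STEP used once. The floor
is deliberately the clustering cap rather than something tighter: the
within-template spread is bounded by the caps, localization accuracy is
bounded below by the sensor spacing (~0.2 disc radii at 32–64 channels),
and clinically meaningful latency delays of 50–80 ms must remain
matchable — a 50 ms window would silently exclude the very patients the
score is meant to flag. Unmatched templates are excluded from group
statistics (no imputation) with match rates reported.

Percentiles use the mid-rank formula
`100·(#{ref < v} + 0.5·#{ref = v})/n`. Amplitude is the signed peak value
(no rectification): the published effect sizes for amplitude scores are
negative, implying signed treatment. Scoring reference members against
their own reference yields percentiles uniform on [0, 100] by
construction; this calibration is asserted by a Kolmogorov–Smirnov test.
Extraction is per band, then band-labelled — the reporting convention
with a frequency-band column per score implies per-band extraction, which
we adopt.

### ERPv

`SE(c,t) = SD_trials(c,t)/√n` (n−1 denominator) on broadband cleaned
epochs — the variability analysis sits outside the band-filtered flow —
averaged over all post-stimulus time points and channels. Valid trials
are correct responses surviving artifact rejection; for conditions
without responses (Frequent, Novel) validity is artifact-free only, and
for NoGo it additionally requires a correct inhibition. The units of the
published 0–1-range scores are not stated, so alongside the raw µV score
we report a normalized score (raw divided by the RMS of the
condition-average post-stimulus ERP), which lands on that scale;
all directional and discriminative claims are checked on our own scores,
never against the published magnitudes.

### Statistics

The mixed ANOVA is a classical split-plot (group between, visit within;
between-group F against the subject-within-group stratum), with Cohen's d
on subject means as effect size. Levene's test uses absolute deviations
from group means; Welch's t is computed from group summaries with
Welch–Satterthwaite df. ROC analysis uses the rank (Mann–Whitney)
formulation with mid-rank tie handling, patients as positives,
orientation flipped so AUC ≥ 0.5, operating point by Youden's J, and the
subject × visit score as the observation unit (the convention is recorded
in output metadata; the source reporting is silent on it). The ICC is
fixed to two-way mixed, absolute agreement, single measurement — no model
is named in the source, and this is the standard choice for test–retest
designs. No multiple-testing adjustment is applied by default (per-score
p-values are reported unadjusted, matching the reporting style this
mirrors); a Benjamini–Hochberg helper exists for users who want it.

One printed Welch statistic in the source tables (Target percent correct,
t = −3.43) cannot be reproduced from the printed summary statistics under
any plausible observation unit, while the Go percent-correct t (−6.12)
can (≈ −6.13 at 60/18 subject × visit units); printed t values are
therefore never used as checks.

## Problem sizes of the simulation studies

The statistical studies keep the clinical design — 30 controls + 9
patients, two visits, 250 Hz, full epoch windows, a 120-member reference —
and thin everything that only costs precision:

* 32-channel montage and 24 × 24 grid (same geometry family as the full
  64/32² defaults; the pipeline is agnostic to density, and unit tests
  exercise the full geometry);
* per-condition trials: Novel 60 (the clinical count), Frequent 50,
  Target 25, Go 40, NoGo 30 — ERPv precision is driven by the
  channels × time average, not the trial count;
* blink-free recordings in the replicate studies (the ICA stage is
  validated separately against held ground truth).

With these sizes the 120-member reference builds in ~0.3 s per member and
the 20-replicate recovery study (78 subject × visit simulations per
replicate, each through epoch rejection, filtering, gridding, STEP
extraction, matching, percentile scoring and five ERPv scores) completes
in minutes on one CPU. The null calibration of the statistical layer uses
500 score-level simulations (scores drawn directly under exchangeability
with visit correlation 0.6), because the null behavior of the ANOVA/ROC
layer does not depend on how the scores were produced.

The "ERPv AUC ≥ 0.75 on every condition" recovery check is evaluated as
the mean AUC over the 20 replicates per condition: a single 9-vs-30 AUC
has a sampling SD of ~0.1, so a per-replicate bound would test noise, not
separability.

## Numerical choices, degeneracies, tie-breaks

* Strict extrema: plateau points are never peaks; grid nodes outside the
  head mask and the first/last time samples are never peaks; spatial-edge
  nodes are judged against their available neighbors.
* Half-open time convention `[start, end)`; epoch sample 0 sits at
  −200 ms; post-stimulus means t ≥ 0.
* The 2.5 SD reaction-time outlier rule is single-pass (no re-iteration),
  computed per subject × visit × condition; SD = 0 excludes nothing.
  Sample SDs use n − 1 throughout.
* Percentile ties use mid-ranks; matching ties resolve by ascending
  normalized distance; cluster dispersions are floored (10 ms, 0.05
  radii) before use as matching scales.
* Zero-variance guards: an all-identical score table returns F = 0, p = 1;
  zero total variance is an error for the ICC; a zero-RMS average is an
  error for normalized ERPv.
* EDF interchange quantizes to 16 bits per channel over the per-channel
  range; intermediate stages stay in memory at double precision, so
  quantization affects only the on-disk round trip.

## Known limitations

* The synthetic generator's noise is white and channel-independent;
  neighbor-dissimilarity electrode detection is therefore calibrated on
  evoked averages and its raw-sample behavior on real EEG is untested
  here.
* The theta-band filter ripple noted above.
* The proprietary matcher this design mirrors is undisclosed; our
  similarity metric and windows are declared and configurable, but they
  are a reconstruction, not a replication.
* Connectivity-style analyses between STEP pairs are out of scope: only
  per-peak amplitude/latency scores and ERPv are produced.
* With 9 patients, per-replicate ROC operating points (sensitivity /
  specificity) are coarse (steps of 1/9 or 1/18); they are reported but
  never asserted against.
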