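# stepnet

Spatiotemporal ERP peak scoring and trial-to-trial variability analysis
for task-evoked EEG.

## What problem this solves

Objective outcome measures of cognitive function are scarce for
neurodevelopmental conditions — the motivating case is the 15q13.3
microdeletion syndrome, where standard instruments are hard to administer
and clinical trials suffer large placebo effects. Event-related
potentials (ERPs) recorded during an auditory oddball (AOB) and an
auditory Go/NoGo (GNG) task probe the relevant processes directly: N100
and P200 index sensory processing and filtering, N2 inhibitory control,
and P3a attention-driven orienting. `stepnet` turns epoched task EEG into
a compact battery of subject-level scores and the group statistics needed
to ask whether patients and controls differ and whether the scores are
reliable:

* **Normative percentile scores of spatiotemporal ERP peaks (STEPs).**
  For each frequency band (delta 0.5–4, theta 3–8, alpha 7–13 Hz) and
  condition, the condition-average ERP is zero-phase FIR-filtered,
  interpolated onto a scalp grid by an exact thin-plate spline, and
  segmented into STEPs — strict local space-time extrema with their
  half-amplitude surrounds. STEPs shared by ≥ 70% of a reference cohort
  are clustered into template peaks ("main STEPs"); a subject's matched
  peak amplitude `a` and latency `t` become percentiles of the reference
  distribution, `100·(#{ref < v} + ½·#{ref = v})/n`.
* **ERP variability.** `ERPv = mean over channels and post-stimulus time
  of SD_trials/√n` — the trial-by-trial standard error of the amplitude;
  `1 − ERPv` (normalized) is a neural-consistency score. High ERPv means
  an inconsistent neural response to identical stimuli.
* **Behavioral performance.** Percent correct and RT mean/SD per
  condition with a single-pass 2.5 SD outlier rule and a 65 %-correct
  recording-validity floor.
* **Group statistics.** Mixed group × visit ANOVA (split-plot), Levene
  and Welch tests, rank-based ROC (AUC, Youden sensitivity/specificity),
  two-way mixed absolute-agreement ICC, and Cohen's d.

Because the clinical recordings that motivated this design are private,
the package includes a synthetic cohort generator (64-channel 250 Hz
recordings, planted N100/P200/N2/P3a components, trial jitter, blinks,
reaction times and error rates with group-level differences), so the
whole pipeline is testable end-to-end.

## Worked example

The numbered scripts under `analysis/` run a small demonstration study
end-to-end — simulate a 12-subject two-visit cohort to EDF + TSV, clean
it (bad electrodes, blink ICA, epoch rejection), build a simulated
normative reference, score everyone, compute ERPv and behavior, and run
the group statistics:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_reference_and_scores.R
Rscript analysis/04_erpv_and_behavior.R
Rscript analysis/05_group_statistics.R
```

Step 3 prints the per-group mean percentile scores (8 controls vs 4
patients, two visits each, scored against a 60-member simulated
reference):

```
    group        main_step attribute percentile
3 healthy Novel-delta-P298 amplitude   43.02083
4 patient Novel-delta-P298 amplitude    1.87500
7 healthy Novel-delta-P298   latency   46.25000
8 patient Novel-delta-P298   latency   97.70833
```

Controls sit near the 50th percentile by construction; the simulated
patients' P3a is attenuated (2nd percentile amplitude) and delayed (98th
percentile latency). Step 5 turns the score tables into one row per
score (F/df/p from the mixed ANOVA, Levene p, Welch t where variances
differ, AUC/specificity/sensitivity, test–retest ICC, effect size),
e.g.:

```
                score        F df1 df2      p levene_p welch_t    auc    icc effect_size
Novel-delta-P298 latency 10.4425   1  10 0.0090   0.0006 -6.6365 0.9805 0.9815      1.9789
           ERPv Novel    14.3658   1  10 0.0035   0.5365      NA 0.9688 0.9587      2.3210
```

and renders the multi-parameter radar plot
(`results/figures/multi_parameter_scores.pdf`) comparing the two groups'
percentile profiles.

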