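#!/usr/bin/env Rscript
# Step 1: simulate a demonstration cohort and write it to disk in the
# interchange formats (EDF + events/behavior TSVs + manifest JSON).
#
# The demo cohort is deliberately small (8 controls + 4 patients, two
# visits, thinned trial counts, 32 channels) so the full workflow runs in
# about a minute; the acceptance script runs the statistically sized
# studies.

suppressPackageStartupMessages(library(stepnet))

seed <- 20260924L
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

specs <- list(
  task_spec("AOB", n_trials = 120,
            condition_probs = c(Frequent = 60 / 120, Target = 20 / 120,
                                Novel = 40 / 120)),
  task_spec("GNG", n_trials = 60,
            condition_probs = c(Go = 40 / 60, NoGo = 20 / 60))
)
montage <- make_montage(32)
cfg <- cohort_config(n_healthy = 8, n_patient = 4, visits = 2,
                     seed = seed, tasks = specs, blink_rate = 2)

manifest <- list(seed = seed, n_healthy = 8, n_patient = 4, visits = 2,
                 fs = 250, n_channels = 32, files = list())

# stream subject x visit x task straight to disk (same seed-derivation
# scheme as generate_cohort, so the cohort is reproducible piecewise)
groups <- c(rep("healthy", cfg$n_healthy), rep("patient", cfg$n_patient))
ids <- sprintf("S%03d", seq_along(groups))
for (si in seq_along(ids)) {
  for (v in seq_len(cfg$visits)) {
    for (ti in seq_along(specs)) {
      spec <- specs[[ti]]
      params <- draw_subject_params(groups[si], spec$name, cfg$group_effect,
                                    seed = derive_seed(seed, si, 0L, ti),
                                    blink_rate = cfg$blink_rate)
      sq <- generate_task_sequence(spec, derive_seed(seed, si, v, ti, 1L))
      eeg <- simulate_subject_eeg(sq, params, montage,
                                  derive_seed(seed, si, v, ti, 2L),
                                  window = spec$epoch_window, task = spec$name)
      beh <- simulate_behavior(sq, spec, params, derive_seed(seed, si, v, ti, 3L))
      stem <- sprintf("%s_visit%d_%s", ids[si], v, spec$name)
      write_recording(eeg, sq, beh, out_dir, stem)
      manifest$files[[stem]] <- list(subject = ids[si], group = groups[si],
                                     visit = v, task = spec$name)
      message("wrote ", stem)
    }
  }
}

jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("cohort manifest: ", file.path(out_dir, "manifest.json"))
message(sprintf("done: %d recordings under %s",
                length(manifest$files), out_dir))
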