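#!/usr/bin/env Rscript
# Step 2: artifact rejection over the simulated cohort written by step 1.
# Re-cuts epochs from the EDFs, runs bad-electrode detection +
# interpolation, blink-component ICA and noisy-epoch rejection, and writes
# a per-recording cleaning report.

suppressPackageStartupMessages(library(stepnet))

in_dir <- "results/cohort"
manifest <- jsonlite::read_json(file.path(in_dir, "manifest.json"))
montage <- make_montage(manifest$n_channels)
cfg <- cleaning_config()

windows <- list(AOB = c(-200, 1200), GNG = c(-200, 800))
reports <- list()
for (stem in names(manifest$files)) {
  info <- manifest$files[[stem]]
  ep <- load_epochs(file.path(in_dir, paste0(stem, ".edf")),
                    file.path(in_dir, paste0(stem, "_events.tsv")),
                    windows[[info$task]], montage)
  res <- clean_epochs(ep, cfg)
  reports[[stem]] <- list(
    subject = info$subject, visit = info$visit, task = info$task,
    bad_channels = as.list(res$report$bad_channels),
    n_rejected_epochs = length(res$report$rejected_epochs),
    removed_components = res$report$removed_components,
    fraction_retained = res$report$fraction_retained
  )
  message(sprintf("%s: %d bad channel(s), %d epoch(s) rejected, %d blink component(s), %.0f%% retained",
                  stem, length(res$report$bad_channels),
                  length(res$report$rejected_epochs),
                  res$report$removed_components,
                  100 * res$report$fraction_retained))
}

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(reports, "results/cleaning_report.json",
                     auto_unbox = TRUE, pretty = TRUE)
frac <- vapply(reports, function(r) r$fraction_retained, 0)
message(sprintf("cleaning report for %d recordings; retention %.0f%%..%.0f%%",
                length(reports), 100 * min(frac), 100 * max(frac)))
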