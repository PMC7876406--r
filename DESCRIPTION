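Package: stepnet
Title: Spatiotemporal ERP Peak Scoring and Trial-to-Trial Variability
    Analysis for Task EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-related potential (ERP) assessment pipeline for
    task-evoked EEG in small clinical cohorts. Extracts spatiotemporal ERP
    peaks (STEPs) from band-filtered, grid-interpolated condition averages,
    clusters them across a normative reference cohort into group-common
    template peaks, and converts single-subject peak amplitude and latency
    into normative percentile scores. Also computes a trial-to-trial ERP
    variability (ERPv) score, behavioral performance summaries for auditory
    oddball and Go/NoGo paradigms, and the group-comparison statistics used
    to assess discriminability and test-retest reliability (mixed ANOVA,
    Levene and Welch tests, ROC/AUC, intraclass correlation). Includes a
    synthetic task-EEG cohort generator, artifact-rejection and blink-ICA
    preprocessing, and EDF/TSV interchange so the full workflow runs
    end-to-end without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    car,
    yaml,
    jsonlite,
    rlang
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
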