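#' Default study configuration
#'
#' One nested list housing every analysis constant: the two task
#' specifications, the cleaning limits (+/-100 microvolts, 7 SD, 65%
#' correct), the band edges, grid resolution, clustering/matching windows
#' (70% prevalence, 100 ms / 0.25 radii caps), the reference-group size
#' (120) and the statistics options. Serializable to YAML with round-trip
#' identity.
#'
#' @param seed Master seed stored in the configuration.
#' @return A `study_config` list.
#' @export
default_study_config <- function(seed = 1) {
  structure(list(
    fs = 250,
    n_channels = 64,
    tasks = list(
      AOB = list(n_trials = 600,
                 condition_probs = list(Frequent = 0.8, Target = 0.1, Novel = 0.1),
                 tone_freqs = list(Frequent = 2000, Target = 1000, Novel = NA),
                 isi = 1500, epoch_window = c(-200, 1200), min_correct = 0.65),
      GNG = list(n_trials = 300,
                 condition_probs = list(Go = 0.8, NoGo = 0.2),
                 tone_freqs = list(Go = 2000, NoGo = 1000),
                 isi = c(1000, 2000), epoch_window = c(-200, 800),
                 min_correct = 0.65)
    ),
    cleaning = list(amp_limit = 100, epoch_sd_limit = 7,
                    neighbor_sim_threshold = 0.25, bad_sample_fraction = 0.05,
                    max_blink_components = 2, blink_cor_cutoff = 0.6),
    bands = list(delta = c(0.5, 4), theta = c(3, 8), alpha = c(7, 13)),
    grid_resolution = c(32, 32),
    clustering = list(prevalence_min = 0.7, max_dt_ms = 100, max_ds = 0.25),
    matching = list(window_floor_ms = 100, window_floor_ds = 0.25),
    reference_size = 120,
    min_abs_amplitude = 1,
    filter_order = 80,
    rt_outlier_sd = 2.5,
    stats = list(alpha = 0.05, multiple_testing = "none"),
    seed = seed
  ), class = "study_config")
}

#' Write a study configuration to YAML
#' @param config A `study_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a study configuration from YAML
#' @param path YAML path.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  structure(yaml::read_yaml(path), class = "study_config")
}

#' Load the packaged patient demographics table
#'
#' The demographic table of the ten-patient 15q13.3 microdeletion cohort
#' (sex, age in years and months, autism diagnosis, IQ, seizure history)
#' shipped as a plain TSV.
#'
#' @return data.frame with columns `subject_id`, `sex`, `age_years`,
#'   `age_months`, `deletion`, `autism`, `iq`, `seizure_history`.
#' @export
load_demographics <- function() {
  path <- system.file("extdata", "patient_demographics.tsv",
                      package = "stepnet", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Export tidy score tables with a metadata sidecar
#'
#' Writes each table as a TSV with a deterministic column order and an
#' accompanying JSON sidecar recording the seed, configuration and package
#' version, so two runs with identical seed and configuration produce
#' byte-identical files.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param meta Named list of run metadata (seed, config, ...).
#' @return Character vector of the files written.
#' @export
export_scores <- function(tables, out_dir, meta = list()) {
  stopifnot(length(tables) > 0, !is.null(names(tables)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    tb <- tb[, sort(names(tb)), drop = FALSE]    # deterministic column order
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tb, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  meta$package_version <- as.character(utils::packageVersion("stepnet"))
  meta$config_hash <- rlang::hash(meta$config)
  side <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  c(files, side)
}

#' Re-load exported score tables
#' @param out_dir Directory written by [export_scores()].
#' @return Named list of data.frames.
#' @export
load_scores <- function(out_dir) {
  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, utils::read.delim, sep = "\t",
                stringsAsFactors = FALSE)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}
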