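#' Match single-subject STEPs to group template peaks
#'
#' A candidate STEP matches a template (main STEP) iff it has the same
#' polarity, its time lies within the template's time window and its scalp
#' distance within the spatial window. Among candidates the minimal
#' normalized distance `sqrt((dt/sd_t)^2 + (ds/sd_s)^2)` wins, using the
#' cluster dispersions (floored) as scales. Matching is greedy by ascending
#' distance and each subject STEP is used at most once.
#'
#' @param subject_steps STEP data.frame from [extract_steps()].
#' @param main_steps Template data.frame from [cluster_steps()].
#' @param window_dt_ms,window_ds Matching windows; `NULL` (default) uses
#'   `max(2 x dispersion, floor)` per template with floors (100 ms, 0.25 -- the clustering caps).
#' @return data.frame, one row per template: `label`, `matched`,
#'   `amplitude`, `time_ms`, `x`, `y`, `distance`.
#' @export
match_steps <- function(subject_steps, main_steps,
                        window_dt_ms = NULL, window_ds = NULL) {
  n_main <- nrow(main_steps)
  res <- data.frame(
    label = main_steps$label, matched = FALSE,
    amplitude = NA_real_, time_ms = NA_real_,
    x = NA_real_, y = NA_real_, distance = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!n_main || !nrow(subject_steps)) return(res)
  wt <- if (is.null(window_dt_ms)) pmax(2 * main_steps$time_dispersion, 100) else rep(window_dt_ms, n_main)
  ws <- if (is.null(window_ds)) pmax(2 * main_steps$spatial_dispersion, 0.25) else rep(window_ds, n_main)
  stopifnot(all(wt > 0), all(ws > 0))
  cand <- NULL
  for (m in seq_len(n_main)) {
    dt <- subject_steps$time_ms - main_steps$centroid_time[m]
    ds <- sqrt((subject_steps$x - main_steps$centroid_x[m])^2 +
                 (subject_steps$y - main_steps$centroid_y[m])^2)
    ok <- subject_steps$polarity == main_steps$polarity[m] &
      abs(dt) <= wt[m] & ds <= ws[m]
    if (!any(ok)) next
    dist <- sqrt((dt / main_steps$time_dispersion[m])^2 +
                   (ds / main_steps$spatial_dispersion[m])^2)
    cand <- rbind(cand, data.frame(main = m, step = which(ok),
                                   distance = dist[ok]))
  }
  if (is.null(cand)) return(res)
  cand <- cand[order(cand$distance), , drop = FALSE]
  used_step <- logical(nrow(subject_steps))
  used_main <- logical(n_main)
  for (i in seq_len(nrow(cand))) {
    m <- cand$main[i]; s <- cand$step[i]
    if (used_main[m] || used_step[s]) next
    used_main[m] <- TRUE
    used_step[s] <- TRUE
    res$matched[m] <- TRUE
    res$amplitude[m] <- subject_steps$amplitude[s]
    res$time_ms[m] <- subject_steps$time_ms[s]
    res$x[m] <- subject_steps$x[s]
    res$y[m] <- subject_steps$y[s]
    res$distance[m] <- cand$distance[i]
  }
  res
}

#' Build a reference group from a cohort of STEP sets
#'
#' Matches every reference subject's STEPs to the main STEPs and stores the
#' matched attribute values (signed amplitude in microvolts, latency in ms)
#' sorted ascending, per template. Templates matched by fewer than half the
#' reference members are dropped with a warning.
#'
#' @param cohort_steps Named list (subject -> STEP data.frame).
#' @param main_steps Template data.frame from [cluster_steps()].
#' @param min_match_fraction Drop threshold (default 0.5).
#' @return A `reference_group` object: list with `main_steps`, `values`
#'   (per label: list(amplitude = sorted numeric, latency = sorted
#'   numeric)), `match_rate`, `n_members`.
#' @export
build_reference_group <- function(cohort_steps, main_steps,
                                  min_match_fraction = 0.5) {
  stopifnot(nrow(main_steps) >= 1)
  n <- length(cohort_steps)
  vals <- lapply(seq_len(nrow(main_steps)), function(i)
    list(amplitude = numeric(0), latency = numeric(0)))
  names(vals) <- main_steps$label
  for (st in cohort_steps) {
    mm <- match_steps(st, main_steps)
    for (m in which(mm$matched)) {
      lab <- mm$label[m]
      vals[[lab]]$amplitude <- c(vals[[lab]]$amplitude, mm$amplitude[m])
      vals[[lab]]$latency <- c(vals[[lab]]$latency, mm$time_ms[m])
    }
  }
  match_rate <- vapply(vals, function(v) length(v$amplitude) / n, 0)
  drop <- match_rate < min_match_fraction
  if (any(drop)) {
    warning(sprintf("dropping %d template(s) matched by < %d%% of members: %s",
                    sum(drop), round(100 * min_match_fraction),
                    paste(names(vals)[drop], collapse = ", ")))
    vals <- vals[!drop]
    main_steps <- main_steps[!drop, , drop = FALSE]
    match_rate <- match_rate[!drop]
  }
  vals <- lapply(vals, function(v)
    list(amplitude = sort(v$amplitude), latency = sort(v$latency)))
  structure(
    list(main_steps = main_steps, values = vals,
         match_rate = match_rate, n_members = n),
    class = "reference_group"
  )
}

#' @export
print.reference_group <- function(x, ...) {
  cat(sprintf("<reference_group> %d members, %d template peak(s)\n",
              x$n_members, nrow(x$main_steps)))
  for (lab in names(x$values))
    cat(sprintf("  %s: %d stored values, match rate %.2f\n",
                lab, length(x$values[[lab]]$amplitude), x$match_rate[lab]))
  invisible(x)
}

#' Percentile of a value within a sorted reference list
#'
#' `100 * (count(ref < value) + 0.5 * count(ref == value)) / n` -- the
#' mid-rank percentile, monotone non-decreasing in the value.
#'
#' @param value Numeric scalar (or vector).
#' @param reference Numeric vector of reference values.
#' @return Percentile(s) in 0..100.
#' @export
percentile_score <- function(value, reference) {
  if (!length(reference)) stop("empty reference", call. = FALSE)
  vapply(value, function(v) {
    100 * (sum(reference < v) + 0.5 * sum(reference == v)) / length(reference)
  }, 0)
}

#' Extract STEPs from cleaned epochs for every band x condition
#'
#' The single-subject feature-extraction path shared by reference building
#' and scoring: for each registry entry, average the condition's epochs,
#' band-filter the average (zero-phase), interpolate onto the scalp grid
#' and extract STEPs.
#'
#' @param epochs Cleaned [eeg_epochs()].
#' @param registry data.frame with columns `condition` and `band` naming
#'   the band x condition combinations to process.
#' @param bands Band registry, e.g. [default_bands()].
#' @param resolution Grid resolution.
#' @param min_abs_amplitude Minimum absolute STEP amplitude.
#' @param filter_order FIR order passed to [bandpass_filter()].
#' @return Named list `"condition|band"` -> STEP data.frame.
#' @export
subject_steps <- function(epochs, registry, bands = default_bands(),
                          resolution = c(32, 32), min_abs_amplitude = 1,
                          filter_order = 80) {
  out <- list()
  for (i in seq_len(nrow(registry))) {
    cond <- registry$condition[i]
    bname <- registry$band[i]
    if (!cond %in% epochs$condition) next
    erp <- compute_condition_erp(epochs, cond)
    filt <- bandpass_filter(erp, bands[[bname]], epochs$fs, order = filter_order)
    grid <- interpolate_grid(filt, epochs$montage, epochs$times,
                             resolution = resolution,
                             band = bname, condition = cond)
    out[[paste(cond, bname, sep = "|")]] <-
      extract_steps(grid, min_abs_amplitude, compute_surround = FALSE)
  }
  out
}

#' Score one subject against a reference group
#'
#' Applies the identical feature-extraction path used for the reference
#' members, matches the resulting STEPs to the reference templates, and
#' converts matched amplitude and latency to percentile scores by ranking
#' within the stored reference distributions. Unmatched templates yield
#' `matched = FALSE` and no percentile.
#'
#' @param epochs Cleaned [eeg_epochs()] for one subject.
#' @param reference A `reference_group`.
#' @param bands,resolution,min_abs_amplitude,filter_order As in
#'   [subject_steps()].
#' @return data.frame: `main_step`, `condition`, `band`, `attribute`,
#'   `raw`, `percentile`, `matched`.
#' @export
score_subject <- function(epochs, reference, bands = default_bands(),
                          resolution = c(32, 32), min_abs_amplitude = 1,
                          filter_order = 80) {
  ms <- reference$main_steps
  if (!nrow(ms)) {
    return(data.frame(main_step = character(0), condition = character(0),
                      band = character(0), attribute = character(0),
                      raw = numeric(0), percentile = numeric(0),
                      matched = logical(0), stringsAsFactors = FALSE))
  }
  registry <- unique(ms[, c("condition", "band")])
  st <- subject_steps(epochs, registry, bands, resolution,
                      min_abs_amplitude, filter_order)
  out <- NULL
  for (key in names(st)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sel <- ms$condition == parts[1] & ms$band == parts[2]
    if (!any(sel)) next
    mm <- match_steps(st[[key]], ms[sel, , drop = FALSE])
    for (m in seq_len(nrow(mm))) {
      lab <- mm$label[m]
      for (attribute in c("amplitude", "latency")) {
        raw <- if (!mm$matched[m]) NA_real_
               else if (attribute == "amplitude") mm$amplitude[m] else mm$time_ms[m]
        pct <- if (!mm$matched[m]) NA_real_ else
          percentile_score(raw, reference$values[[lab]][[attribute]])
        out <- rbind(out, data.frame(
          main_step = lab, condition = parts[1], band = parts[2],
          attribute = attribute, raw = raw, percentile = pct,
          matched = mm$matched[m], stringsAsFactors = FALSE
        ))
      }
    }
  }
  rownames(out) <- NULL
  out
}
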