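#' Cohort configuration
#'
#' Describes a simulated two-group, two-visit study: 30 healthy controls and
#' 9 patients by default, each recorded on two visits with the same
#' subject-level parameters (so test-retest reliability is positive) but
#' visit-specific noise realizations.
#'
#' @param n_healthy,n_patient Group sizes (> 0).
#' @param visits Number of visits per subject.
#' @param group_effect A [default_group_effect()]-style list (or
#'   [null_group_effect()]).
#' @param seed Master integer seed.
#' @param tasks List of [task_spec()] objects to administer.
#' @param noise_sd_mean Population mean additive-noise SD (microvolts).
#' @param blink_rate Blinks per minute (0 disables blinks).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_healthy = 30, n_patient = 9, visits = 2,
                          group_effect = default_group_effect(), seed = 1,
                          tasks = list(task_spec("AOB"), task_spec("GNG")),
                          noise_sd_mean = 5, blink_rate = 2) {
  stopifnot(n_healthy > 0, n_patient > 0, visits >= 1)
  structure(
    list(n_healthy = n_healthy, n_patient = n_patient, visits = visits,
         group_effect = group_effect, seed = seed, tasks = tasks,
         noise_sd_mean = noise_sd_mean, blink_rate = blink_rate),
    class = "cohort_config"
  )
}

#' Generate a simulated study cohort
#'
#' Simulates every subject x visit x task: stimulus sequence, epoched EEG
#' and behavioral record. Subject-level parameters (component latencies and
#' amplitudes, noise level, RT model) are drawn once per subject per task
#' and reused across visits; each visit re-simulates trials under a
#' visit-specific sub-seed. Patients receive the configured group effect.
#'
#' To keep large cohorts within memory, pass `process`: it is called as
#' `process(subject_id, group, visit, task_name, eeg, behavior, params)`
#' for every cell and only its return value is stored.
#'
#' @param config A [cohort_config()].
#' @param montage Montage data.frame (default 64 channels).
#' @param process Optional per-cell reducer function (see Details).
#' @param include_eeg Set FALSE to skip EEG simulation entirely (behavioral
#'   records only) -- useful for fast behavioral/statistical calibration.
#' @return A `cohort` list: `subjects` (data.frame id, group), `config`,
#'   `montage`, and `cells`, a list indexed `[[subject]][[visit]][[task]]`
#'   holding either `list(eeg =, behavior =)` or the `process` return value.
#' @export
generate_cohort <- function(config, montage = make_montage(64),
                            process = NULL, include_eeg = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(rep("healthy", config$n_healthy), rep("patient", config$n_patient))
  ids <- sprintf("S%03d", seq_along(groups))
  cells <- vector("list", length(ids))
  names(cells) <- ids
  for (si in seq_along(ids)) {
    per_visit <- vector("list", config$visits)
    # subject-level parameters drawn once per task, shared across visits
    params_by_task <- lapply(config$tasks, function(spec) {
      draw_subject_params(groups[si], spec$name, config$group_effect,
                          seed = derive_seed(config$seed, si, 0L,
                                             match(spec$name, c("AOB", "GNG"))),
                          noise_sd_mean = config$noise_sd_mean,
                          blink_rate = config$blink_rate)
    })
    names(params_by_task) <- vapply(config$tasks, `[[`, "", "name")
    for (v in seq_len(config$visits)) {
      per_task <- list()
      for (ti in seq_along(config$tasks)) {
        spec <- config$tasks[[ti]]
        params <- params_by_task[[spec$name]]
        s_seq <- derive_seed(config$seed, si, v, ti, 1L)
        s_eeg <- derive_seed(config$seed, si, v, ti, 2L)
        s_beh <- derive_seed(config$seed, si, v, ti, 3L)
        sequence <- generate_task_sequence(spec, s_seq)
        behavior <- simulate_behavior(sequence, spec, params, s_beh)
        eeg <- if (include_eeg) {
          simulate_subject_eeg(sequence, params, montage, s_eeg,
                               window = spec$epoch_window, task = spec$name)
        } else NULL
        cell <- if (is.null(process)) {
          list(eeg = eeg, behavior = behavior)
        } else {
          process(ids[si], groups[si], v, spec$name, eeg, behavior, params)
        }
        per_task[[spec$name]] <- cell
      }
      per_visit[[v]] <- per_task
    }
    cells[[si]] <- per_visit
  }
  structure(
    list(subjects = data.frame(id = ids, group = groups,
                               stringsAsFactors = FALSE),
         config = config, montage = montage, cells = cells),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d healthy + %d patient subjects x %d visit(s)\n",
              sum(x$subjects$group == "healthy"),
              sum(x$subjects$group == "patient"), x$config$visits))
  invisible(x)
}

#' Demographic metadata for a simulated cohort
#'
#' Ages (14-18 years) and sex are generated as reporting metadata only; they
#' do not influence the simulated signals.
#'
#' @param cohort A `cohort` object.
#' @param seed Integer seed.
#' @return data.frame: id, group, sex, age_years, age_months.
#' @export
cohort_demographics <- function(cohort, seed = 1) {
  rng <- local_rng(seed)
  n <- nrow(cohort$subjects)
  yrs <- rng(sample(14:18, n, replace = TRUE))
  mos <- rng(sample(0:11, n, replace = TRUE))
  sex <- rng(sample(c("M", "F"), n, replace = TRUE, prob = c(0.9, 0.1)))
  data.frame(id = cohort$subjects$id, group = cohort$subjects$group,
             sex = sex, age_years = yrs, age_months = mos,
             stringsAsFactors = FALSE)
}
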