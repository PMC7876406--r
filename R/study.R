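#' Simulation-study task specifications (reduced trial counts)
#'
#' The simulation studies (reference building, percentile calibration,
#' effect-recovery and null calibration) keep the study design -- 30 + 9
#' subjects, two visits, 250 Hz, the full epoch windows, the rare-event
#' trial counts -- but reduce the frequent-condition trial counts and the
#' montage density so a full multi-replicate study runs on one CPU in
#' minutes. Rare conditions (Novel 60, NoGo 30) keep their study sizes;
#' only the frequent conditions are thinned (they enter the analysis
#' through ERPv, whose precision is driven by channels x time averaging,
#' not trial count).
#'
#' @return Named list of [task_spec()] objects (`AOB`, `GNG`).
#' @export
study_task_specs <- function() {
  list(
    AOB = task_spec("AOB", n_trials = 135,
                    condition_probs = c(Frequent = 50 / 135, Target = 25 / 135,
                                        Novel = 60 / 135)),
    GNG = task_spec("GNG", n_trials = 70,
                    condition_probs = c(Go = 40 / 70, NoGo = 30 / 70))
  )
}

#' Montage and grid used by the simulation studies
#' @return List: `montage` (32 channels), `resolution` (24 x 24 grid).
#' @export
study_geometry <- function() {
  list(montage = make_montage(32), resolution = c(24, 24))
}

# Simulate one subject-visit and return its Novel-delta STEPs plus the
# per-condition ERPv table. Blink-free recordings; epoch rejection applied.
simulate_subject_features <- function(group, seed, montage, resolution,
                                      group_effect = default_group_effect(),
                                      params = NULL, visit = 1,
                                      with_erpv = TRUE,
                                      specs = study_task_specs()) {
  registry <- data.frame(condition = "Novel", band = "delta")
  if (is.null(params)) {
    params <- lapply(names(specs), function(tn)
      draw_subject_params(group, tn, group_effect,
                          seed = derive_seed(seed, 0L, match(tn, c("AOB", "GNG"))),
                          blink_rate = 0))
    names(params) <- names(specs)
  }
  steps <- NULL
  erpv <- NULL
  for (tn in names(specs)) {
    spec <- specs[[tn]]
    ti <- match(tn, c("AOB", "GNG"))
    sq <- generate_task_sequence(spec, derive_seed(seed, visit, ti, 1L))
    ee <- simulate_subject_eeg(sq, params[[tn]], montage,
                               derive_seed(seed, visit, ti, 2L),
                               window = spec$epoch_window, task = tn)
    rej <- reject_noisy_epochs(ee)
    ee <- rej$epochs
    if (tn == "AOB") {
      steps <- subject_steps(ee, registry, resolution = resolution)[[1]]
    }
    if (with_erpv) {
      ev <- erpv_by_condition(ee)
      ev$task <- tn
      erpv <- rbind(erpv, ev)
    }
  }
  list(steps = steps, erpv = erpv, params = params)
}

#' Build a simulated normative reference group
#'
#' Simulates `n_members` healthy subjects end-to-end (task sequence, EEG,
#' epoch rejection, Novel-condition delta-band STEP extraction), clusters
#' their STEPs into template peaks and stores the per-member matched
#' amplitude/latency distributions.
#'
#' @param n_members Reference size (the normative convention is 120).
#' @param seed Integer seed.
#' @param montage,resolution Geometry (defaults: [study_geometry()]).
#' @param specs Task specifications (defaults: [study_task_specs()]).
#' @return List: `reference` (a `reference_group`), `member_steps` (list of
#'   STEP tables), `main_steps` (labelled template table).
#' @export
build_simulated_reference <- function(n_members = 120, seed = 1,
                                      montage = NULL, resolution = NULL,
                                      specs = study_task_specs()) {
  geo <- study_geometry()
  if (is.null(montage)) montage <- geo$montage
  if (is.null(resolution)) resolution <- geo$resolution
  member_steps <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    f <- simulate_subject_features("healthy", derive_seed(seed, 9000L, i),
                                   montage, resolution, with_erpv = FALSE,
                                   specs = specs["AOB"])
    member_steps[[i]] <- f$steps
  }
  names(member_steps) <- sprintf("R%03d", seq_len(n_members))
  ms <- label_main_steps(cluster_steps(member_steps))
  ref <- build_reference_group(member_steps, ms)
  ref$main_steps <- label_main_steps(ref$main_steps)
  list(reference = ref, member_steps = member_steps,
       main_steps = ref$main_steps)
}

#' Percentile self-calibration of a reference group
#'
#' Scores every reference member against the full reference (the member's
#' own value included, as it is part of the normative distribution) and
#' pools the percentiles of all template x attribute combinations.
#'
#' @param ref_build Result of [build_simulated_reference()].
#' @return Numeric vector of percentiles.
#' @export
reference_self_percentiles <- function(ref_build) {
  ref <- ref_build$reference
  pcts <- numeric(0)
  for (st in ref_build$member_steps) {
    mm <- match_steps(st, ref$main_steps)
    for (m in which(mm$matched)) {
      lab <- mm$label[m]
      pcts <- c(pcts,
                percentile_score(mm$amplitude[m], ref$values[[lab]]$amplitude),
                percentile_score(mm$time_ms[m], ref$values[[lab]]$latency))
    }
  }
  pcts
}

#' Simulate one cohort replicate and score it against a fixed reference
#'
#' Simulates `n_healthy` controls and `n_patient` patients for `visits`
#' visits, extracts P3a percentile scores (Novel condition, delta band)
#' against the supplied reference and per-condition normalized ERPv,
#' mirroring the two-group, two-visit study design.
#'
#' @param ref_build Reference from [build_simulated_reference()].
#' @param seed Replicate seed.
#' @param n_healthy,n_patient,visits Cohort design.
#' @param group_effect Group effect applied to patients.
#' @return List: `scores` (subject, visit, group, p3a_latency_pct,
#'   p3a_amplitude_pct), `erpv` (subject, visit, group, task, condition,
#'   normalized_erpv).
#' @export
score_cohort_replicate <- function(ref_build, seed, n_healthy = 30,
                                   n_patient = 9, visits = 2,
                                   group_effect = default_group_effect()) {
  geo <- study_geometry()
  ref <- ref_build$reference
  p3a <- ref$main_steps$label[ref$main_steps$component == "P3a"][1]
  if (is.na(p3a)) stop("reference has no P3a template", call. = FALSE)
  groups <- c(rep("healthy", n_healthy), rep("patient", n_patient))
  scores <- NULL
  erpv <- NULL
  for (si in seq_along(groups)) {
    params <- NULL
    for (v in seq_len(visits)) {
      f <- simulate_subject_features(groups[si], derive_seed(seed, si),
                                     geo$montage, geo$resolution,
                                     group_effect = group_effect,
                                     params = params, visit = v)
      params <- f$params       # subject-level parameters shared across visits
      mm <- match_steps(f$steps, ref$main_steps)
      row <- mm[mm$label == p3a, ]
      scores <- rbind(scores, data.frame(
        subject = sprintf("S%03d", si), visit = v, group = groups[si],
        p3a_latency_pct = if (row$matched)
          percentile_score(row$time_ms, ref$values[[p3a]]$latency) else NA_real_,
        p3a_amplitude_pct = if (row$matched)
          percentile_score(row$amplitude, ref$values[[p3a]]$amplitude) else NA_real_,
        stringsAsFactors = FALSE
      ))
      ev <- f$erpv
      ev$subject <- sprintf("S%03d", si)
      ev$visit <- v
      ev$group <- groups[si]
      erpv <- rbind(erpv, ev)
    }
  }
  list(scores = scores, erpv = erpv)
}

#' Effect-recovery study over seeded replicates
#'
#' Runs `n_reps` cohort replicates (30 controls + 9 patients, two visits)
#' with the planted patient effects, tests the P3a latency and amplitude
#' percentile scores with the mixed group x visit ANOVA, and computes the
#' patient-vs-control ROC AUC of normalized ERPv per condition
#' (subject x visit observations).
#'
#' @param ref_build Reference from [build_simulated_reference()].
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param group_effect Planted patient effect.
#' @param alpha Significance level for the ANOVA rejection count.
#' @return List: `latency_sig_rate`, `amplitude_sig_rate` (proportions of
#'   replicates with p < alpha), `erpv_auc` (data.frame condition x mean
#'   AUC), `per_rep` (per-replicate detail).
#' @export
recovery_study <- function(ref_build, n_reps = 20, seed = 1,
                           group_effect = default_group_effect(),
                           alpha = 0.05) {
  lat_p <- amp_p <- numeric(n_reps)
  auc_tab <- NULL
  for (r in seq_len(n_reps)) {
    rep_res <- score_cohort_replicate(ref_build, derive_seed(seed, 100L, r),
                                      group_effect = group_effect)
    sc <- rep_res$scores
    lat_p[r] <- tryCatch(
      mixed_anova(data.frame(subject = sc$subject, visit = sc$visit,
                             group = sc$group, score = sc$p3a_latency_pct))$p,
      error = function(e) NA_real_)
    amp_p[r] <- tryCatch(
      mixed_anova(data.frame(subject = sc$subject, visit = sc$visit,
                             group = sc$group, score = sc$p3a_amplitude_pct))$p,
      error = function(e) NA_real_)
    ev <- rep_res$erpv
    for (cond in unique(ev$condition)) {
      sub <- ev[ev$condition == cond, ]
      auc <- roc_analysis(sub$normalized_erpv, sub$group)$auc
      auc_tab <- rbind(auc_tab, data.frame(rep = r, condition = cond,
                                           auc = auc))
    }
  }
  erpv_auc <- stats::aggregate(auc ~ condition, data = auc_tab, FUN = mean)
  list(
    latency_sig_rate = mean(lat_p < alpha, na.rm = TRUE),
    amplitude_sig_rate = mean(amp_p < alpha, na.rm = TRUE),
    erpv_auc = erpv_auc,
    per_rep = list(latency_p = lat_p, amplitude_p = amp_p, auc = auc_tab)
  )
}

#' Score-level null calibration of the statistical layer
#'
#' Simulates score tables with no group effect (both groups drawn from the
#' same subject-level distribution, two correlated visits per subject) and
#' measures the mixed ANOVA rejection rate at `alpha` and the mean ROC AUC.
#'
#' @param n_reps Number of simulated score tables.
#' @param seed Integer seed.
#' @param n_healthy,n_patient Group sizes.
#' @param alpha Nominal level.
#' @param icc Within-subject correlation of the two visits.
#' @return List: `rejection_rate`, `mean_auc`, `n_reps`.
#' @export
null_score_calibration <- function(n_reps = 500, seed = 1, n_healthy = 30,
                                   n_patient = 9, alpha = 0.05, icc = 0.6) {
  rng <- local_rng(seed)
  n <- n_healthy + n_patient
  group <- c(rep("healthy", n_healthy), rep("patient", n_patient))
  rej <- logical(n_reps)
  aucs <- numeric(n_reps)
  sb <- sqrt(icc); se <- sqrt(1 - icc)
  for (r in seq_len(n_reps)) {
    subj <- rng(stats::rnorm(n, 0, sb))
    v1 <- subj + rng(stats::rnorm(n, 0, se))
    v2 <- subj + rng(stats::rnorm(n, 0, se))
    tab <- data.frame(
      subject = rep(sprintf("S%03d", 1:n), 2),
      visit = rep(1:2, each = n),
      group = rep(group, 2),
      score = c(v1, v2)
    )
    rej[r] <- mixed_anova(tab)$p < alpha
    aucs[r] <- roc_analysis(c(v1, v2), rep(group, 2))$auc
    # undo the orientation convention for the null average: use raw AUC
    raw <- {
      pos <- rep(group, 2) == "patient"
      rk <- rank(c(v1, v2))
      (sum(rk[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
    }
    aucs[r] <- raw
  }
  list(rejection_rate = mean(rej), mean_auc = mean(aucs), n_reps = n_reps)
}
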