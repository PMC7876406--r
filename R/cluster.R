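#' Cluster STEPs across subjects into group-common template peaks
#'
#' Pools the STEPs of all subjects within one band x condition, separates
#' by polarity, and groups them by agglomerative (average-linkage)
#' clustering under a capped space-time metric: two STEPs may share a
#' cluster only if their times differ by at most `max_dt_ms` and their
#' scalp distance is at most `max_ds`. Within each cluster at most one STEP
#' per subject is kept (nearest to the cluster centroid); a cluster is
#' retained iff the fraction of subjects contributing a STEP is at least
#' `prevalence_min`.
#'
#' @param per_subject_steps Named list (one element per subject) of STEP
#'   data.frames from [extract_steps()], all from the same band x condition.
#' @param prevalence_min Minimum fraction of subjects (default 0.7).
#' @param max_dt_ms,max_ds Cluster caps: time (ms) and scalp distance (disc
#'   radii).
#' @param min_time_sd,min_space_sd Dispersion floors used downstream as
#'   matching scales.
#' @return A `main_steps` data.frame: `label`, `centroid_time`,
#'   `centroid_x`, `centroid_y`, `time_dispersion`, `spatial_dispersion`,
#'   `prevalence`, `polarity`, `n_members`, `band`, `condition`.
#' @export
cluster_steps <- function(per_subject_steps, prevalence_min = 0.7,
                          max_dt_ms = 100, max_ds = 0.25,
                          min_time_sd = 10, min_space_sd = 0.05) {
  stopifnot(length(per_subject_steps) >= 2)
  n_subj <- length(per_subject_steps)
  if (is.null(names(per_subject_steps)))
    names(per_subject_steps) <- sprintf("S%03d", seq_len(n_subj))
  pooled <- do.call(rbind, lapply(names(per_subject_steps), function(id) {
    st <- per_subject_steps[[id]]
    if (!nrow(st)) return(NULL)
    data.frame(subject = id, amplitude = st$amplitude, time_ms = st$time_ms,
               x = st$x, y = st$y, polarity = st$polarity,
               band = st$band, condition = st$condition,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(
    label = character(0), centroid_time = numeric(0), centroid_x = numeric(0),
    centroid_y = numeric(0), time_dispersion = numeric(0),
    spatial_dispersion = numeric(0), prevalence = numeric(0),
    polarity = numeric(0), n_members = integer(0), band = character(0),
    condition = character(0), stringsAsFactors = FALSE
  )
  if (is.null(pooled) || !nrow(pooled)) return(empty)
  out <- empty
  for (pol in unique(pooled$polarity)) {
    sub <- pooled[pooled$polarity == pol, , drop = FALSE]
    cl <- if (nrow(sub) == 1) 1L else {
      # normalized Chebyshev-style metric: distance 1 at either cap;
      # average linkage tolerates the between-subject latency spread of a
      # single component while keeping well-separated populations apart
      dt <- abs(outer(sub$time_ms, sub$time_ms, "-")) / max_dt_ms
      ds <- sqrt(outer(sub$x, sub$x, "-")^2 + outer(sub$y, sub$y, "-")^2) / max_ds
      dd <- pmax(dt, ds)
      stats::cutree(stats::hclust(stats::as.dist(dd), method = "average"), h = 1)
    }
    for (g in unique(cl)) {
      mem <- sub[cl == g, , drop = FALSE]
      # one STEP per subject: nearest to the provisional centroid
      ct <- mean(mem$time_ms); cx <- mean(mem$x); cy <- mean(mem$y)
      if (anyDuplicated(mem$subject)) {
        dd <- sqrt(((mem$time_ms - ct) / max_dt_ms)^2 +
                     ((mem$x - cx)^2 + (mem$y - cy)^2) / max_ds^2)
        keep <- unlist(lapply(split(seq_len(nrow(mem)), mem$subject),
                              function(ii) ii[which.min(dd[ii])]))
        mem <- mem[sort(keep), , drop = FALSE]
        ct <- mean(mem$time_ms); cx <- mean(mem$x); cy <- mean(mem$y)
      }
      prev <- length(unique(mem$subject)) / n_subj
      if (prev < prevalence_min) next
      sd_t <- max(stats::sd(mem$time_ms), min_time_sd)
      if (is.na(sd_t)) sd_t <- min_time_sd
      disp_s <- max(sqrt(mean((mem$x - cx)^2 + (mem$y - cy)^2)), min_space_sd)
      band <- mem$band[1]; condition <- mem$condition[1]
      out <- rbind(out, data.frame(
        label = sprintf("%s-%s-%s%d",
                        ifelse(is.na(condition), "any", condition),
                        ifelse(is.na(band), "broadband", band),
                        ifelse(pol > 0, "P", "N"), round(ct)),
        centroid_time = ct, centroid_x = cx, centroid_y = cy,
        time_dispersion = sd_t, spatial_dispersion = disp_s,
        prevalence = prev, polarity = pol,
        n_members = nrow(mem),
        band = band, condition = condition,
        stringsAsFactors = FALSE
      ))
    }
  }
  out <- out[order(out$centroid_time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach canonical component names to clustered template peaks
#'
#' Maps each main STEP to the canonical auditory component whose polarity
#' and latency window it falls in (N100: negative 60-160 ms; P200: positive
#' 150-260 ms; N2: negative 180-350 ms; P3a: positive 240-500 ms); peaks
#' outside every window keep their generic label.
#'
#' @param main_steps A `main_steps` data.frame from [cluster_steps()].
#' @return The same data.frame with a `component` column.
#' @export
label_main_steps <- function(main_steps) {
  windows <- list(
    N100 = list(pol = -1, lo = 60, hi = 160),
    P200 = list(pol = +1, lo = 150, hi = 260),
    N2   = list(pol = -1, lo = 180, hi = 350),
    P3a  = list(pol = +1, lo = 240, hi = 500)
  )
  comp <- rep(NA_character_, nrow(main_steps))
  for (i in seq_len(nrow(main_steps))) {
    for (nm in names(windows)) {
      w <- windows[[nm]]
      if (main_steps$polarity[i] == w$pol &&
          main_steps$centroid_time[i] >= w$lo &&
          main_steps$centroid_time[i] <= w$hi && is.na(comp[i])) {
        comp[i] <- nm
      }
    }
  }
  main_steps$component <- ifelse(is.na(comp), main_steps$label, comp)
  main_steps
}
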