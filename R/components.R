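#' ERP component specification
#'
#' Describes one evoked component as a separable spatiotemporal source: a
#' Gaussian bump in time (centre = latency, width = `kernel_sd`) times an
#' isotropic Gaussian patch on the projected scalp (centre = `topo_center`,
#' scale = `topo_spread`). `latency_sd` and `amplitude_sd` are
#' between-subject spreads used when drawing subject-level parameters;
#' trial-to-trial jitter lives in [subject_params()].
#'
#' @param label Component name, one of "N100", "P200", "N2", "P3a" (free
#'   text allowed for custom components).
#' @param polarity +1 or -1.
#' @param topo_center Length-2 numeric (x, y) on the unit scalp disc.
#' @param topo_spread Spatial Gaussian scale (disc radii).
#' @param latency_mean,latency_sd Post-stimulus latency mean / between-subject
#'   SD in ms.
#' @param amplitude_mean,amplitude_sd Peak amplitude mean / between-subject SD
#'   in microvolts; `amplitude_mean` must be positive (sign carried by
#'   `polarity`).
#' @param kernel_sd Temporal Gaussian width in ms.
#' @param band Dominant frequency band label ("delta", "theta" or "alpha"),
#'   used to choose the filtered ERP in which the component is scored.
#' @param conditions Character vector of conditions that evoke the component.
#' @return A `component_spec` list.
#' @export
component_spec <- function(label, polarity, topo_center, topo_spread,
                           latency_mean, latency_sd,
                           amplitude_mean, amplitude_sd,
                           kernel_sd = 40,
                           band = c("delta", "theta", "alpha"),
                           conditions) {
  band <- match.arg(band)
  stopifnot(polarity %in% c(-1, 1), amplitude_mean > 0,
            latency_sd >= 0, amplitude_sd >= 0, kernel_sd > 0,
            length(topo_center) == 2, topo_spread > 0)
  structure(
    list(label = label, polarity = polarity,
         topo_center = as.numeric(topo_center), topo_spread = topo_spread,
         latency_mean = latency_mean, latency_sd = latency_sd,
         amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
         kernel_sd = kernel_sd, band = band,
         conditions = as.character(conditions)),
    class = "component_spec"
  )
}

#' Default evoked components for a task
#'
#' The canonical auditory components at their textbook latencies and
#' topographies: N100 (fronto-central negativity ~100 ms), P200 (central
#' positivity ~200 ms), and for rare events the attention-driven P3a
#' (fronto-central positivity ~300 ms); the GNG NoGo condition additionally
#' carries the inhibitory N2 (~250 ms). Early components are given sharper
#' temporal kernels (25-30 ms) than the slow P3a (50-60 ms) so their
#' spectral content sits in the theta/alpha range while the P3a is
#' delta-dominant.
#'
#' @param task "AOB" or "GNG".
#' @return List of [component_spec()] objects.
#' @export
default_components <- function(task = c("AOB", "GNG")) {
  task <- match.arg(task)
  if (task == "AOB") {
    list(
      component_spec("N100", -1, c(0, 0.35), 0.45, 100, 10, 4.0, 0.8,
                     kernel_sd = 25, band = "theta",
                     conditions = c("Frequent", "Target", "Novel")),
      component_spec("P200", +1, c(0, 0.05), 0.45, 200, 12, 5.0, 1.0,
                     kernel_sd = 30, band = "theta",
                     conditions = c("Frequent", "Target")),
      component_spec("P3a", +1, c(0, 0.20), 0.50, 300, 25, 8.0, 1.6,
                     kernel_sd = 60, band = "delta",
                     conditions = "Novel")
    )
  } else {
    list(
      component_spec("N100", -1, c(0, 0.35), 0.45, 100, 10, 4.0, 0.8,
                     kernel_sd = 25, band = "theta",
                     conditions = c("Go", "NoGo")),
      component_spec("P200", +1, c(0, 0.05), 0.45, 200, 12, 6.0, 1.2,
                     kernel_sd = 25, band = "alpha",
                     conditions = c("Go", "NoGo")),
      component_spec("N2", -1, c(0, 0.30), 0.45, 250, 20, 5.0, 1.0,
                     kernel_sd = 30, band = "alpha",
                     conditions = "NoGo"),
      component_spec("P3a", +1, c(0, 0.20), 0.50, 320, 25, 7.0, 1.4,
                     kernel_sd = 50, band = "theta",
                     conditions = "NoGo")
    )
  }
}

#' Subject-level simulation parameters
#'
#' Holds everything needed to simulate one subject on one task: the drawn
#' component realizations, the trial-to-trial jitter scales, the additive
#' noise level, blink rate and the behavioral response model.
#'
#' @param group "healthy" or "patient".
#' @param components List of `component_spec` objects (subject-level
#'   realizations; their `latency_mean`/`amplitude_mean` are this subject's
#'   values).
#' @param trial_latency_jitter_sd Trial-to-trial latency jitter SD in ms.
#' @param trial_amplitude_jitter_sd Trial-to-trial additive amplitude jitter
#'   SD in microvolts.
#' @param noise_sd Additive white-noise SD in microvolts.
#' @param blink_rate Blink events per minute.
#' @param rt_mean,rt_sd Reaction-time mean / within-subject SD in ms.
#' @param error_rate Named numeric vector of per-condition error
#'   probabilities.
#' @param component_jitter_scale Named numeric vector of per-component
#'   multipliers applied to both trial jitters for that component (default
#'   1 for all).
#' @return A `subject_params` list.
#' @export
subject_params <- function(group = c("healthy", "patient"),
                           components,
                           trial_latency_jitter_sd = 20,
                           trial_amplitude_jitter_sd = 2,
                           noise_sd = 5,
                           blink_rate = 2,
                           rt_mean = 455, rt_sd = 92,
                           error_rate = c(Target = 0.02),
                           component_jitter_scale = NULL) {
  group <- match.arg(group)
  stopifnot(trial_latency_jitter_sd >= 0, trial_amplitude_jitter_sd >= 0,
            noise_sd >= 0, blink_rate >= 0, rt_sd >= 0,
            all(error_rate >= 0 & error_rate <= 1))
  structure(
    list(group = group, components = components,
         trial_latency_jitter_sd = trial_latency_jitter_sd,
         trial_amplitude_jitter_sd = trial_amplitude_jitter_sd,
         noise_sd = noise_sd, blink_rate = blink_rate,
         rt_mean = rt_mean, rt_sd = rt_sd, error_rate = error_rate,
         component_jitter_scale = component_jitter_scale),
    class = "subject_params"
  )
}

#' Default patient-vs-control group effect
#'
#' The planted group differences applied to patient subjects: a delayed,
#' attenuated and more variable P3a (+50 ms latency, x0.7 amplitude, x1.5
#' trial jitter on that component), a global x1.5 scaling of trial-to-trial
#' jitter and a x1.3 scaling of background noise (the "neural noise"
#' signature of reduced response consistency), plus slower, more variable
#' and less accurate behavior. Pass `null_group_effect()` for an
#' exchangeable-groups cohort.
#'
#' @return A `group_effect` list with elements `components` (per-component
#'   `dlat_ms`, `amp_scale`, `jitter_scale`), `jitter_scale`, `noise_scale`
#'   and `behavior_patient` (per-task RT / error-rate parameters).
#' @export
default_group_effect <- function() {
  structure(list(
    components = list(
      P3a = list(dlat_ms = 50, amp_scale = 0.7, jitter_scale = 1.5)
    ),
    jitter_scale = 1.5,
    noise_scale = 1.3,
    behavior = list(
      healthy = list(
        AOB = list(rt_mean = 455.13, rt_mean_sd = 71.0,
                   rt_sd = 92.22, rt_sd_sd = 32.62,
                   error_rate = c(Target = 1 - 0.9799)),
        GNG = list(rt_mean = 374.07, rt_mean_sd = 53.19,
                   rt_sd = 102.96, rt_sd_sd = 25.25,
                   error_rate = c(Go = 1 - 0.9834, NoGo = 1 - 0.8733))
      ),
      patient = list(
        AOB = list(rt_mean = 570.68, rt_mean_sd = 119.31,
                   rt_sd = 143.46, rt_sd_sd = 40.45,
                   error_rate = c(Target = 1 - 0.9417)),
        GNG = list(rt_mean = 499.32, rt_mean_sd = 60.94,
                   rt_sd = 159.98, rt_sd_sd = 33.71,
                   error_rate = c(Go = 1 - 0.8741, NoGo = 1 - 0.9093))
      )
    )
  ), class = "group_effect")
}

#' Null group effect (exchangeable groups)
#'
#' Identical generating parameters for both groups; useful for type-I-error
#' calibration.
#' @return A `group_effect` list with no planted differences.
#' @export
null_group_effect <- function() {
  ge <- default_group_effect()
  ge$components <- list()
  ge$jitter_scale <- 1
  ge$noise_scale <- 1
  ge$behavior$patient <- ge$behavior$healthy
  ge
}

#' Draw subject-level parameters for one subject
#'
#' Realizes between-subject variability (component latencies/amplitudes,
#' noise level, behavioral parameters) and applies the group effect for
#' patients.
#'
#' @param group "healthy" or "patient".
#' @param task "AOB" or "GNG".
#' @param group_effect A [default_group_effect()]-style list.
#' @param seed Integer seed.
#' @param components Base component list (defaults to
#'   [default_components()]).
#' @param noise_sd_mean Population mean of the additive noise SD
#'   (microvolts); subject values are lognormal with 15% coefficient of
#'   variation.
#' @param blink_rate Blinks per minute (0 disables the blink model).
#' @return A [subject_params()] object.
#' @export
draw_subject_params <- function(group, task, group_effect = default_group_effect(),
                                seed = 1, components = NULL,
                                noise_sd_mean = 5, blink_rate = 2) {
  if (is.null(components)) components <- default_components(task)
  rng <- local_rng(seed)
  is_pat <- group == "patient"
  comp_scale <- if (is_pat) group_effect$components else list()
  jit_scale <- numeric(0)
  comps <- lapply(components, function(cs) {
    cs$latency_mean <- cs$latency_mean + rng(stats::rnorm(1, 0, cs$latency_sd))
    amp <- cs$amplitude_mean * exp(rng(stats::rnorm(1, 0, cs$amplitude_sd / cs$amplitude_mean)))
    eff <- comp_scale[[cs$label]]
    if (!is.null(eff)) {
      cs$latency_mean <- cs$latency_mean + eff$dlat_ms
      amp <- amp * eff$amp_scale
    }
    cs$amplitude_mean <- amp
    cs
  })
  for (cs in components) {
    eff <- comp_scale[[cs$label]]
    jit_scale[cs$label] <- if (!is.null(eff)) eff$jitter_scale else 1
  }
  g_jit <- if (is_pat) group_effect$jitter_scale else 1
  g_noise <- if (is_pat) group_effect$noise_scale else 1
  beh <- group_effect$behavior[[group]][[task]]
  rt_mean <- rng(stats::rnorm(1, beh$rt_mean, beh$rt_mean_sd))
  rt_sd <- max(20, rng(stats::rnorm(1, beh$rt_sd, beh$rt_sd_sd)))
  noise_sd <- noise_sd_mean * g_noise * exp(rng(stats::rnorm(1, 0, 0.15)))
  subject_params(
    group = group, components = comps,
    trial_latency_jitter_sd = 20 * g_jit,
    trial_amplitude_jitter_sd = 2 * g_jit,
    noise_sd = noise_sd, blink_rate = blink_rate,
    rt_mean = max(150, rt_mean), rt_sd = rt_sd,
    error_rate = beh$error_rate,
    component_jitter_scale = jit_scale
  )
}
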