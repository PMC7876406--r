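#' Task specification for the auditory paradigms
#'
#' Builds the stimulus-level description of one of the two auditory tasks:
#' the auditory oddball (AOB; frequent standards with rare targets and rare
#' novel sounds) or the Go/NoGo (GNG; frequent Go tones requiring a button
#' press, rare NoGo tones requiring response inhibition).
#'
#' Defaults follow the standard administration of these paradigms: AOB with
#' 600 tones at 80/10/10% (Frequent 2000 Hz, Target 1000 Hz, Novel complex
#' sounds) presented every 1.5 s, epochs -200..+1200 ms; GNG with 300 tones
#' at 80/20% (Go 2000 Hz, NoGo 1000 Hz), inter-stimulus interval drawn
#' uniformly in 1000..2000 ms, epochs -200..+800 ms. A recording is
#' considered valid when at least 65% of scoreable trials are correct.
#'
#' @param name "AOB" or "GNG".
#' @param n_trials Total number of stimuli.
#' @param condition_probs Named numeric vector of condition probabilities
#'   (must sum to 1).
#' @param tone_freqs Named numeric vector of tone frequencies (Hz); NA for
#'   the Novel complex sounds.
#' @param isi Inter-stimulus interval in ms: length-1 (fixed) or length-2
#'   (uniform range).
#' @param isi_jitter Extra jitter field carried in the configuration but not
#'   applied: the administration protocol describes both a uniform ISI range
#'   and a separate small jitter whose interaction is ambiguous, so only the
#'   uniform range is realized.
#' @param epoch_window Length-2 numeric, (pre_ms, post_ms) with pre_ms < 0.
#' @param min_correct Minimum overall proportion correct for a valid
#'   recording.
#' @return A `task_spec` list.
#' @export
task_spec <- function(name = c("AOB", "GNG"),
                      n_trials = NULL,
                      condition_probs = NULL,
                      tone_freqs = NULL,
                      isi = NULL,
                      isi_jitter = NULL,
                      epoch_window = NULL,
                      min_correct = 0.65) {
  name <- match.arg(name)
  if (name == "AOB") {
    if (is.null(n_trials)) n_trials <- 600L
    if (is.null(condition_probs))
      condition_probs <- c(Frequent = 0.8, Target = 0.1, Novel = 0.1)
    if (is.null(tone_freqs))
      tone_freqs <- c(Frequent = 2000, Target = 1000, Novel = NA_real_)
    if (is.null(isi)) isi <- 1500
    if (is.null(epoch_window)) epoch_window <- c(-200, 1200)
    response_conditions <- "Target"
    inhibition_conditions <- character(0)
  } else {
    if (is.null(n_trials)) n_trials <- 300L
    if (is.null(condition_probs)) condition_probs <- c(Go = 0.8, NoGo = 0.2)
    if (is.null(tone_freqs)) tone_freqs <- c(Go = 2000, NoGo = 1000)
    if (is.null(isi)) isi <- c(1000, 2000)
    if (is.null(epoch_window)) epoch_window <- c(-200, 800)
    response_conditions <- "Go"
    inhibition_conditions <- "NoGo"
  }
  if (abs(sum(condition_probs) - 1) > 1e-9)
    stop("condition_probs must sum to 1", call. = FALSE)
  stopifnot(epoch_window[1] <= 0, epoch_window[2] > 0)
  structure(
    list(name = name, n_trials = as.integer(n_trials),
         condition_probs = condition_probs, tone_freqs = tone_freqs,
         isi = isi, isi_jitter = isi_jitter, epoch_window = epoch_window,
         min_correct = min_correct,
         response_conditions = response_conditions,
         inhibition_conditions = inhibition_conditions),
    class = "task_spec"
  )
}

#' Generate a stimulus sequence for a task
#'
#' Produces the ordered trial list: condition, onset time and tone
#' frequency. Per-condition trial counts are fixed at
#' `round(n_trials * prob)` (largest-remainder correction if rounding does
#' not conserve the total); the order is a seeded random permutation.
#' Onsets accumulate the configured ISI (fixed interval, or uniform draw
#' within the range).
#'
#' @param spec A [task_spec()].
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @return A data.frame with columns `trial`, `condition`, `onset_ms`,
#'   `tone_hz`.
#' @export
generate_task_sequence <- function(spec, seed) {
  stopifnot(inherits(spec, "task_spec"))
  probs <- spec$condition_probs
  if (abs(sum(probs) - 1) > 1e-9)
    stop("condition_probs must sum to 1", call. = FALSE)
  counts <- round(spec$n_trials * probs)
  # largest-remainder fix so counts always conserve n_trials
  excess <- spec$n_trials - sum(counts)
  if (excess != 0) {
    frac <- spec$n_trials * probs - floor(spec$n_trials * probs)
    ord <- order(frac, decreasing = excess > 0)
    counts[ord[seq_len(abs(excess))]] <- counts[ord[seq_len(abs(excess))]] + sign(excess)
  }
  conds <- rep(names(counts), times = counts)
  rng <- local_rng(seed)
  conds <- conds[rng(sample.int(length(conds)))]
  isi_ms <- if (length(spec$isi) == 1) {
    rep(spec$isi, spec$n_trials)
  } else {
    rng(stats::runif(spec$n_trials, spec$isi[1], spec$isi[2]))
  }
  data.frame(
    trial = seq_len(spec$n_trials),
    condition = conds,
    onset_ms = cumsum(isi_ms),
    tone_hz = unname(spec$tone_freqs[conds]),
    stringsAsFactors = FALSE
  )
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, without
# disturbing the caller's RNG state. Returns a closure so several draws can
# share one stream.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    expr
  }
}

#' Derive a reproducible sub-seed from a master seed
#'
#' One master seed drives a whole simulated study; per-subject, per-visit
#' and per-stage streams are derived with a documented counter scheme so any
#' part can be regenerated in isolation. The scheme is a multiplicative
#' congruential mix of the master seed and the integer indices, kept below
#' 2^31.
#'
#' @param seed Master integer seed.
#' @param ... Further integer indices (e.g. subject, visit, stage).
#' @return An integer in 1..(2^31-2).
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647)
  for (k in seq_along(idx)) {
    s <- (s * 69069 + as.double(idx[k]) * 2654435 + 104729 * k) %% 2147483647
  }
  as.integer(s + 1)
}
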