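# Minimal European Data Format (EDF) writer/reader: one continuous
# multi-channel record, 16-bit samples, a single data record spanning the
# whole recording. Sufficient for interchange of simulated cohorts; not a
# general-purpose EDF implementation.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)
}

#' Write a continuous recording to an EDF file
#'
#' @param x Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate, Hz.
#' @param labels Channel labels (defaults to E01..).
#' @param path Output file path.
#' @param patient,recording Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, fs, labels = NULL, path,
                      patient = "X", recording = "simulated") {
  stopifnot(is.matrix(x))
  ns <- nrow(x)
  n_samp <- ncol(x)
  if (is.null(labels)) labels <- sprintf("E%02d", seq_len(ns))
  phys_min <- apply(x, 1, min)
  phys_max <- apply(x, 1, max)
  flat <- phys_max - phys_min < 1e-9
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field(recording, 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(1, 8),                              # one data record
    pad_field(format(n_samp / fs, digits = 10), 8),
    pad_field(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("AgAgCl electrode", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(phys_min, function(v) pad_field(format(v, digits = 7), 8), ""), collapse = ""),
    paste(vapply(phys_max, function(v) pad_field(format(v, digits = 7), 8), ""), collapse = ""),
    paste(rep(pad_field(dig_min, 8), ns), collapse = ""),
    paste(rep(pad_field(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_field("none", 80), ns), collapse = ""),
    paste(rep(pad_field(n_samp, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  for (ch in seq_len(ns)) {
    scale <- (dig_max - dig_min) / (phys_max[ch] - phys_min[ch])
    dig <- round((x[ch, ] - phys_min[ch]) * scale + dig_min)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return List: `data` (channels x samples, microvolts), `fs`, `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr) < 256) stop("malformed EDF: truncated header", call. = FALSE)
  version <- trimws(substr(hdr, 1, 8))
  if (version != "0") stop("malformed EDF: bad version field", call. = FALSE)
  n_records <- as.integer(trimws(substr(hdr, 237, 244)))
  rec_dur <- as.numeric(trimws(substr(hdr, 245, 252)))
  ns <- as.integer(trimws(substr(hdr, 253, 256)))
  if (is.na(ns) || ns < 1) stop("malformed EDF: bad signal count", call. = FALSE)
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  # field offsets in bytes from start of signal header block:
  # labels 0, transducer 16ns, dim 96ns, phys_min 104ns, phys_max 112ns,
  # dig_min 120ns, dig_max 128ns, prefilter 136ns, n_samp 216ns
  off_of <- function(byte_off, width, i) {
    start <- byte_off + (i - 1) * width + 1
    trimws(substr(sig, start, start + width - 1))
  }
  labels <- vapply(seq_len(ns), function(i) off_of(0, 16, i), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) off_of(104 * ns, 8, i), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) off_of(112 * ns, 8, i), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) off_of(120 * ns, 8, i), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) off_of(128 * ns, 8, i), ""))
  n_samp <- as.integer(vapply(seq_len(ns), function(i) off_of(216 * ns, 8, i), ""))
  total <- n_samp * n_records
  data <- matrix(0, ns, total[1])
  for (rec in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = n_samp[ch], size = 2,
                     endian = "little", signed = TRUE)
      scale <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      cols <- ((rec - 1) * n_samp[ch] + 1):(rec * n_samp[ch])
      data[ch, cols] <- (dig - dig_min[ch]) * scale + phys_min[ch]
    }
  }
  fs <- n_samp[1] / rec_dur
  list(data = data, fs = fs, labels = labels)
}

#' Cut epochs from a continuous EDF recording and an events table
#'
#' Epochs are cut with the half-open window `[onset + pre, onset + post)`;
#' the onset sample maps to t = 0. Events whose window extends beyond the
#' recording end are skipped with a warning; an empty events table is an
#' error.
#'
#' @param edf_path Path to the EDF file.
#' @param events_tsv Path to a tab-separated events table with a header row
#'   and columns `onset_ms`, `condition` (extra columns ignored).
#' @param window Length-2 numeric (pre_ms, post_ms).
#' @param montage Montage data.frame matching the recording's channels.
#' @return An [eeg_epochs()] object.
#' @export
load_epochs <- function(edf_path, events_tsv, window, montage) {
  rec <- read_edf(edf_path)
  ev <- utils::read.delim(events_tsv, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(ev)) stop("empty event table", call. = FALSE)
  stopifnot(all(c("onset_ms", "condition") %in% names(ev)))
  stopifnot(nrow(montage) == nrow(rec$data))
  fs <- rec$fs
  n_pre <- round(-window[1] * fs / 1000)
  n_post <- round(window[2] * fs / 1000)
  nt <- n_pre + n_post
  times <- seq(window[1], window[2] - 1000 / fs, by = 1000 / fs)
  total <- ncol(rec$data)
  keep <- list()
  conds <- character(0)
  for (i in seq_len(nrow(ev))) {
    onset_samp <- round(ev$onset_ms[i] * fs / 1000) + 1
    lo <- onset_samp - n_pre
    hi <- onset_samp + n_post - 1
    if (lo < 1 || hi > total) {
      warning(sprintf("event %d at %.0f ms outside recording; skipped",
                      i, ev$onset_ms[i]))
      next
    }
    keep[[length(keep) + 1]] <- rec$data[, lo:hi]
    conds <- c(conds, ev$condition[i])
  }
  if (!length(keep)) stop("no events fall inside the recording", call. = FALSE)
  data <- array(unlist(keep), dim = c(nrow(rec$data), nt, length(keep)))
  eeg_epochs(data, times, fs, montage, conds)
}

#' Write one subject x visit recording as EDF + events/behavior TSVs
#'
#' Serializes epoched data back to a continuous record by placing epochs at
#' their sequence onsets (gaps are zero-filled).
#'
#' @param epochs An [eeg_epochs()] object.
#' @param sequence The stimulus sequence the epochs were cut around.
#' @param behavior The behavioral record.
#' @param dir Output directory (created if needed).
#' @param stem File name stem, e.g. "S001_visit1_AOB".
#' @return Named character vector of the files written.
#' @export
write_recording <- function(epochs, sequence, behavior, dir, stem) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- epochs$fs
  pre <- -min(epochs$times)
  nt <- dim(epochs$data)[2]
  onset_samp <- round(sequence$onset_ms * fs / 1000) + 1
  total <- max(onset_samp) + nt
  cont <- matrix(0, dim(epochs$data)[1], total)
  for (i in seq_len(nrow(sequence))) {
    lo <- onset_samp[i] - round(pre * fs / 1000)
    if (lo < 1) next
    cont[, lo:(lo + nt - 1)] <- epochs$data[, , i]
  }
  edf <- file.path(dir, paste0(stem, ".edf"))
  write_edf(cont, fs, epochs$montage$label, edf)
  ev <- file.path(dir, paste0(stem, "_events.tsv"))
  utils::write.table(sequence[, c("onset_ms", "condition", "tone_hz")],
                     ev, sep = "\t", row.names = FALSE, quote = FALSE)
  beh <- file.path(dir, paste0(stem, "_behavior.tsv"))
  utils::write.table(behavior, beh, sep = "\t", row.names = FALSE, quote = FALSE)
  c(edf = edf, events = ev, behavior = beh)
}
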