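#' Build a synthetic EEG montage on the unit scalp disc
#'
#' Channel positions are laid out on concentric rings of an
#' azimuthal-equidistant ("top view") projection of the scalp, with the
#' vertex at the origin and the y axis pointing anterior. The default 64
#' channels approximate the density of a 64-electrode net referenced at the
#' vertex; positions are deterministic.
#'
#' @param n_channels Number of electrodes. Supported layouts place channels
#'   on up to six rings; any count between 4 and 64 is accepted (rings are
#'   filled from the vertex outwards).
#' @return A data.frame with columns `label`, `x`, `y` (unit-disc
#'   coordinates, radius <= 1).
#' @examples
#' mon <- make_montage(64)
#' plot(mon$x, mon$y, asp = 1)
#' @export
make_montage <- function(n_channels = 64) {
  stopifnot(n_channels >= 4, n_channels <= 64)
  ring_radii <- c(0, 0.2, 0.4, 0.6, 0.8, 0.95)
  ring_sizes <- c(1, 6, 10, 14, 16, 17)
  xs <- ys <- numeric(0)
  remaining <- n_channels
  for (i in seq_along(ring_radii)) {
    if (remaining <= 0) break
    k <- min(ring_sizes[i], remaining)
    if (ring_radii[i] == 0) {
      xs <- c(xs, 0); ys <- c(ys, 0)
    } else {
      # stagger rings; start each ring at the anterior midline
      ang <- pi / 2 + 2 * pi * (seq_len(k) - 1) / k + (i %% 2) * pi / ring_sizes[i]
      xs <- c(xs, ring_radii[i] * cos(ang))
      ys <- c(ys, ring_radii[i] * sin(ang))
    }
    remaining <- remaining - k
  }
  data.frame(
    label = sprintf("E%02d", seq_len(n_channels)),
    x = round(xs, 6), y = round(ys, 6),
    stringsAsFactors = FALSE
  )
}

#' Nearest spatial neighbors of every channel
#'
#' @param montage Montage data.frame from [make_montage()].
#' @param k Number of neighbors per channel.
#' @return Integer matrix (n_channels x k) of neighbor row indices.
#' @export
channel_neighbors <- function(montage, k = 4) {
  n <- nrow(montage)
  stopifnot(n > k)
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' Most anterior channels (frontal / ocular proxy)
#'
#' @param montage Montage data.frame.
#' @param k Number of channels to return.
#' @return Integer vector of channel indices ordered by decreasing y.
#' @export
frontal_channels <- function(montage, k = 2) {
  order(montage$y, decreasing = TRUE)[seq_len(k)]
}
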