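#' Extract spatiotemporal ERP peaks (STEPs) from a grid
#'
#' A STEP is a post-stimulus grid point that is a strict local maximum (or
#' minimum) of the amplitude in its 3 x 3 x 3 space-time neighborhood with
#' absolute amplitude at least `min_abs_amplitude`, together with its
#' half-amplitude surround: the same-sign 26-connected region around the
#' peak in which every point's absolute amplitude is at least half the
#' peak's. Grid nodes outside the head mask (NA) and pre-stimulus time
#' points are never peaks; candidate points must have both temporal
#' neighbors (interior in time), while spatially edge-adjacent points are
#' judged against their available neighbors.
#'
#' @param grid An `erp_grid` from [interpolate_grid()].
#' @param min_abs_amplitude Minimum absolute peak amplitude (microvolts).
#' @param compute_surround Set FALSE to skip the surround flood-fill (the
#'   scoring path only needs amplitude/time/location).
#' @return A data.frame sorted by decreasing |amplitude| with columns
#'   `amplitude`, `time_ms`, `x`, `y`, `ix`, `iy`, `it`, `polarity`,
#'   `n_surround`, and (if requested) a list column `surround` of integer
#'   matrices (ix, iy, it).
#' @export
extract_steps <- function(grid, min_abs_amplitude = 1,
                          compute_surround = TRUE) {
  arr <- grid$values
  d <- dim(arr)
  post <- which(grid$times >= 0)
  peaks_max <- local_extrema_idx(arr, post, min_abs_amplitude, maxima = TRUE)
  peaks_min <- local_extrema_idx(-arr, post, min_abs_amplitude, maxima = TRUE)
  all_idx <- rbind(peaks_max, peaks_min)
  if (!nrow(all_idx)) {
    return(empty_steps(compute_surround))
  }
  amp <- arr[all_idx]
  out <- data.frame(
    amplitude = amp,
    time_ms = grid$times[all_idx[, 3]],
    x = grid$xs[all_idx[, 1]],
    y = grid$ys[all_idx[, 2]],
    ix = all_idx[, 1], iy = all_idx[, 2], it = all_idx[, 3],
    polarity = sign(amp)
  )
  ord <- order(-abs(out$amplitude))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (compute_surround) {
    surr <- vector("list", nrow(out))
    for (i in seq_len(nrow(out))) {
      surr[[i]] <- half_amplitude_surround(
        arr, c(out$ix[i], out$iy[i], out$it[i]), out$amplitude[i]
      )
    }
    out$n_surround <- vapply(surr, nrow, 0L)
    out$surround <- I(surr)
  } else {
    out$n_surround <- NA_integer_
  }
  out$band <- if (is.null(grid$band)) NA_character_ else grid$band
  out$condition <- if (is.null(grid$condition)) NA_character_ else grid$condition
  out
}

empty_steps <- function(compute_surround) {
  out <- data.frame(
    amplitude = numeric(0), time_ms = numeric(0), x = numeric(0),
    y = numeric(0), ix = integer(0), iy = integer(0), it = integer(0),
    polarity = numeric(0), n_surround = integer(0)
  )
  if (compute_surround) out$surround <- I(list())
  out$band <- character(0)
  out$condition <- character(0)
  out
}

# Vectorized strict-local-maximum scan over the 26-neighborhood. NA cells
# (outside the mask) are treated as absent neighbors; candidate cells must
# be non-NA, post-stimulus, interior in time, and >= threshold. Implemented
# on an NA-padded copy so every comparison is a contiguous-range slice.
local_extrema_idx <- function(arr, post_idx, min_abs, maxima = TRUE) {
  d <- dim(arr)
  a <- arr
  a[is.na(a)] <- -Inf
  tkeep <- intersect(post_idx, 2:(d[3] - 1))
  if (!length(tkeep)) return(matrix(0L, 0, 3))
  # stage 1: strict extremum along time on the post-stimulus interior
  # (cheap, removes almost everything)
  cur <- a[, , tkeep, drop = FALSE]
  is_cand <- is.finite(cur) & cur >= min_abs &
    cur > a[, , tkeep - 1L, drop = FALSE] &
    cur > a[, , tkeep + 1L, drop = FALSE]
  if (!any(is_cand)) return(matrix(0L, 0, 3))
  cand <- which(is_cand, arr.ind = TRUE)
  cand[, 3] <- tkeep[cand[, 3]]
  # stage 2: sparse check of the remaining 24 neighbors; spatial neighbors
  # outside the array bounds are absent
  vals <- a[cand]
  keep <- rep(TRUE, nrow(cand))
  for (dx in -1:1) for (dy in -1:1) for (dt in -1:1) {
    if (dx == 0 && dy == 0) next
    nx <- cand[, 1] + dx; ny <- cand[, 2] + dy; nt <- cand[, 3] + dt
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2]
    li <- nx + (ny - 1) * d[1] + (nt - 1) * d[1] * d[2]
    cmp <- rep(TRUE, nrow(cand))
    cmp[ok] <- vals[ok] > a[li[ok]]
    keep <- keep & cmp
  }
  cand[keep, , drop = FALSE]
}

# 26-connected flood fill of the same-sign half-amplitude region containing
# the peak. Operates on the candidate-cell set only (sparse BFS).
half_amplitude_surround <- function(arr, peak_idx, peak_amp) {
  d <- dim(arr)
  pol <- sign(peak_amp)
  cand <- !is.na(arr) & (sign(arr) == pol) & (abs(arr) >= abs(peak_amp) / 2)
  cand_lin <- which(cand)
  if (!length(cand_lin)) return(matrix(0L, 0, 3))
  peak_lin <- peak_idx[1] + (peak_idx[2] - 1) * d[1] + (peak_idx[3] - 1) * d[1] * d[2]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dt = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  in_region <- logical(length(cand_lin))
  pos <- match(peak_lin, cand_lin)
  if (is.na(pos)) return(matrix(peak_idx, 1, 3))
  in_region[pos] <- TRUE
  frontier <- peak_lin
  # index arithmetic on (ix, iy, it)
  coords <- cbind(((cand_lin - 1) %% d[1]) + 1,
                  ((cand_lin - 1) %/% d[1]) %% d[2] + 1,
                  ((cand_lin - 1) %/% (d[1] * d[2])) + 1)
  while (length(frontier)) {
    fx <- ((frontier - 1) %% d[1]) + 1
    fy <- ((frontier - 1) %/% d[1]) %% d[2] + 1
    ft <- ((frontier - 1) %/% (d[1] * d[2])) + 1
    nbr <- integer(0)
    for (k in seq_len(nrow(offs))) {
      nx <- fx + offs[k, 1]; ny <- fy + offs[k, 2]; nt <- ft + offs[k, 3]
      ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nt >= 1 & nt <= d[3]
      if (!any(ok)) next
      nbr <- c(nbr, nx[ok] + (ny[ok] - 1) * d[1] + (nt[ok] - 1) * d[1] * d[2])
    }
    nbr <- unique(nbr)
    pos <- match(nbr, cand_lin)
    pos <- pos[!is.na(pos)]
    pos <- pos[!in_region[pos]]
    in_region[pos] <- TRUE
    frontier <- cand_lin[pos]
  }
  coords[in_region, , drop = FALSE]
}
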