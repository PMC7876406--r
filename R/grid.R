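# Thin-plate spline basis: U(r) = r^2 log r, U(0) = 0.
tps_u <- function(r) {
  out <- r * r * log(r)
  out[r < 1e-12] <- 0
  out
}

#' Precompute a scalp-grid interpolation mapper
#'
#' Builds the linear map from electrode values to a W x H grid over the
#' unit scalp disc using an exact thin-plate spline interpolant (values at
#' grid nodes coinciding with electrode positions equal the electrode
#' values). Nodes outside the head disc are masked. The returned function
#' maps a channel x time matrix to a W x H x T array in one matrix product,
#' so repeated interpolation over many subjects is cheap.
#'
#' @param montage Montage data.frame.
#' @param resolution Length-2 integer (W, H).
#' @param mask_radius Radius of the head mask in disc units.
#' @return A function `f(erp)` (channels x time -> W x H x T array with NA
#'   outside the mask), with attributes `xs`, `ys`, `mask`.
#' @export
make_grid_mapper <- function(montage, resolution = c(32, 32),
                             mask_radius = 1.02) {
  pos <- as.matrix(montage[, c("x", "y")])
  n <- nrow(pos)
  stopifnot(n >= 4)
  if (qr(cbind(1, pos))$rank < 3)
    stop("degenerate montage: electrode positions are collinear", call. = FALSE)
  K <- tps_u(as.matrix(stats::dist(pos)))
  P <- cbind(1, pos)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Li <- solve(L)
  xs <- seq(-1, 1, length.out = resolution[1])
  ys <- seq(-1, 1, length.out = resolution[2])
  gxy <- as.matrix(expand.grid(x = xs, y = ys))
  mask <- sqrt(rowSums(gxy^2)) <= mask_radius
  gin <- gxy[mask, , drop = FALSE]
  D <- sqrt(outer(gin[, 1], pos[, 1], "-")^2 + outer(gin[, 2], pos[, 2], "-")^2)
  B <- cbind(tps_u(D), 1, gin)            # n_in x (n + 3)
  Mmap <- B %*% Li[, seq_len(n), drop = FALSE]  # n_in x n: exact interpolant
  f <- function(erp) {
    if (is.null(dim(erp))) erp <- matrix(erp, ncol = 1)
    vals <- Mmap %*% erp                  # n_in x T
    out <- array(NA_real_, dim = c(resolution[1], resolution[2], ncol(erp)))
    flat <- matrix(NA_real_, nrow(gxy), ncol(erp))
    flat[mask, ] <- vals
    out[] <- flat
    out
  }
  attr(f, "xs") <- xs
  attr(f, "ys") <- ys
  attr(f, "mask") <- matrix(mask, resolution[1], resolution[2])
  f
}

# one mapper cache per montage geometry + resolution
.mapper_cache <- new.env(parent = emptyenv())

#' Interpolate a channel x time ERP onto the scalp grid
#'
#' @param erp Numeric matrix, channels x time (microvolts).
#' @param montage Montage data.frame.
#' @param times Time axis in ms (length = ncol(erp)).
#' @param resolution Grid size (W, H); default 32 x 32.
#' @param band,condition Optional labels stored on the result.
#' @return An `erp_grid` object: list with `values` (W x H x T, NA outside
#'   the head mask), `xs`, `ys`, `times`, `band`, `condition`.
#' @export
interpolate_grid <- function(erp, montage, times, resolution = c(32, 32),
                             band = NULL, condition = NULL) {
  stopifnot(ncol(erp) == length(times))
  key <- rlang::hash(list(montage$x, montage$y, resolution))
  mapper <- .mapper_cache[[key]]
  if (is.null(mapper)) {
    mapper <- make_grid_mapper(montage, resolution)
    .mapper_cache[[key]] <- mapper
  }
  structure(
    list(values = mapper(erp), xs = attr(mapper, "xs"),
         ys = attr(mapper, "ys"), times = times,
         band = band, condition = condition),
    class = "erp_grid"
  )
}

#' @export
print.erp_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<erp_grid> %d x %d grid x %d samples (%g..%g ms)%s%s\n",
              d[1], d[2], d[3], min(x$times), max(x$times),
              if (!is.null(x$band)) paste0(", band ", x$band) else "",
              if (!is.null(x$condition)) paste0(", condition ", x$condition) else ""))
  invisible(x)
}
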