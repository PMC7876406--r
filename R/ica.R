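# Compact symmetric FastICA (tanh contrast) over a whitened channel-space.
# x: channels x samples (assumed roughly zero-mean per channel).
# Returns list(S = sources k x samples, A = mixing channels x k,
# W = unmixing k x channels, converged).
fast_ica <- function(x, n_comp = NULL, max_iter = 100, tol = 1e-4, seed = 1) {
  n_ch <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-9)
  if (is.null(n_comp)) n_comp <- length(keep)
  n_comp <- min(n_comp, length(keep))
  d <- eg$values[seq_len(n_comp)]
  E <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  wh <- diag(1 / sqrt(d), n_comp) %*% t(E)       # whitening: k x channels
  dewh <- E %*% diag(sqrt(d), n_comp)            # channels x k
  z <- wh %*% xc
  rng <- local_rng(seed)
  W <- matrix(rng(stats::rnorm(n_comp * n_comp)), n_comp)
  W <- sym_decorrelate(W)
  converged <- FALSE
  delta <- Inf
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- (g %*% t(z)) / ncol(z) - diag(rowMeans(gp), n_comp) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- W %*% z
  A <- dewh %*% t(W)                              # channels x k mixing
  # noise-dominated components may keep rotating without ever satisfying
  # the formal criterion; the estimate is usable as long as it is finite --
  # `converged` stays informational
  list(S = S, A = A, W = W %*% wh, mean = mu, converged = converged,
       usable = all(is.finite(S)) && all(is.finite(A)))
}

sym_decorrelate <- function(W) {
  sv <- svd(W)
  sv$u %*% t(sv$v)
}

#' Remove blink components with ICA
#'
#' Decomposes the concatenated epochs with a symmetric FastICA, correlates
#' each component's time course with a frontal ocular proxy (the mean of
#' the two most anterior channels of the input), zeroes the components
#' exceeding the correlation cutoff (at most `max_blink_components`,
#' strongest correlations first) and reconstructs the data. If the
#' decomposition fails to converge the input is passed through with a
#' warning.
#'
#' @param epochs An [eeg_epochs()] object with >= 8 channels and >= 30
#'   epochs (for a stable unmixing estimate).
#' @param cfg A [cleaning_config()].
#' @param n_comp Number of components to estimate (default: up to 20).
#' @param seed Seed for the ICA initialization.
#' @return List: `epochs` (reconstructed), `removed_components` (count),
#'   `converged`.
#' @export
remove_blink_components <- function(epochs, cfg = cleaning_config(),
                                    n_comp = NULL, seed = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dm <- dim(epochs$data)
  stopifnot(dm[1] >= 8, dm[3] >= 30)
  if (cfg$max_blink_components == 0)
    return(list(epochs = epochs, removed_components = 0L, converged = TRUE))
  x <- matrix(epochs$data, nrow = dm[1])           # channels x (time*trials)
  if (is.null(n_comp)) n_comp <- min(10L, dm[1])
  dec <- tryCatch(
    fast_ica(x, n_comp = n_comp, seed = seed),
    error = function(e) NULL
  )
  if (is.null(dec) || !dec$usable) {
    warning("ICA decomposition failed; blink removal skipped")
    return(list(epochs = epochs, removed_components = 0L, converged = FALSE))
  }
  fr <- frontal_channels(epochs$montage, 2)
  proxy <- colMeans(x[fr, , drop = FALSE])
  r <- abs(apply(dec$S, 1, stats::cor, y = proxy))
  cand <- which(r > cfg$blink_cor_cutoff)
  if (length(cand) > cfg$max_blink_components)
    cand <- cand[order(r[cand], decreasing = TRUE)][seq_len(cfg$max_blink_components)]
  if (length(cand)) {
    # subtract only the blink components' contribution; variance outside
    # the estimated subspace is untouched
    x_rec <- x - dec$A[, cand, drop = FALSE] %*% dec$S[cand, , drop = FALSE]
    epochs$data <- array(x_rec, dim = dm)
  }
  list(epochs = epochs, removed_components = length(cand),
       converged = TRUE)
}
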