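# Regularized linear-nonlinear receptive-field estimation from
# cloud-stimulus responses.

#' Bin spikes at the stimulus refresh rate
#'
#' @param spike_times Spike times (ms).
#' @param duration_ms Record duration (ms).
#' @param refresh_hz Stimulus refresh rate (Hz), default 20 (50 ms bins).
#' @return Integer vector of counts, one per stimulus frame.
#' @export
bin_spikes <- function(spike_times, duration_ms, refresh_hz = 20) {
  bin_ms <- 1000 / refresh_hz
  n <- ceiling(duration_ms / bin_ms)
  counts <- tabulate(pmin(floor(spike_times / bin_ms) + 1L, n), nbins = n)
  as.integer(counts)
}

# Discrete 5-point Laplacian with replicated edges (so flat and affine
# fields have zero interior penalty and edge pixels are not penalized for
# grid truncation).
laplacian_2d <- function(k) {
  up <- k[c(1, seq_len(nrow(k) - 1)), , drop = FALSE]
  dn <- k[c(seq_len(nrow(k) - 1) + 1, nrow(k)), , drop = FALSE]
  lf <- k[, c(1, seq_len(ncol(k) - 1)), drop = FALSE]
  rt <- k[, c(seq_len(ncol(k) - 1) + 1, ncol(k)), drop = FALSE]
  up + dn + lf + rt - 4 * k
}

# Sparse matrix form of laplacian_2d on an (nr x nc) grid, so the penalty
# gradient can use the exact transpose (the replicated-edge operator is
# not symmetric).
laplacian_operator <- function(nr, nc) {
  idx <- function(r, c) (c - 1L) * nr + r
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  add <- function(r2, c2, v) {
    rows <<- c(rows, idx(g$r, g$c))
    cols <<- c(cols, idx(r2, c2))
    vals <<- c(vals, rep(v, nrow(g)))
  }
  add(pmax(g$r - 1L, 1L), g$c, 1)
  add(pmin(g$r + 1L, nr), g$c, 1)
  add(g$r, pmax(g$c - 1L, 1L), 1)
  add(g$r, pmin(g$c + 1L, nc), 1)
  add(g$r, g$c, -4)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(nr * nc, nr * nc))
}

#' Laplacian-square smoothness penalty of a spatiotemporal filter
#'
#' Sum over pixels and time steps of the squared discrete 5-point spatial
#' Laplacian (replicated edges).
#'
#' @param k Numeric array `(nx, ny, n_lags)` or a single matrix.
#' @return Scalar penalty.
#' @export
laplacian_penalty <- function(k) {
  if (is.matrix(k)) k <- array(k, c(dim(k), 1))
  sum(vapply(seq_len(dim(k)[3]),
             function(l) sum(laplacian_2d(k[, , l])^2), 0))
}

#' GLM training settings
#'
#' Defaults mirror the reference estimation protocol: 3000 epochs of
#' full-batch Adam at learning rate 1e-6, decayed by 10 % every 2000
#' epochs, mean-squared-error loss with a Laplacian-square penalty on the
#' spatial filters.
#'
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param decay Multiplicative decay applied every `decay_every` epochs.
#' @param decay_every Epochs between decays.
#' @param lambda Laplacian penalty weight (on standardized stimuli).
#' @param beta1,beta2,eps Adam moment parameters.
#' @return A `glm_config` list.
#' @export
glm_config <- function(epochs = 3000, lr = 1e-6, decay = 0.9,
                       decay_every = 2000, lambda = 1.0, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  stopifnot(epochs > 0, lr > 0, lambda >= 0)
  structure(list(epochs = epochs, lr = lr, decay = decay,
                 decay_every = decay_every, lambda = lambda, beta1 = beta1,
                 beta2 = beta2, eps = eps), class = "glm_config")
}

#' Fit a spatiotemporal receptive field by penalized rectified regression
#'
#' Predicts the binned spike count of one RGC as
#' `r(t) = ReLU(b + sum_i k_i . s_i(t))` over `n_lags` stimulus frames
#' (the spike bin's frame and the preceding ones), minimizing mean squared
#' error plus a Laplacian-square penalty by full-batch Adam.  Stimulus
#' pixels are standardized internally; filters are initialized at zero, so
#' the fit is deterministic.
#'
#' @param frames Stimulus array `(nx, ny, T)` (e.g.
#'   `light_cloud()$frames`).
#' @param counts Binned spike counts, length `T` (see [bin_spikes()]).
#' @param config A [glm_config()].
#' @param n_lags Temporal span in frames (default 5: 0 to -200 ms at
#'   20 Hz).
#' @return A `glm_filter`: list with `k` (array `nx, ny, n_lags`, lag 1 =
#'   time of spike), `bias`, `loss` (per-epoch training loss), `config`.
#' @export
fit_glm <- function(frames, counts, config = glm_config(), n_lags = 5) {
  dm <- dim(frames)
  if (length(dm) != 3) stop("'frames' must be an (nx, ny, T) array")
  T_all <- dm[3]
  if (length(counts) != T_all)
    stop("'counts' length must match the number of stimulus frames")
  if (T_all <= n_lags) stop("need more frames than temporal lags")
  npix <- dm[1] * dm[2]
  S <- matrix(frames, nrow = npix)          # npix x T
  mu <- mean(S); sdv <- stats::sd(S)
  S <- (S - mu) / sdv
  valid <- seq.int(n_lags, T_all)           # frames with full history
  y <- counts[valid]
  Tn <- length(valid)
  # lag l uses frame t - (l - 1)
  Slag <- lapply(seq_len(n_lags), function(l) S[, valid - (l - 1), drop = FALSE])
  L <- laplacian_operator(dm[1], dm[2])
  LtL2 <- 2 * Matrix::crossprod(L, L)
  k <- matrix(0, npix, n_lags)
  b <- 0
  m1 <- matrix(0, npix, n_lags); v1 <- matrix(0, npix, n_lags)
  m1b <- 0; v1b <- 0
  lr <- config$lr
  loss <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    if (ep > 1 && (ep - 1) %% config$decay_every == 0) lr <- lr * config$decay
    u <- rep(b, Tn)
    for (l in seq_len(n_lags)) u <- u + crossprod(Slag[[l]], k[, l])[, 1]
    r <- pmax(u, 0)
    e <- r - y
    pen <- 0
    gk <- matrix(0, npix, n_lags)
    # subgradient 1 at exactly zero, so the deterministic zero
    # initialization is not a dead point of the rectifier
    gu <- 2 * e * (u >= 0) / Tn
    for (l in seq_len(n_lags)) {
      gk[, l] <- Slag[[l]] %*% gu
      lk <- as.vector(L %*% k[, l])
      pen <- pen + sum(lk^2)
      gk[, l] <- gk[, l] + config$lambda * as.vector(LtL2 %*% k[, l])
    }
    gb <- sum(gu)
    loss[ep] <- mean(e^2) + config$lambda * pen
    # Adam update
    m1 <- config$beta1 * m1 + (1 - config$beta1) * gk
    v1 <- config$beta2 * v1 + (1 - config$beta2) * gk^2
    m1b <- config$beta1 * m1b + (1 - config$beta1) * gb
    v1b <- config$beta2 * v1b + (1 - config$beta2) * gb^2
    mh <- m1 / (1 - config$beta1^ep); vh <- v1 / (1 - config$beta2^ep)
    k <- k - lr * mh / (sqrt(vh) + config$eps)
    b <- b - lr * (m1b / (1 - config$beta1^ep)) /
      (sqrt(v1b / (1 - config$beta2^ep)) + config$eps)
  }
  structure(list(k = array(k, c(dm[1], dm[2], n_lags)), bias = b,
                 loss = loss, config = config,
                 standardize = c(mean = mu, sd = sdv)), class = "glm_filter")
}

#' Predict binned rates from a fitted receptive field
#'
#' @param object A `glm_filter`.
#' @param frames Stimulus array `(nx, ny, T)` on the same pixel grid.
#' @param ... Unused.
#' @return Predicted rate per frame (first `n_lags - 1` frames are NA).
#' @export
predict.glm_filter <- function(object, frames, ...) {
  dm <- dim(frames)
  n_lags <- dim(object$k)[3]
  S <- (matrix(frames, nrow = dm[1] * dm[2]) - object$standardize["mean"]) /
    object$standardize["sd"]
  out <- rep(NA_real_, dm[3])
  valid <- seq.int(n_lags, dm[3])
  u <- rep(object$bias, length(valid))
  for (l in seq_len(n_lags))
    u <- u + crossprod(S[, valid - (l - 1), drop = FALSE],
                       as.vector(object$k[, , l]))[, 1]
  out[valid] <- pmax(u, 0)
  out
}
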