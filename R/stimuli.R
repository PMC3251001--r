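#' Stimulus ensembles
#'
#' A stimulus ensemble is a sequence of `T` luminance frames of `H` x `W`
#' pixels, stored as a `T x H x W` array together with bookkeeping metadata.
#' Ensembles are the raw material for spatiotemporal embedding
#' ([embed_spatiotemporal()]) and for simulating LN model cells.
#'
#' @param frames numeric `T x H x W` array of luminance values.
#' @param frame_rate frames per second (metadata only).
#' @param kind one of `"white_noise"`, `"naturalistic"`, `"external"`.
#' @param seed integer seed the frames were generated from, or `NULL`.
#' @return An object of class `"stimulus_ensemble"`: the frame array with
#'   attributes `frame_rate`, `kind` and `seed`.
#' @export
stimulus_ensemble <- function(frames, frame_rate = 33, kind = "external",
                              seed = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a T x H x W array")
  if (any(!is.finite(frames)))
    stop("stimulus frames must be finite")
  kind <- match.arg(kind, c("white_noise", "naturalistic", "external"))
  structure(frames,
            frame_rate = frame_rate, kind = kind, seed = seed,
            class = c("stimulus_ensemble", "array"))
}

#' @export
print.stimulus_ensemble <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Stimulus ensemble (%s): %d frames of %d x %d pixels @ %g Hz\n",
              attr(x, "kind"), d[1], d[2], d[3], attr(x, "frame_rate")))
  cat(sprintf("  mean %.4f, sd %.4f, seed %s\n", mean(x), stats::sd(x),
              if (is.null(attr(x, "seed"))) "none" else attr(x, "seed")))
  invisible(x)
}

#' Generate an uncorrelated Gaussian white-noise ensemble
#'
#' Every pixel of every frame is an independent standard-normal draw; the
#' whole ensemble is then z-scored so the pooled mean is exactly 0 and the
#' pooled standard deviation exactly 1.
#'
#' @param T,H,W number of frames and frame height/width in pixels.
#' @param seed integer seed; the same seed always produces the same array.
#' @param frame_rate frames per second (metadata).
#' @return A [stimulus_ensemble()] of kind `"white_noise"`.
#' @export
generate_white_noise <- function(T, H, W, seed = 1L, frame_rate = 33) {
  stopifnot(T >= 1, H >= 1, W >= 1)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  x <- array(stats::rnorm(T * H * W), dim = c(T, H, W))
  x <- (x - mean(x)) / stats::sd(x)
  stimulus_ensemble(x, frame_rate = frame_rate, kind = "white_noise",
                    seed = seed)
}

#' Generate a correlated, non-Gaussian naturalistic surrogate ensemble
#'
#' Emulates the second-order and marginal statistics that distinguish natural
#' movies from white noise: a power-law spatial power spectrum
#' (power ~ 1/f^`spectrum_exponent`), temporal correlation by AR(1) mixing of
#' successive frames, and a non-Gaussian pixel marginal obtained by
#' histogram-matching the pooled values to a log-normal distribution.  The
#' result is z-scored overall.  With `spectrum_exponent = 0`,
#' `ar_coefficient = 0` and the identity transform the output is white noise.
#'
#' @inheritParams generate_white_noise
#' @param spectrum_exponent exponent of the spatial power spectrum (>= 0);
#'   2 approximates natural scenes.
#' @param nongaussian_transform `"lognormal"` (histogram-match the pooled
#'   marginal to a log-normal, giving heavy tails) or `"identity"`.
#' @param ar_coefficient AR(1) mixing coefficient across frames in [0, 1).
#' @param lognormal_sdlog sdlog of the log-normal target marginal.
#' @return A [stimulus_ensemble()] of kind `"naturalistic"`.
#' @export
generate_naturalistic <- function(T, H, W, spectrum_exponent = 2,
                                  nongaussian_transform = c("lognormal",
                                                            "identity"),
                                  ar_coefficient = 0.6, seed = 1L,
                                  frame_rate = 33, lognormal_sdlog = 1) {
  stopifnot(T >= 1, H >= 1, W >= 1, spectrum_exponent >= 0,
            ar_coefficient >= 0, ar_coefficient < 1)
  nongaussian_transform <- match.arg(nongaussian_transform)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))

  # amplitude filter on the 2D DFT grid: power ~ 1/f^a  =>  amplitude 1/f^(a/2)
  fx <- dft_frequencies(H)
  fy <- dft_frequencies(W)
  f <- sqrt(outer(fx^2, fy^2, `+`))
  amp <- ifelse(f > 0, f^(-spectrum_exponent / 2), 0)  # zero out DC

  frames <- array(0, dim = c(T, H, W))
  prev <- matrix(0, H, W)
  mix <- ar_coefficient
  innov_scale <- sqrt(1 - mix^2)
  for (t in seq_len(T)) {
    wn <- matrix(stats::rnorm(H * W), H, W)
    if (spectrum_exponent > 0) {
      sp <- stats::fft(wn) * amp
      wn <- Re(stats::fft(sp, inverse = TRUE)) / (H * W)
    }
    prev <- if (t == 1) wn else mix * prev + innov_scale * wn
    frames[t, , ] <- prev
  }

  if (nongaussian_transform == "lognormal") {
    # monotone rank map of the pooled marginal onto a log-normal:
    # preserves the spatial/temporal correlation structure (up to the
    # monotone distortion) while making the marginal heavy-tailed.
    r <- rank(frames, ties.method = "average")
    q <- stats::qlnorm(r / (length(frames) + 1), meanlog = 0,
                       sdlog = lognormal_sdlog)
    frames <- array(q, dim = dim(frames))
  }
  frames <- (frames - mean(frames)) / stats::sd(frames)
  stimulus_ensemble(frames, frame_rate = frame_rate, kind = "naturalistic",
                    seed = seed)
}

dft_frequencies <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' Embed a stimulus ensemble spatiotemporally
#'
#' Builds the `N x D` design matrix of the LN model: row `i` is the
#' concatenation of `n_lags` consecutive frames ending at frame
#' `i + n_lags - 1` (most recent frame last), each frame flattened
#' column-major.  `D = H * W * n_lags` and `N = T - n_lags + 1`; initial
#' frames with incomplete history are dropped, not zero-padded, so every row
#' is a fully observed causal stimulus history.
#'
#' @param ensemble a [stimulus_ensemble()] or `T x H x W` array.
#' @param n_lags number of time points per filter (>= 1).
#' @return An object of class `"embedded_stimuli"`: an `N x D` matrix with
#'   attributes `H`, `W`, `n_lags` and `frame_index` (the original index of
#'   the most recent frame in each row).
#' @export
embed_spatiotemporal <- function(ensemble, n_lags) {
  d <- dim(ensemble)
  T <- d[1]; H <- d[2]; W <- d[3]
  if (n_lags < 1 || n_lags != round(n_lags)) stop("`n_lags` must be a positive integer")
  if (T < n_lags) stop("need at least `n_lags` frames")
  N <- T - n_lags + 1
  P <- H * W
  flat <- matrix(ensemble, nrow = T)   # T x (H*W), frame t flattened in row t
  X <- matrix(0, N, P * n_lags)
  for (l in seq_len(n_lags)) {
    X[, ((l - 1) * P + 1):(l * P)] <- flat[l:(l + N - 1), , drop = FALSE]
  }
  structure(X, H = H, W = W, n_lags = n_lags,
            frame_index = n_lags:T,
            class = c("embedded_stimuli", "matrix", "array"))
}

#' @export
print.embedded_stimuli <- function(x, ...) {
  cat(sprintf("Embedded stimuli: N = %d rows, D = %d (%d x %d pixels x %d lags)\n",
              nrow(x), ncol(x), attr(x, "H"), attr(x, "W"), attr(x, "n_lags")))
  invisible(x)
}

#' Reconstruct the frame sequence from an embedding
#'
#' Inverse of [embed_spatiotemporal()] up to the dropped initial frames:
#' returns the `T x H x W` array covered by the embedded rows.
#'
#' @param embedded an `"embedded_stimuli"` matrix.
#' @return A `T x H x W` array with `T = N + n_lags - 1`.
#' @export
unembed_frames <- function(embedded) {
  H <- attr(embedded, "H"); W <- attr(embedded, "W")
  L <- attr(embedded, "n_lags"); P <- H * W
  N <- nrow(embedded)
  T <- N + L - 1
  flat <- matrix(0, T, P)
  flat[1:N, ] <- embedded[, 1:P, drop = FALSE]
  if (L > 1)   # trailing frames come from the last row, one block per frame
    flat[(N + 1):T, ] <- matrix(embedded[N, (P + 1):(P * L)],
                                nrow = L - 1, ncol = P, byrow = TRUE)
  array(flat, dim = c(T, H, W))
}

#' Contiguous jackknife partition of N rows
#'
#' Splits row indices `1..N` into `fold_count` contiguous held-out blocks of
#' near-equal size (sizes differ by at most one; shorter blocks first).  Fold
#' `k` trains on all rows outside block `k`.
#'
#' @param N number of rows.
#' @param fold_count number of folds (default 4).
#' @return Object of class `"jackknife_partition"`: a list with `n`, `folds`,
#'   and `blocks` (list of held-out index vectors).
#' @export
jackknife_partitions <- function(N, fold_count = 4L) {
  if (N < fold_count) stop("N must be at least `fold_count`")
  sizes <- rep(N %/% fold_count, fold_count)
  extra <- N %% fold_count
  if (extra > 0) sizes[(fold_count - extra + 1):fold_count] <-
      sizes[(fold_count - extra + 1):fold_count] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- Map(seq.int, starts, ends)
  structure(list(n = N, folds = fold_count, blocks = blocks),
            class = "jackknife_partition")
}

#' Training rows for one jackknife fold
#' @param partition a [jackknife_partitions()] object.
#' @param fold fold index in `1..folds`.
#' @return Integer vector of training row indices (everything outside the
#'   fold's held-out block).
#' @export
training_rows <- function(partition, fold) {
  setdiff(seq_len(partition$n), partition$blocks[[fold]])
}

#' Held-out rows for one jackknife fold
#' @inheritParams training_rows
#' @export
heldout_rows <- function(partition, fold) partition$blocks[[fold]]

#' Per-frame spike response aligned with embedded stimuli
#'
#' @param counts nonnegative integer vector of per-frame spike counts, one
#'   per embedded row.
#' @return Object of class `"spike_response"`: the counts with attribute
#'   `mean_rate` (spikes per frame).
#' @export
spike_response <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts)) || any(!is.finite(counts)))
    stop("spike counts must be nonnegative integers")
  structure(counts, mean_rate = sum(counts) / length(counts),
            class = "spike_response")
}

#' @export
print.spike_response <- function(x, ...) {
  cat(sprintf("Spike response: %d frames, %d spikes, mean rate %.4f/frame\n",
              length(x), sum(x), attr(x, "mean_rate")))
  invisible(x)
}

# --- seeded RNG helpers -----------------------------------------------------
# Generators take an explicit seed and must not disturb the caller's RNG
# stream; save and restore .Random.seed around seeded sections.

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  if (!is.null(seed)) set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# derive a distinct 31-bit sub-seed from a master seed and a stream label
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
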