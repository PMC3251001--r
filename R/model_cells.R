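#' Gabor spatiotemporal filter specification
#'
#' @param center length-2 centre in pixels `(row, col)`; default frame centre.
#' @param orientation grating orientation in radians.
#' @param spatial_frequency cycles per pixel.
#' @param phase grating phase in radians (phases pi/2 apart give quadrature
#'   pairs).
#' @param envelope_sd Gaussian envelope SD in pixels (> 0).
#' @param temporal_weights numeric weights indexed by lag: first element is
#'   lag 0 (the most recent frame), second lag 1, and so on.  Not all zero.
#' @return A list of class `"gabor_spec"`.
#' @export
gabor_spec <- function(center = NULL, orientation = 0,
                       spatial_frequency = 0.125, phase = 0,
                       envelope_sd = 3, temporal_weights = c(1, 0.5, -0.25)) {
  if (envelope_sd <= 0) stop("`envelope_sd` must be positive")
  if (all(temporal_weights == 0)) stop("temporal weights must not all be zero")
  structure(list(center = center, orientation = orientation,
                 spatial_frequency = spatial_frequency, phase = phase,
                 envelope_sd = envelope_sd,
                 temporal_weights = temporal_weights),
            class = "gabor_spec")
}

#' Build a unit-norm spatiotemporal dimension from a Gabor specification
#'
#' The dimension is separable: a spatial Gabor profile (Gaussian envelope
#' times an oriented cosine grating) multiplied by per-lag temporal weights,
#' laid out to match [embed_spatiotemporal()] (lag blocks oldest to most
#' recent, each frame flattened column-major), and normalised to unit
#' Euclidean length.
#'
#' @param spec a [gabor_spec()].
#' @param H,W frame height and width in pixels.
#' @param n_lags number of lags of the embedding; `length(temporal_weights)`
#'   must not exceed it (missing lags are zero).
#' @return Unit-norm numeric vector of length `H * W * n_lags`.
#' @export
make_gabor_dimension <- function(spec, H, W, n_lags) {
  tw <- spec$temporal_weights
  if (length(tw) > n_lags) stop("more temporal weights than lags")
  tw <- c(tw, rep(0, n_lags - length(tw)))
  ctr <- if (is.null(spec$center)) c((H + 1) / 2, (W + 1) / 2) else spec$center
  row <- matrix(seq_len(H), H, W) - ctr[1]
  col <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2]
  u <- row * cos(spec$orientation) + col * sin(spec$orientation)
  env <- exp(-(row^2 + col^2) / (2 * spec$envelope_sd^2))
  gab <- env * cos(2 * pi * spec$spatial_frequency * u + spec$phase)
  # lag block l holds the frame n_lags - l frames in the past
  v <- as.vector(vapply(seq_len(n_lags),
                        function(l) tw[n_lags - l + 1] * gab,
                        matrix(0, H, W)))
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("degenerate Gabor parameters give a zero filter")
  v / nv
}

#' LN model-cell specification
#'
#' Defines an LN model neuron by its relevant dimensions (unit-norm columns
#' of `dimensions`) and a static gain family:
#' \describe{
#'   \item{`or_threshold`}{spike if `|s1 + n1| > theta` OR `|s2 + n2| > theta`
#'     with independent Gaussian noise `n_i ~ N(0, sigma^2)`; Bernoulli
#'     spiking with the noise-averaged probability.}
#'   \item{`divisive`}{`r = gamma * ((s.e1)^2 + (s.e2)^2) / (1 + omega * (s.e3)^2)`,
#'     Poisson spiking; `omega = 0` reduces it to the 2D quadratic cell.}
#'   \item{`quadratic_1d`}{`r = gamma * (s.e1)^2`, Poisson spiking.}
#' }
#'
#' @param dimensions `D x K` matrix of linearly independent unit-norm columns
#'   (`K` in 1..3).
#' @param gain_family one of `"or_threshold"`, `"divisive"`, `"quadratic_1d"`.
#' @param theta,sigma OR-threshold and noise SD (or_threshold family).
#' @param gamma scale of the quadratic numerator (> 0).
#' @param omega suppression strength of the third dimension (>= 0).
#' @return A list of class `"ln_cell"`.
#' @export
ln_cell <- function(dimensions,
                    gain_family = c("or_threshold", "divisive", "quadratic_1d"),
                    theta = 2, sigma = 0.5, gamma = 1, omega = 0) {
  gain_family <- match.arg(gain_family)
  dimensions <- as.matrix(dimensions)
  dimnames(dimensions) <- NULL
  K <- ncol(dimensions)
  arity <- switch(gain_family, or_threshold = 2L, divisive = 3L,
                  quadratic_1d = 1L)
  if (K != arity)
    stop(sprintf("gain family '%s' needs %d dimensions, got %d",
                 gain_family, arity, K))
  nrm <- sqrt(colSums(dimensions^2))
  if (any(abs(nrm - 1) > 1e-8)) dimensions <- sweep(dimensions, 2, nrm, `/`)
  if (qr(dimensions)$rank < K) stop("dimensions must be linearly independent")
  if (theta <= 0 || sigma <= 0 || gamma <= 0 || omega < 0)
    stop("require theta, sigma, gamma > 0 and omega >= 0")
  structure(list(dimensions = dimensions, gain_family = gain_family,
                 theta = theta, sigma = sigma, gamma = gamma, omega = omega),
            class = "ln_cell")
}

#' @export
print.ln_cell <- function(x, ...) {
  cat(sprintf("LN model cell: %s gain, K = %d, D = %d\n", x$gain_family,
              ncol(x$dimensions), nrow(x$dimensions)))
  pars <- switch(x$gain_family,
    or_threshold = sprintf("theta = %.4g, sigma = %.4g", x$theta, x$sigma),
    divisive = sprintf("gamma = %.4g, omega = %.4g", x$gamma, x$omega),
    quadratic_1d = sprintf("gamma = %.4g", x$gamma))
  cat("  ", pars, "\n", sep = "")
  invisible(x)
}

#' Expected per-frame spike rate (or spike probability) of an LN cell
#'
#' For the OR-threshold family the returned value is the noise-averaged
#' Bernoulli spike probability, computed in closed form from Gaussian tail
#' probabilities; for the quadratic families it is the Poisson mean.
#'
#' @param cell an [ln_cell()].
#' @param projections `N x K` matrix of stimulus projections onto the cell's
#'   dimensions (columns in the order of `cell$dimensions`).
#' @return Numeric vector of length `N` of expected spike counts per frame.
#' @export
expected_rate <- function(cell, projections) {
  projections <- as.matrix(projections)
  K <- ncol(cell$dimensions)
  if (ncol(projections) != K)
    stop(sprintf("expected %d projection columns, got %d", K,
                 ncol(projections)))
  switch(cell$gain_family,
    or_threshold = {
      p1 <- or_exceed_prob(projections[, 1], cell$theta, cell$sigma)
      p2 <- or_exceed_prob(projections[, 2], cell$theta, cell$sigma)
      1 - (1 - p1) * (1 - p2)
    },
    divisive = {
      cell$gamma * (projections[, 1]^2 + projections[, 2]^2) /
        (1 + cell$omega * projections[, 3]^2)
    },
    quadratic_1d = cell$gamma * projections[, 1]^2)
}

# P(|s + n| > theta) with n ~ N(0, sigma^2); exact in the sigma -> 0 limit
or_exceed_prob <- function(s, theta, sigma) {
  if (sigma == 0) return(as.numeric(abs(s) > theta))
  stats::pnorm((s - theta) / sigma) + stats::pnorm(-(s + theta) / sigma)
}

#' Projections of embedded stimuli onto the cell's own dimensions
#' @param cell an [ln_cell()].
#' @param embedded an `N x D` embedded stimulus matrix.
#' @return `N x K` projection matrix.
#' @export
cell_projections <- function(cell, embedded) {
  unclass(embedded) %*% cell$dimensions
}

#' Calibrate the gain parameters of an LN cell on a stimulus ensemble
#'
#' For the divisive family, solves the suppression strength from the linear
#' condition `mean(1 + omega * (s.e3)^2) = suppression_target`, then scales
#' `gamma` so the empirical mean rate equals `rate_target`.  For the
#' OR-threshold family, bisects `theta` so the mean spike probability equals
#' `rate_target`.  For the quadratic family, scales `gamma` to `rate_target`.
#'
#' @param cell an [ln_cell()].
#' @param embedded `N x D` embedded stimuli used as the calibration ensemble.
#' @param rate_target target mean spikes per frame (default 0.56, the
#'   divisive model-cell operating point).
#' @param suppression_target target of `mean(1 + omega * (s.e3)^2)`
#'   (default 4.26); divisive family only.
#' @return The cell with calibrated parameters.
#' @export
calibrate_gain <- function(cell, embedded, rate_target = 0.56,
                           suppression_target = 4.26) {
  if (rate_target <= 0) stop("`rate_target` must be positive")
  proj <- cell_projections(cell, embedded)
  if (cell$gain_family == "divisive") {
    if (suppression_target <= 1) stop("`suppression_target` must exceed 1")
    m3 <- mean(proj[, 3]^2)
    cell$omega <- (suppression_target - 1) / m3
    base <- mean((proj[, 1]^2 + proj[, 2]^2) /
                   (1 + cell$omega * proj[, 3]^2))
    cell$gamma <- rate_target / base
  } else if (cell$gain_family == "quadratic_1d") {
    cell$gamma <- rate_target / mean(proj[, 1]^2)
  } else {
    if (rate_target >= 1) stop("Bernoulli rate target must be < 1")
    f <- function(th) {
      c2 <- cell; c2$theta <- th
      mean(expected_rate(c2, proj)) - rate_target
    }
    hi <- max(abs(proj)) + 6 * cell$sigma
    if (f(1e-8) < 0) stop("rate target unattainable for this ensemble")
    cell$theta <- stats::uniroot(f, c(1e-8, hi), tol = 1e-12)$root
  }
  cell
}

#' Draw spikes from per-frame expected rates
#'
#' Poisson counts for rate-valued cells, Bernoulli for probability-valued
#' ones.  Reproducible for a fixed seed and independent of the caller's RNG
#' state.
#'
#' @param rates nonnegative expected spikes per frame.
#' @param seed integer seed.
#' @param model `"poisson"` or `"bernoulli"`.
#' @return A [spike_response()].
#' @export
simulate_spikes <- function(rates, seed = 1L,
                            model = c("poisson", "bernoulli")) {
  model <- match.arg(model)
  if (any(rates < 0) || any(!is.finite(rates)))
    stop("rates must be finite and nonnegative")
  if (model == "bernoulli" && any(rates > 1))
    stop("Bernoulli model needs probabilities in [0, 1]")
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  counts <- if (model == "poisson") stats::rpois(length(rates), rates)
            else stats::rbinom(length(rates), 1L, rates)
  spike_response(counts)
}

#' Spiking model matched to a cell's gain family
#' @param cell an [ln_cell()].
#' @return `"bernoulli"` for the OR-threshold family, else `"poisson"`.
#' @export
spike_model <- function(cell) {
  if (cell$gain_family == "or_threshold") "bernoulli" else "poisson"
}

#' Standard two- and three-dimensional Gabor model cells
#'
#' Builds the reference model geometry: a quadrature pair of spatial Gabors
#' (identical orientation and spatial frequency, phases pi/2 apart) with a
#' transient temporal profile, plus — for the 3D divisive cell — a third,
#' suppressive Gabor at the orthogonal orientation.
#'
#' @param H,W,n_lags embedding geometry (defaults 16 x 16 x 3).
#' @param gain_family `"or_threshold"` (2D), `"divisive"` (3D) or
#'   `"quadratic_1d"` (1D; first Gabor only).
#' @param theta,sigma,gamma,omega gain parameters passed to [ln_cell()].
#' @param spatial_frequency,envelope_sd shared Gabor geometry.
#' @return An [ln_cell()].
#' @export
make_model_cell <- function(H = 16, W = 16, n_lags = 3,
                            gain_family = c("or_threshold", "divisive",
                                            "quadratic_1d"),
                            theta = 2, sigma = 0.5, gamma = 1, omega = 0,
                            spatial_frequency = 2 / 16, envelope_sd = 3.2) {
  gain_family <- match.arg(gain_family)
  tw <- c(1, 0.6, -0.3)[seq_len(min(3, n_lags))]
  g1 <- gabor_spec(orientation = pi / 4, spatial_frequency = spatial_frequency,
                   phase = 0, envelope_sd = envelope_sd, temporal_weights = tw)
  g2 <- gabor_spec(orientation = pi / 4, spatial_frequency = spatial_frequency,
                   phase = pi / 2, envelope_sd = envelope_sd,
                   temporal_weights = tw)
  g3 <- gabor_spec(orientation = 3 * pi / 4,
                   spatial_frequency = spatial_frequency, phase = 0,
                   envelope_sd = envelope_sd, temporal_weights = tw)
  e1 <- make_gabor_dimension(g1, H, W, n_lags)
  e2 <- make_gabor_dimension(g2, H, W, n_lags)
  e3 <- make_gabor_dimension(g3, H, W, n_lags)
  dims <- switch(gain_family,
                 quadratic_1d = cbind(e1),
                 or_threshold = cbind(e1, e2),
                 divisive = cbind(e1, e2, e3))
  ln_cell(dims, gain_family, theta = theta, sigma = sigma, gamma = gamma,
          omega = omega)
}

#' Simulate an LN cell's response to an ensemble
#'
#' Convenience wrapper: embeds the ensemble, scales the OR threshold and
#' noise relative to the observed projection SD (so `theta`/`sigma` are in
#' projection-SD units for that family), computes expected rates, and draws
#' spikes.
#'
#' @param cell an [ln_cell()].
#' @param ensemble a [stimulus_ensemble()].
#' @param seed spike-generation seed.
#' @param scale_threshold if `TRUE` (default) and the cell is OR-threshold,
#'   interpret `theta` and `sigma` as multiples of the SD of the projections
#'   onto the cell's dimensions.
#' @return List with `embedded`, `projections`, `rates`, `spikes`, `cell`
#'   (with absolute threshold units).
#' @export
simulate_cell_response <- function(cell, ensemble, seed = 1L,
                                   scale_threshold = TRUE) {
  n_lags <- length(cell$dimensions[, 1]) / (dim(ensemble)[2] * dim(ensemble)[3])
  if (n_lags != round(n_lags))
    stop("cell dimensionality incompatible with ensemble frame size")
  emb <- embed_spatiotemporal(ensemble, as.integer(n_lags))
  proj <- cell_projections(cell, emb)
  if (cell$gain_family == "or_threshold" && scale_threshold) {
    s <- mean(apply(proj[, 1:2, drop = FALSE], 2, stats::sd))
    cell$theta <- cell$theta * s
    cell$sigma <- cell$sigma * s
  }
  rates <- expected_rate(cell, proj)
  spikes <- simulate_spikes(rates, seed = seed, model = spike_model(cell))
  list(embedded = emb, projections = proj, rates = rates, spikes = spikes,
       cell = cell)
}
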