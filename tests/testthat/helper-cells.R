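# Shared fixture builders: everything is generated in code at fixed seeds.

# small 1D quadratic-gain cell on white noise, with embedded stimuli
small_quadratic_data <- function(T = 6000, H = 6, W = 6, n_lags = 1,
                                 seed = 11, gamma = 0.5) {
  stim <- generate_white_noise(T, H, W, seed = seed)
  cell <- make_model_cell(H, W, n_lags, "quadratic_1d",
                         spatial_frequency = 1.5 / H, envelope_sd = H / 4,
                         gamma = gamma)
  resp <- simulate_cell_response(cell, stim, seed = seed + 1)
  c(resp, list(stim = stim))
}

# small 2D OR-threshold cell
small_or_data <- function(T = 8000, H = 6, W = 6, n_lags = 1, seed = 21,
                          theta = 1.2, sigma = 0.5,
                          kind = c("white", "natural", "gaussian_corr")) {
  kind <- match.arg(kind)
  stim <- switch(kind,
    white = generate_white_noise(T, H, W, seed = seed),
    natural = generate_naturalistic(T, H, W, seed = seed),
    gaussian_corr = generate_naturalistic(T, H, W, seed = seed,
                                          nongaussian_transform = "identity"))
  cell <- make_model_cell(H, W, n_lags, "or_threshold",
                         spatial_frequency = 1.5 / H, envelope_sd = H / 4,
                         theta = theta, sigma = sigma)
  resp <- simulate_cell_response(cell, stim, seed = seed + 1)
  c(resp, list(stim = stim))
}

# direct-summation oracle for the binned information: an independent second
# implementation (plain loop over bins)
mi_oracle <- function(p_spike, p_x) {
  total <- 0
  for (b in seq_along(p_spike)) {
    if (p_spike[b] > 0) total <- total + p_spike[b] * log2(p_spike[b] / p_x[b])
  }
  total
}

# direct-formula oracle for the order-2 Renyi divergence
renyi2_oracle <- function(p_spike, p_x) {
  acc <- 0
  for (b in seq_along(p_spike))
    if (p_spike[b] > 0) acc <- acc + p_spike[b]^2 / p_x[b]
  log2(acc)
}

# chi^2 gradient of the PPR objective at dimension v with ridge f
ppr_chi2_gradient <- function(S, res, v, ridge) {
  pv <- as.vector(S %*% v)
  fv <- midest:::ridge_eval(ridge, pv)
  fp <- midest:::ridge_slope(ridge, pv)
  as.vector(crossprod(S, -2 * (res - fv) * fp))
}

# component of vector g outside the span of the columns of E
out_of_span <- function(g, E) {
  B <- qr.Q(qr(E))[, seq_len(ncol(as.matrix(E))), drop = FALSE]
  g - B %*% crossprod(B, g)
}
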