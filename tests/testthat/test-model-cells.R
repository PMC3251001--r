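test_that("Gabor dimensions are unit-norm, separable and quadrature pairs decorrelate", {
  sp <- gabor_spec(orientation = pi / 3, spatial_frequency = 0.2,
                   envelope_sd = 4, temporal_weights = c(1, -0.5))
  v <- make_gabor_dimension(sp, 12, 12, 2)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)

  # quadrature pair: phases pi/2 apart are nearly orthogonal when the
  # envelope covers at least a wavelength
  sq <- sp; sq$phase <- sp$phase + pi / 2
  w <- make_gabor_dimension(sq, 12, 12, 2)
  expect_lt(abs(sum(v * w)), 0.1)

  # temporal separability: weights indexed by lag, zero weights zero out
  # whole lag blocks (lag 0 = most recent = last block)
  s3 <- gabor_spec(temporal_weights = c(0, 0, 1))
  v3 <- make_gabor_dimension(s3, 4, 4, 3)
  P <- 16
  expect_true(all(v3[(P + 1):(3 * P)] == 0))   # lags 0 and 1 empty
  expect_gt(sum(abs(v3[1:P])), 0)              # lag 2 carries the filter

  expect_error(make_gabor_dimension(gabor_spec(temporal_weights = c(0, 0))))
})

test_that("expected rates follow each gain family's closed form", {
  D <- 20
  e <- diag(D)[, 1:3]
  div <- ln_cell(e, "divisive", gamma = 1.3, omega = 0.8)
  proj <- matrix(rnorm(30 * 3, sd = 2), 30, 3)
  r <- expected_rate(div, proj)
  expect_equal(r, 1.3 * (proj[, 1]^2 + proj[, 2]^2) /
                 (1 + 0.8 * proj[, 3]^2))

  # omega = 0 reduces the divisive cell to the sum of squares
  div0 <- ln_cell(e, "divisive", gamma = 1.3, omega = 0)
  expect_equal(expected_rate(div0, proj),
               1.3 * (proj[, 1]^2 + proj[, 2]^2))

  q <- ln_cell(e[, 1, drop = FALSE], "quadratic_1d", gamma = 2)
  expect_equal(expected_rate(q, matrix(0, 3, 1)), rep(0, 3))

  expect_error(expected_rate(div, proj[, 1:2]))
})

test_that("OR-threshold probabilities match their noiseless and noisy limits", {
  e <- diag(6)[, 1:2]
  cell <- ln_cell(e, "or_threshold", theta = 1, sigma = 0.4)

  # noiseless limit
  c0 <- cell; c0$sigma <- 1e-12
  expect_equal(expected_rate(c0, cbind(1.5, 0)), 1, tolerance = 1e-6)
  expect_equal(expected_rate(c0, cbind(0.5, -0.8)), 0, tolerance = 1e-6)

  # at (theta, 0) the first component exceeds threshold half the time
  for (sg in c(0.1, 0.5, 2)) {
    cs <- cell; cs$sigma <- sg
    expect_gte(expected_rate(cs, cbind(1, 0)), 0.5)
  }

  # closed form against a brute-force Monte-Carlo average over the noise
  set.seed(42)
  s <- c(0.7, -1.2)
  n <- 2e5
  mc <- mean(abs(s[1] + rnorm(n, 0, 0.4)) > 1 |
             abs(s[2] + rnorm(n, 0, 0.4)) > 1)
  expect_equal(unname(expected_rate(cell, rbind(s))[1]), mc,
               tolerance = 5e-3)
})

test_that("rate functions are symmetric under sign flips of any dimension", {
  d <- small_or_data(T = 200)
  proj <- d$projections
  expect_equal(expected_rate(d$cell, proj), expected_rate(d$cell, -proj))
  dv <- ln_cell(diag(10)[, 1:3], "divisive", gamma = 1, omega = 0.5)
  p3 <- matrix(rnorm(60), 20, 3)
  for (k in 1:3) {
    pf <- p3; pf[, k] <- -pf[, k]
    expect_equal(expected_rate(dv, p3), expected_rate(dv, pf))
  }
})

test_that("divisive calibration hits its operating point and is idempotent", {
  stim <- generate_naturalistic(3000, 8, 8, seed = 31)
  emb <- embed_spatiotemporal(stim, 2)
  cell <- make_model_cell(8, 8, 2, "divisive")
  cal <- calibrate_gain(cell, emb)
  proj <- cell_projections(cal, emb)
  expect_equal(mean(1 + cal$omega * proj[, 3]^2), 4.26, tolerance = 1e-6)
  expect_equal(mean(expected_rate(cal, proj)), 0.56, tolerance = 1e-6)

  cal2 <- calibrate_gain(cal, emb)
  expect_lt(abs(cal2$gamma - cal$gamma), 1e-9)
  expect_lt(abs(cal2$omega - cal$omega), 1e-9)

  # unit-variance projections give omega = 3.26 analytically; enforce by
  # whitening the third projection through a synthetic embedding
  set.seed(32)
  S <- matrix(rnorm(4000 * 3), ncol = 3)
  S[, 3] <- S[, 3] / stats::sd(S[, 3]) * sqrt(4000 / (4000 - 0))
  S[, 3] <- S[, 3] / sqrt(mean(S[, 3]^2))       # mean square exactly 1
  cell3 <- ln_cell(diag(3), "divisive")
  cal3 <- calibrate_gain(cell3, S)
  expect_equal(cal3$omega, 3.26, tolerance = 1e-9)
})

test_that("OR-threshold calibration reaches a target firing probability", {
  d <- small_or_data(T = 3000)
  cal <- calibrate_gain(d$cell, d$embedded, rate_target = 0.3)
  r <- expected_rate(cal, cell_projections(cal, d$embedded))
  expect_equal(mean(r), 0.3, tolerance = 1e-6)
  expect_error(calibrate_gain(d$cell, d$embedded, rate_target = 1.5))
})

test_that("spike simulation is reproducible Poisson/Bernoulli with unit Fano factor", {
  expect_equal(as.numeric(simulate_spikes(rep(0, 50), seed = 1)), rep(0, 50))
  expect_error(simulate_spikes(c(-0.1, 1)))

  r <- rep(0.56, 50000)
  sp <- simulate_spikes(r, seed = 3)
  expect_identical(as.numeric(simulate_spikes(r, seed = 3)), as.numeric(sp))
  expect_lt(abs(mean(sp) - 0.56), 3 * sqrt(0.56 / 50000))
  expect_gt(stats::var(as.numeric(sp)) / mean(sp), 0.95)
  expect_lt(stats::var(as.numeric(sp)) / mean(sp), 1.05)

  b <- simulate_spikes(rep(0.3, 1000), seed = 4, model = "bernoulli")
  expect_true(all(as.numeric(b) %in% 0:1))
  expect_error(simulate_spikes(rep(1.5, 10), model = "bernoulli"))
})
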