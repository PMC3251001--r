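test_that("projection is linear and respects basis vectors", {
  d <- small_quadratic_data(T = 300)
  emb <- d$embedded
  D <- ncol(emb)
  p5 <- project_stimuli(emb, unit_basis(D, 5))
  expect_equal(as.vector(p5), unclass(emb)[, 5])

  set.seed(1)
  v <- rnorm(D)
  expect_equal(project_stimuli(emb, 2 * v), 2 * project_stimuli(emb, v))

  # rotating a dimension pair rotates the projection pair identically
  V <- cbind(rnorm(D), rnorm(D))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(project_stimuli(emb, V %*% R), project_stimuli(emb, V) %*% R)

  expect_error(project_stimuli(emb, rnorm(D + 1)))
})

test_that("binned distributions are normalized histograms with spike weighting", {
  x <- cbind(rep(0.5, 40))
  sp <- c(rep(1, 10), rep(0, 30))
  bd <- bin_distributions(x, sp, bins = 6)
  expect_equal(sum(bd$P_x), 1)
  expect_equal(sum(bd$P_x_spike), 1)
  expect_equal(max(bd$P_x), 1)          # point mass
  expect_equal(max(bd$P_x_spike), 1)

  set.seed(2)
  x2 <- cbind(rnorm(500))
  sp2 <- integer(500); sp2[x2 > 1] <- 1   # spikes only in the upper bins
  bd2 <- bin_distributions(x2, sp2, bins = 8)
  expect_true(all(bd2$P_x_spike[bd2$P_x == 0] == 0))  # support containment
  expect_equal(sum(bd2$P_x_spike > 0 & bd2$P_x == 0), 0)

  # uniform spiking makes the two distributions identical
  bd3 <- bin_distributions(x2, rep(1, 500), bins = 7)
  expect_equal(bd3$P_x_spike, bd3$P_x)

  expect_error(bin_distributions(x2, integer(500)))
})

test_that("empirical gain follows g = rbar * P(x|spike)/P(x) with its normalization", {
  # two-bin worked example
  bd <- structure(list(P_x = c(0.5, 0.5), P_x_spike = c(1, 0),
                       counts = c(5, 5), spike_weights = c(1, 0), n = 10,
                       n_spikes = 1, mean_rate = 0.1, K = 1,
                       scheme = binning_scheme(cbind(c(0, 1)), 2)),
                  class = "binned_distributions")
  g <- estimate_gain(bd)
  expect_equal(g$g, c(0.2, 0))

  set.seed(3)
  x <- cbind(rnorm(2000))
  sp <- rpois(2000, exp(x) / 3)
  bd2 <- bin_distributions(x, sp, bins = 9)
  g2 <- estimate_gain(bd2)
  occ <- bd2$P_x > 0
  expect_equal(sum(bd2$P_x[occ] * g2$g[occ]), bd2$mean_rate,
               tolerance = 1e-12)

  # uninformative dimension: P identical -> g constant at the mean rate
  bd3 <- bin_distributions(x, rep(2, 2000), bins = 5)
  g3 <- estimate_gain(bd3)
  expect_equal(unique(round(g3$g[bd3$P_x > 0], 12)), 2)
})

test_that("mutual information matches a direct-summation oracle", {
  bd <- list(P_x = c(0.5, 0.5), P_x_spike = c(1, 0))
  expect_equal(mutual_information(bd), 1)
  bd0 <- list(P_x = c(0.3, 0.7), P_x_spike = c(0.3, 0.7))
  expect_equal(mutual_information(bd0), 0)

  set.seed(4)
  for (rep in 1:5) {
    px <- runif(5); px <- px / sum(px)
    ps <- runif(5); ps[sample(5, 1)] <- 0; ps <- ps / sum(ps)
    bd <- list(P_x = px, P_x_spike = ps)
    expect_equal(mutual_information(bd), mi_oracle(ps, px),
                 tolerance = 1e-12)
  }
})

test_that("Renyi-2 divergence matches its direct formula and sharpens monotonely", {
  bd0 <- list(P_x = c(0.4, 0.6), P_x_spike = c(0.4, 0.6))
  expect_equal(renyi2_divergence(bd0), 0)

  set.seed(5)
  px <- runif(6); px <- px / sum(px)
  ps <- runif(6); ps <- ps / sum(ps)
  expect_equal(renyi2_divergence(list(P_x = px, P_x_spike = ps)),
               renyi2_oracle(ps, px), tolerance = 1e-12)

  # interpolating P(x|spike) toward a point mass never decreases it
  point <- numeric(6); point[which.max(ps / px)] <- 1
  vals <- sapply(seq(0, 1, length.out = 21), function(a) {
    p <- (1 - a) * px + a * point
    renyi2_divergence(list(P_x = px, P_x_spike = p))
  })
  expect_true(all(diff(vals) > -1e-12))
})

test_that("rate-based information per spike has its closed forms", {
  expect_equal(info_per_spike(rep(3.2, 100)), 0)
  r <- rep(c(2, 0), each = 50)   # twice the mean on half the frames
  expect_equal(info_per_spike(r), 1)
  expect_error(info_per_spike(rep(0, 10)))
})

test_that("information is scale-invariant, nonnegative and recombination-stable", {
  d <- small_or_data(T = 20000)
  emb <- d$embedded; sp <- d$spikes
  set.seed(6)
  v <- rnorm(ncol(emb))
  I1 <- info_objective(emb, sp, v, bins = 9)
  expect_equal(info_objective(emb, sp, 3.7 * v, bins = 9), I1)
  expect_equal(info_objective(emb, sp, -v, bins = 9), I1)
  expect_gte(I1, 0)

  # invertible recombination of a 2D set changes binned info by < 5%
  V <- d$cell$dimensions
  I2 <- info_objective(emb, sp, V, bins = 9)
  set.seed(7)
  for (rep in 1:3) {
    th <- runif(1, 0, pi)   # rotation plus mild anisotropy: well-conditioned
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    I2r <- info_objective(emb, sp, V %*% (R %*% diag(c(1, 1.5))), bins = 9)
    expect_lt(abs(I2r - I2), 0.05 * I2)
  }
})

test_that("the data-processing chain holds and the 2D OR projections are sufficient", {
  d <- small_or_data(T = 50000, theta = 2)
  emb <- d$embedded; sp <- d$spikes
  e1 <- d$cell$dimensions[, 1]; e2 <- d$cell$dimensions[, 2]
  I1 <- info_objective(emb, sp, e1, bins = 11)
  I12 <- info_objective(emb, sp, d$cell$dimensions, bins = 11)
  ispk <- info_per_spike(d$rates)
  expect_lte(I1, I12 + 1e-9)
  expect_lte(I12, ispk * 1.05)          # bound up to estimator noise
  # sufficiency: the true pair captures nearly all rate information; the
  # shortfall (measured ~11% here) is the equal-width binning loss at B = 11
  expect_gte(I12, 0.85 * ispk)
})
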