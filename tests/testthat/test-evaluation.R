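test_that("subspace projection has its closed-form anchor cases", {
  D <- 30
  set.seed(91)
  E <- qr.Q(qr(matrix(rnorm(D * 6), D, 6)))
  M <- E[, 1:3]
  expect_equal(subspace_projection(M, M)$O, 1, tolerance = 1e-12)
  expect_equal(subspace_projection(M, E[, 4:6])$O, 0, tolerance = 1e-12)

  # each of three dimensions recovered with projection 0.8 along an
  # independent tilt: O = 0.8 while the raw volume is only ~0.5
  R <- 0.8 * M + 0.6 * E[, 4:6]
  sp <- subspace_projection(M, R)
  expect_equal(sp$O, 0.8, tolerance = 1e-12)
  expect_equal(sp$volume, 0.512, tolerance = 1e-12)

  # K = 1 equals absolute cosine similarity
  v <- rnorm(D); w <- rnorm(D)
  expect_equal(subspace_projection(cbind(v), cbind(w))$O,
               abs(sum(v * w)) / sqrt(sum(v^2) * sum(w^2)),
               tolerance = 1e-12)

  expect_error(subspace_projection(cbind(M[, 1], M[, 1]), R[, 1:2]),
               "rank")
})

test_that("subspace projection is symmetric and recombination-invariant", {
  set.seed(92)
  D <- 25
  X <- matrix(rnorm(D * 2), D, 2)
  Y <- matrix(rnorm(D * 2), D, 2)
  O <- subspace_projection(X, Y)$O
  expect_equal(subspace_projection(Y, X)$O, O, tolerance = 1e-12)
  for (rep in 1:5) {
    A <- matrix(rnorm(4), 2, 2) + 1.5 * diag(2)
    B <- matrix(rnorm(4), 2, 2) + 1.5 * diag(2)
    expect_lt(abs(subspace_projection(X %*% A, Y %*% B)$O - O), 1e-10)
  }
})

test_that("percent information explained is anchored by exact and random dimensions", {
  d <- small_or_data(T = 40000, seed = 93, theta = 2)
  ispk <- info_per_spike(d$rates)
  exact <- percent_info_explained(d$cell$dimensions, d$embedded, d$spikes,
                                  ispk)
  # the ~11% shortfall from 100% is the equal-width B = 11 binning loss
  expect_gte(exact$percent, 85)

  set.seed(94)
  rnd <- percent_info_explained(cbind(rnorm(ncol(d$embedded))),
                                d$embedded, d$spikes, ispk)
  expect_gte(rnd$percent, 0)
  expect_lt(rnd$percent, exact$percent / 2)

  expect_error(percent_info_explained(d$cell$dimensions, d$embedded,
                                      d$spikes, 0))
})

test_that("held-out percent information uses each fold's own dimensions", {
  d <- small_quadratic_data(T = 10000, H = 4, W = 4, seed = 95)
  fit <- mid(d$embedded, d$spikes, K = 1, folds = 4,
             control = mid_control(iterations = 100), seed = 96)
  ispk <- info_per_spike(d$rates)
  pi <- percent_info_explained(fit, d$embedded, d$spikes, ispk)
  expect_length(pi$per_fold, 4)
  expect_gt(pi$percent, 50)              # well-determined 1D problem
  expect_lt(pi$percent, 115)             # bound up to estimator noise
})

test_that("SNR maps flag saturation and stay low for pure noise estimates", {
  set.seed(97)
  v <- rnorm(40)
  same <- replicate(3, cbind(v), simplify = FALSE)
  s <- snr_map(same)
  expect_true(all(is.infinite(s)))

  # shuffled-spike (pure noise) estimates: few coefficients exceed SNR 2
  noise <- replicate(4, cbind(rnorm(200)), simplify = FALSE)
  sn <- snr_map(noise)
  expect_lte(mean(sn > 2), 0.10)
  expect_error(snr_map(noise[1]))
})

test_that("the convergence experiment tabulates O against the sampling ratio", {
  stim <- generate_naturalistic(3000, 5, 5, seed = 98)
  emb <- embed_spatiotemporal(stim, 1)
  cells <- list("1" = make_model_cell(5, 5, 1, "quadratic_1d",
                                      spatial_frequency = 0.3,
                                      envelope_sd = 1.25))
  tab <- convergence_experiment(emb, cells, spike_budgets = c(400, 1600),
                                cell_K = 1, seeds = 1:2,
                                control = mid_control(iterations = 60))
  expect_equal(nrow(tab), 8)             # 2 budgets x 2 seeds x 2 modes
  expect_true(all(tab$O >= 0 & tab$O <= 1))
  expect_equal(unique(tab$ratio), unique(tab$K * tab$D / tab$n_spikes))
  # joint and sequential are identical for K = 1 by construction
  js <- merge(tab[tab$mode == "joint", ], tab[tab$mode == "sequential", ],
              by = c("budget", "seed"))
  expect_equal(js$O.x, js$O.y, tolerance = 1e-9)
  expect_error(convergence_experiment(emb, cells, spike_budgets = 0.5,
                                      cell_K = 1))
})
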