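test_that("white-noise generator is deterministic, z-scored and Gaussian", {
  a <- generate_white_noise(500, 4, 4, seed = 7)
  b <- generate_white_noise(500, 4, 4, seed = 7)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a),
                         unclass(generate_white_noise(500, 4, 4, seed = 8))))

  big <- generate_white_noise(50000, 4, 4, seed = 1)
  expect_lt(abs(mean(big)), 0.02)
  expect_lt(abs(stats::var(as.vector(big)) - 1), 0.02)

  # independence across frames: lag-1 autocorrelation of single pixels
  for (px in list(c(1, 1), c(2, 3), c(4, 4))) {
    x <- big[, px[1], px[2]]
    r1 <- stats::cor(x[-1], x[-length(x)])
    expect_lt(abs(r1), 0.02)
  }

  # marginal normality at T = 10000 and |lag-k autocorr| < 3/sqrt(T)
  med <- generate_white_noise(10000, 3, 3, seed = 2)
  x <- med[, 2, 2]
  expect_gt(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value, 0.01)
  for (k in 1:3)
    expect_lt(abs(stats::cor(x[-(1:k)], x[1:(length(x) - k)])),
              3 / sqrt(10000))
})

test_that("white-noise generator rejects non-positive dimensions", {
  expect_error(generate_white_noise(0, 4, 4))
  expect_error(generate_white_noise(10, 0, 4))
})

test_that("naturalistic surrogate is heavy-tailed and spatially correlated", {
  nat <- generate_naturalistic(5000, 8, 8, seed = 3)
  x <- as.vector(nat)
  kurt <- mean((x - mean(x))^4) / stats::sd(x)^4 - 3
  expect_gt(kurt, 0.5)

  # neighbouring-pixel correlation under a 1/f^2 spectrum
  expect_gt(stats::cor(as.vector(nat[, 1:7, ]), as.vector(nat[, 2:8, ])), 0.3)

  # temporal correlation from the AR(1) mixing
  px <- nat[, 4, 4]
  expect_gt(stats::cor(px[-1], px[-length(px)]), 0.2)

  expect_error(generate_naturalistic(100, 4, 4, nongaussian_transform = "no"))
})

test_that("degenerate naturalistic settings reduce to white noise", {
  flat <- generate_naturalistic(5000, 4, 4, spectrum_exponent = 0,
                                nongaussian_transform = "identity",
                                ar_coefficient = 0, seed = 4)
  x <- as.vector(flat)
  expect_gt(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value, 0.01)
  expect_lt(abs(stats::cor(as.vector(flat[, 1:3, ]), as.vector(flat[, 2:4, ]))),
            0.05)
})

test_that("surrogate conditional means are nonlinear, unlike Gaussian ensembles", {
  # the statistical signature the sequential-search bias analysis relies on:
  # <s | s1> along a random projection has a significant quadratic component
  set.seed(5)
  nat <- generate_naturalistic(4000, 6, 6, seed = 5)
  emb <- embed_spatiotemporal(nat, 1)
  u <- rnorm(36); u <- u / sqrt(sum(u^2))
  w <- rnorm(36); w <- w - u * sum(w * u); w <- w / sqrt(sum(w^2))
  x1 <- as.vector(project_stimuli(emb, u))
  x2 <- as.vector(project_stimuli(emb, w))
  fit <- stats::lm(x2 ~ x1 + I(x1^2))
  p_quad <- summary(fit)$coefficients["I(x1^2)", 4]
  expect_lt(p_quad, 0.01)

  gau <- generate_naturalistic(4000, 6, 6, seed = 5,
                               nongaussian_transform = "identity")
  embg <- embed_spatiotemporal(gau, 1)
  y1 <- as.vector(project_stimuli(embg, u))
  y2 <- as.vector(project_stimuli(embg, w))
  p_gau <- summary(stats::lm(y2 ~ y1 + I(y1^2)))$coefficients["I(y1^2)", 4]
  expect_gt(p_gau, 0.01)
})

test_that("spatiotemporal embedding follows the causal indexing convention", {
  fr <- array(c(5, 7, 9), dim = c(3, 1, 1))   # frames a, b, c
  emb <- embed_spatiotemporal(fr, 2)
  expect_equal(unclass(emb), matrix(c(5, 7, 7, 9), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)

  ens <- generate_white_noise(10, 3, 2, seed = 6)
  e1 <- embed_spatiotemporal(ens, 1)
  expect_equal(unclass(e1), matrix(ens, nrow = 10), ignore_attr = TRUE)

  e3 <- embed_spatiotemporal(generate_white_noise(8, 16, 16, seed = 1), 3)
  expect_equal(ncol(e3), 768)
  expect_equal(nrow(e3), 6)

  expect_error(embed_spatiotemporal(fr, 4), "at least")
})

test_that("embedding is lossless", {
  ens <- generate_white_noise(30, 4, 5, seed = 7)
  emb <- embed_spatiotemporal(ens, 3)
  expect_equal(unembed_frames(emb), unclass(ens), ignore_attr = TRUE)
})

test_that("jackknife partitions are contiguous, disjoint and exhaustive", {
  p <- jackknife_partitions(8, 4)
  expect_equal(p$blocks, list(1:2, 3:4, 5:6, 7:8), ignore_attr = TRUE)

  p10 <- jackknife_partitions(10, 4)
  expect_equal(sort(lengths(p10$blocks)), c(2, 2, 3, 3))
  expect_equal(sort(unlist(p10$blocks)), 1:10)
  expect_equal(sum(duplicated(unlist(p10$blocks))), 0)
  expect_equal(sort(c(training_rows(p10, 2), heldout_rows(p10, 2))), 1:10)

  for (N in c(4, 17, 101)) {
    pp <- jackknife_partitions(N, 4)
    expect_equal(sort(unlist(pp$blocks)), seq_len(N))
    expect_true(all(vapply(pp$blocks, function(b)
      all(diff(b) == 1), TRUE)))          # contiguous blocks
  }
  expect_error(jackknife_partitions(3, 4))
})

test_that("stimulus, spike and partition containers round-trip through files", {
  dir <- withr::local_tempdir()
  ens <- generate_naturalistic(40, 5, 4, seed = 8)
  pth <- file.path(dir, "stim.bin")
  write_stimuli(ens, pth)
  back <- read_stimuli(pth)
  expect_equal(unclass(back), unclass(ens), tolerance = 1e-6,
               ignore_attr = TRUE)                       # float32 storage
  expect_equal(attr(back, "kind"), "naturalistic")

  sp <- spike_response(rpois(40, 0.5))
  spth <- file.path(dir, "spikes.txt")
  write_spikes(sp, spth)
  expect_equal(as.numeric(read_spikes(spth)), as.numeric(sp))

  part <- jackknife_partitions(37, 4)
  ppth <- file.path(dir, "part.json")
  write_partition(part, ppth)
  expect_equal(read_partition(ppth)$blocks, part$blocks, ignore_attr = TRUE)

  cell <- make_model_cell(5, 4, 2, "divisive", gamma = 2, omega = 0.7)
  cpth <- file.path(dir, "cell.json")
  write_cell(cell, cpth)
  back_cell <- read_cell(cpth)
  expect_equal(back_cell$dimensions, cell$dimensions)
  expect_equal(back_cell$omega, 0.7)
})

test_that("spike responses validate counts and track the mean rate", {
  sp <- spike_response(c(0, 2, 1, 0))
  expect_equal(attr(sp, "mean_rate"), 0.75)
  expect_error(spike_response(c(-1, 0)))
  expect_error(spike_response(c(0.5, 1)))
})
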