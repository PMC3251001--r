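#' Fit maximally informative dimensions to stimuli and spikes
#'
#' Estimates the `K` relevant dimensions of a linear-nonlinear model by
#' maximizing the mutual information between stimulus projections and spikes,
#' with simulated annealing plus gradient ascent, under a contiguous
#' jackknife protocol: the fit is repeated on each training fold (all data
#' minus one held-out block), the fold estimates are aligned, and their
#' average is reported.
#'
#' Two search strategies are available.  `"sequential"` finds dimensions one
#' at a time, each maximizing the one-dimensional information restricted to
#' the orthogonal complement of all previously found dimensions, which are
#' never revised.  `"joint"` maximizes the `K`-dimensional information:
#' most iterations update the newest dimension, and every
#' `control$refresh_period`-th iteration also re-optimizes each earlier
#' dimension.  The first dimension is identical under both strategies.
#' Every dimension starts from the best of a small candidate set — the
#' fold's spike-triggered average, leading spike-triggered-covariance
#' eigenvectors, and a spike-eliciting stimulus frame — evaluated under the
#' objective (the covariance candidates matter for symmetric gain
#' functions, whose spike-triggered average is zero in expectation).
#'
#' @param x an `"embedded_stimuli"` matrix (see [embed_spatiotemporal()]),
#'   or a [stimulus_ensemble()] together with `n_lags`.
#' @param spikes per-frame spike counts aligned with the embedded rows.
#' @param K number of dimensions (1..3 for the histogram estimator).
#' @param mode `"joint"` or `"sequential"`.
#' @param n_lags embedding depth, only when `x` is a raw ensemble.
#' @param folds number of jackknife folds (default 4); `folds = 1` fits once
#'   on all data.
#' @param control a [mid_control()].
#' @param seed integer seed governing starting frames, annealing noise and
#'   perturbations.
#' @param first_dim optional list of per-fold unit vectors to use as the
#'   (already optimized) first dimension, e.g. to share it between a joint
#'   and a sequential fit, for which it is equivalent by construction.
#' @param allow_large_K override the `K <= 3` histogram-estimator limit.
#' @return An object of class `"mid"`; see [coef.mid()], [predict.mid()],
#'   [plot.mid()], [summary.mid()].
#' @examples
#' stim <- generate_white_noise(600, 4, 4, seed = 1)
#' cell <- ln_cell(cbind(unit_basis(48, 5)), "quadratic_1d", gamma = 0.5)
#' resp <- simulate_cell_response(cell, stim, seed = 2)
#' fit <- mid(resp$embedded, resp$spikes, K = 1, folds = 2,
#'            control = mid_control(iterations = 60))
#' abs(sum(coef(fit) * cell$dimensions))   # overlap with the true filter
#' @export
mid <- function(x, spikes, K = 1L, mode = c("joint", "sequential"),
                n_lags = NULL, folds = 4L, control = mid_control(),
                seed = 1L, first_dim = NULL, allow_large_K = FALSE) {
  mode <- match.arg(mode)
  if (inherits(x, "stimulus_ensemble")) {
    if (is.null(n_lags)) stop("supply `n_lags` to embed a raw ensemble")
    x <- embed_spatiotemporal(x, n_lags)
  }
  if (K < 1 || (K > 3 && !allow_large_K))
    stop("K must be 1..3 (histogram estimator); set `allow_large_K` to override")
  N <- nrow(x)
  if (length(spikes) != N) stop("spikes must align with embedded rows")
  if (sum(spikes) < folds) stop("too few spikes to fit")
  part <- jackknife_partitions(N, folds)
  geom <- list(H = attr(x, "H"), W = attr(x, "W"), n_lags = attr(x, "n_lags"))

  fold_fits <- vector("list", folds)
  for (f in seq_len(folds)) {
    rows <- if (folds == 1L) seq_len(N) else training_rows(part, f)
    S <- make_design(unclass(x)[rows, , drop = FALSE])
    sp <- as.numeric(spikes)[rows]
    if (sum(sp) == 0) stop(sprintf("fold %d has no spikes", f))
    rs <- local_rng(derive_seed(seed, "fold", f))  # mode-independent: the
    # first dimension is identical under joint and sequential search
    fit <- tryCatch(
      fit_fold(S, sp, K, mode, control,
               first_dim = if (is.null(first_dim)) NULL else first_dim[[f]]),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                               call. = FALSE))
    restore_rng(rs)
    fold_fits[[f]] <- fit
  }

  dims_fold <- lapply(fold_fits, `[[`, "dims")
  aligned <- align_fold_dimensions(dims_fold)
  avg <- orthonormalize(Reduce(`+`, aligned) / folds)

  obj <- structure(list(
    dimensions = avg,
    fold_dims = dims_fold,
    fold_dims_aligned = aligned,
    fold_info = vapply(fold_fits, `[[`, 0, "value"),
    traces = lapply(fold_fits, `[[`, "traces"),
    first_dims = lapply(fold_fits, function(z) z$dims[, 1]),
    mode = mode, K = as.integer(K), folds = as.integer(folds),
    partition = part, control = control, seed = seed, geometry = geom,
    n = N, n_spikes = sum(spikes),
    call = match.call()), class = "mid")

  # empirical gain on the full data with the averaged dimensions
  proj <- project_stimuli(x, avg)
  bd <- bin_distributions(proj, spikes, bins = control$eval_bins)
  obj$gain <- estimate_gain(bd)
  obj$binned <- bd
  obj$fitted <- gain_lookup(obj$gain, proj)
  obj$spikes <- as.numeric(spikes)
  obj
}

# Candidate starting points for one dimension: the spike-triggered average,
# the leading eigenvectors (by |eigenvalue|) of the spike-triggered
# covariance difference, and a randomly chosen spike-eliciting stimulus
# frame.  The STA is blind to symmetric gain functions, for which the
# covariance eigenvectors carry the subspace; candidates are projected off
# `earlier` and the one with the highest objective value wins.
informed_start <- function(S, sp, earlier, control, joint = FALSE,
                           n_eig = 4L) {
  n <- dnr(S); D <- dnc(S)
  sta <- spike_triggered_average(S, sp)
  dC <- gram_weighted(S, sp) / sum(sp) - gram(S) / n
  ev <- eigen(dC, symmetric = TRUE)
  keep <- order(abs(ev$values), decreasing = TRUE)[seq_len(n_eig)]
  cand <- cbind(sta, ev$vectors[, keep])
  spk <- which(sp > 0)
  cand <- cbind(cand, drow(S, spk[sample.int(length(spk), 1)]))
  others <- if (joint && !is.null(earlier)) mmat(S, earlier) else NULL
  best_v <- NULL; best_I <- -Inf
  for (j in seq_len(ncol(cand))) {
    v <- orth_complement(cand[, j], earlier)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) next
    v <- v / nv
    I <- .obj_value(mv(S, v), others, sp, control$bins_lo, control$objective)
    if (I > best_I) { best_I <- I; best_v <- v }
  }
  if (is.null(best_v)) stats::rnorm(D) else best_v
}

# fit all K dimensions on one training fold
fit_fold <- function(S, sp, K, mode, control, first_dim = NULL) {
  dims <- matrix(0, dnc(S), K)
  traces <- vector("list", K)
  if (is.null(first_dim)) {
    v0 <- informed_start(S, sp, NULL, control)
    a1 <- anneal_dimension(S, sp, v0, control = control)
    dims[, 1] <- a1$v
    traces[[1]] <- a1$trace
  } else {
    dims[, 1] <- first_dim
    traces[[1]] <- numeric(0)
  }
  value <- NA_real_
  if (K == 1 && is.null(first_dim)) value <- a1$value
  for (k in seq_len(K)[-1]) {
    earlier <- dims[, seq_len(k - 1), drop = FALSE]
    v0 <- informed_start(S, sp, earlier, control, joint = mode == "joint")
    ak <- anneal_dimension(S, sp, v0, earlier = earlier, mode = mode,
                           control = control)
    dims[, k] <- ak$v
    if (mode == "joint") dims[, seq_len(k - 1)] <- ak$earlier
    traces[[k]] <- ak$trace
    value <- ak$value
  }
  if (is.na(value))   # K = 1 with supplied first dimension: evaluate it
    value <- .obj_value(mv(S, dims[, 1]), NULL, sp,
                        control$eval_bins, control$objective)
  list(dims = dims, value = value, traces = traces)
}

# Gram-Schmidt orthonormal basis of the columns
orthonormalize <- function(M) {
  q <- qr.Q(qr(M))
  # fix QR sign indeterminacy: make diag(t(Q) %*% M) positive
  s <- sign(diag(crossprod(q, M)))
  s[s == 0] <- 1
  sweep(q[, seq_len(ncol(M)), drop = FALSE], 2, s, `*`)
}

# Align per-fold dimension sets to the first fold: orthonormalize each
# basis, then rotate within its span by orthogonal Procrustes.  Dimensions
# are identified only up to invertible recombination, so alignment acts on
# subspace bases, not raw vectors.
align_fold_dimensions <- function(dims_fold) {
  ref <- orthonormalize(dims_fold[[1]])
  lapply(dims_fold, function(Dm) {
    B <- orthonormalize(Dm)
    sv <- svd(crossprod(B, ref))
    B %*% (sv$u %*% t(sv$v))
  })
}

# piecewise-constant gain lookup; unoccupied bins fall back to the mean rate
gain_lookup <- function(gain, proj) {
  idx <- bin_indices(as.matrix(proj), gain$scheme)
  r <- gain$g[cell_ids(idx, gain$scheme$bins)]
  r[is.na(r)] <- gain$mean_rate
  r
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("Maximally informative dimensions (%s search)\n", x$mode))
  cat(sprintf("  K = %d, D = %d, N = %d frames, %d spikes, %d jackknife folds\n",
              x$K, nrow(x$dimensions), x$n, x$n_spikes, x$folds))
  cat(sprintf("  training information: %.4f +/- %.4f bits/spike\n",
              mean(x$fold_info), stats::sd(x$fold_info) / sqrt(x$folds)))
  invisible(x)
}

#' @export
summary.mid <- function(object, ...) {
  al <- object$fold_dims_aligned
  stab <- if (object$folds > 1) {
    # mean pairwise subspace overlap between fold estimates
    pairs <- utils::combn(object$folds, 2)
    mean(apply(pairs, 2, function(p)
      subspace_projection(al[[p[1]]], al[[p[2]]])$O))
  } else NA_real_
  out <- list(mode = object$mode, K = object$K, folds = object$folds,
              n = object$n, n_spikes = object$n_spikes,
              fold_info = object$fold_info,
              info_mean = mean(object$fold_info),
              info_se = stats::sd(object$fold_info) / sqrt(object$folds),
              fold_stability = stab,
              control = object$control)
  class(out) <- "summary.mid"
  out
}

#' @export
print.summary.mid <- function(x, ...) {
  cat(sprintf("MID fit, %s search, K = %d, %d folds\n", x$mode, x$K, x$folds))
  cat(sprintf("  data: %d frames, %d spikes\n", x$n, x$n_spikes))
  cat(sprintf("  information per fold (bits/spike): %s\n",
              paste(sprintf("%.4f", x$fold_info), collapse = ", ")))
  cat(sprintf("  mean %.4f +/- %.4f (SE)\n", x$info_mean, x$info_se))
  if (!is.na(x$fold_stability))
    cat(sprintf("  mean pairwise fold subspace overlap: %.3f\n",
                x$fold_stability))
  invisible(x)
}

#' Averaged relevant dimensions of a MID fit
#' @param object a `"mid"` fit.
#' @param ... unused.
#' @return `D x K` matrix with orthonormal columns (fold-aligned average).
#' @export
coef.mid <- function(object, ...) object$dimensions

#' Predict expected spike rate from a MID fit
#'
#' Projects new embedded stimuli onto the fitted dimensions and reads the
#' piecewise-constant empirical gain function; projections outside the
#' training range use the nearest edge bin, and unoccupied bins fall back to
#' the mean rate.
#'
#' @param object a `"mid"` fit.
#' @param newdata `N x D` embedded stimulus matrix; default the training data
#'   fit (returns fitted values).
#' @param ... unused.
#' @return Numeric vector of expected spikes per frame.
#' @export
predict.mid <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  gain_lookup(object$gain, project_stimuli(newdata, object$dimensions))
}

#' @export
residuals.mid <- function(object, ...) object$spikes - object$fitted

#' Simulate spike counts from a fitted MID model
#' @param object a `"mid"` fit.
#' @param nsim number of replicate spike trains.
#' @param seed integer seed.
#' @param newdata optional embedded stimuli (defaults to training data).
#' @param ... unused.
#' @return A list of `nsim` [spike_response()] vectors (a single response if
#'   `nsim = 1`).
#' @export
simulate.mid <- function(object, nsim = 1, seed = 1L, newdata = NULL, ...) {
  r <- predict(object, newdata)
  out <- lapply(seq_len(nsim), function(i)
    simulate_spikes(r, seed = derive_seed(seed, "sim", i), model = "poisson"))
  if (nsim == 1) out[[1]] else out
}

#' Display the fitted spatiotemporal filters
#'
#' One image panel per dimension and lag, pixels reshaped to the original
#' `H x W` grid (most recent lag rightmost).
#'
#' @param x a `"mid"` fit.
#' @param which dimensions to show (default all).
#' @param ... passed to [graphics::image()].
#' @export
plot.mid <- function(x, which = seq_len(x$K), ...) {
  g <- x$geometry
  if (is.null(g$H)) {
    graphics::matplot(x$dimensions[, which, drop = FALSE], type = "l",
                      lty = 1, xlab = "coefficient", ylab = "weight")
    return(invisible(x))
  }
  L <- g$n_lags; P <- g$H * g$W
  op <- graphics::par(mfrow = c(length(which), L), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "Blue-Red 2")
  for (k in which) {
    v <- x$dimensions[, k]
    zl <- max(abs(v)) * c(-1, 1)
    for (l in seq_len(L)) {
      m <- matrix(v[((l - 1) * P + 1):(l * P)], g$H, g$W)
      graphics::image(t(m)[, g$H:1], col = pal, zlim = zl, axes = FALSE,
                      main = sprintf("dim %d, lag %d", k, L - l), ...)
    }
  }
  invisible(x)
}

#' Unit basis vector
#' @param D length.
#' @param i index of the nonzero coordinate.
#' @return Length-`D` vector with 1 at position `i`.
#' @export
unit_basis <- function(D, i) { v <- numeric(D); v[i] <- 1; v }
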