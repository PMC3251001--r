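#' Subspace projection between model and reconstructed dimension sets
#'
#' The projected volume between the two spanned subspaces is
#' `|det P| / sqrt(det G_model * det G_recon)`, with `P` the matrix of
#' mutual inner products and `G` the Gram matrices; the linear overlap `O`
#' is its `K`-th root.  `O` ranges from 0 (orthogonal subspaces) to 1
#' (identical subspaces), equals the absolute cosine similarity for `K = 1`,
#' and is invariant to invertible recombination within either set.
#'
#' @param model_dims,recon_dims `D x K` matrices whose columns span the two
#'   subspaces (full column rank required; orthonormality not required).
#' @return Object of class `"subspace_overlap"`: list with `O`, `volume`
#'   (the projected volume), and `K`.
#' @export
subspace_projection <- function(model_dims, recon_dims) {
  M <- as.matrix(model_dims); R <- as.matrix(recon_dims)
  if (nrow(M) != nrow(R)) stop("dimension sets live in different spaces")
  if (ncol(M) != ncol(R)) stop("dimension sets must have equal K")
  K <- ncol(M)
  Gm <- crossprod(M); Gr <- crossprod(R)
  dm <- det(Gm); dr <- det(Gr)
  if (dm < 1e-20 || dr < 1e-20) stop("rank-deficient dimension set")
  P <- crossprod(M, R)
  vol <- abs(det(P)) / sqrt(dm * dr)
  vol <- min(vol, 1)           # guard rounding just above 1
  structure(list(O = vol^(1 / K), volume = vol, K = K),
            class = "subspace_overlap")
}

#' @export
print.subspace_overlap <- function(x, ...) {
  cat(sprintf("Subspace projection: O = %.4f (volume %.4f, K = %d)\n",
              x$O, x$volume, x$K))
  invisible(x)
}

#' Percent of the rate information captured by fitted dimensions
#'
#' Evaluates the `K`-dimensional binned information of each fold's
#' dimensions on that fold's held-out block (bins refit on the held-out
#' projections) and reports it as a percentage of the model cell's
#' rate-based information per spike (`i_spike`, the data-processing bound).
#' Estimator noise can push individual folds slightly above 100%; values
#' are reported as computed, not clamped.
#'
#' @param fit a `"mid"` fit (per-fold dimensions and partition are taken
#'   from it), or a `D x K` matrix to evaluate as-is on `heldout_rows_list`.
#' @param embedded full `N x D` embedded stimulus matrix.
#' @param spikes full aligned spike counts.
#' @param i_spike rate-based information per spike in bits (see
#'   [info_per_spike()]).
#' @param bins evaluation bin count (default 11).
#' @return List with `percent` (jackknife mean), `per_fold`, `se`.
#' @export
percent_info_explained <- function(fit, embedded, spikes, i_spike,
                                   bins = 11L) {
  if (i_spike <= 0) stop("`i_spike` must be positive")
  spikes <- as.numeric(spikes)
  if (inherits(fit, "mid")) {
    folds <- fit$folds
    pf <- vapply(seq_len(folds), function(f) {
      rows <- heldout_rows(fit$partition, f)
      if (sum(spikes[rows]) == 0) stop("held-out block has no spikes")
      proj <- project_stimuli(unclass(embedded)[rows, , drop = FALSE],
                              fit$fold_dims[[f]])
      bd <- bin_distributions(proj, spikes[rows], bins = bins)
      100 * mutual_information(bd) / i_spike
    }, 0)
    list(percent = mean(pf), per_fold = pf,
         se = stats::sd(pf) / sqrt(folds))
  } else {
    proj <- project_stimuli(embedded, fit)
    bd <- bin_distributions(proj, spikes, bins = bins)
    p <- 100 * mutual_information(bd) / i_spike
    list(percent = p, per_fold = p, se = NA_real_)
  }
}

#' Per-coefficient signal-to-noise map across jackknife estimates
#'
#' For every filter coefficient, `|mean across folds| / SD across folds`,
#' computed on fold estimates that have already been aligned (sign and
#' within-subspace rotation).  Coefficients with zero across-fold SD are
#' flagged as saturated (`Inf`).
#'
#' @param fold_estimates list of aligned `D x K` matrices (>= 2), or a
#'   `"mid"` fit (its aligned fold dimensions are used).
#' @return `D x K` matrix of SNR values.
#' @export
snr_map <- function(fold_estimates) {
  if (inherits(fold_estimates, "mid"))
    fold_estimates <- fold_estimates$fold_dims_aligned
  if (length(fold_estimates) < 2) stop("need at least two fold estimates")
  arr <- simplify2array(fold_estimates)        # D x K x folds
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  snr <- abs(m) / s
  snr[s == 0] <- Inf
  snr
}

#' Convergence of joint and sequential search with the number of spikes
#'
#' Runs the spike-budget experiment on the quadratic family of model cells:
#' for each `K` in `cell_K` (1 = quadratic, 2 = divisive with zero
#' suppression, 3 = divisive), the firing rate is scaled so the expected
#' spike count hits each budget, spikes are drawn from a Poisson generator,
#' and both search modes are fitted with several random seeds.  Results are
#' tabulated against `K * D / N_spikes`, the sampling ratio that joint
#' convergence curves collapse onto.
#'
#' @param embedded `N x D` embedded stimulus matrix (typically from the
#'   naturalistic surrogate).
#' @param cells named list of calibrated [ln_cell()] objects indexed by
#'   `K` (see [make_model_cell()]); only entries in `cell_K` are used.
#' @param spike_budgets vector of expected total spike counts.
#' @param cell_K which model-cell sizes to run (subset of 1:3).
#' @param seeds random seeds (the reference protocol uses eight).
#' @param modes search modes to run.
#' @param control a [mid_control()].
#' @param folds jackknife folds per fit (1 = single fit, the default here:
#'   seed replication already provides the error estimate).
#' @return Data frame with columns `K`, `D`, `n_spikes`, `budget`, `ratio`,
#'   `mode`, `seed`, `O`, `info`.
#' @export
convergence_experiment <- function(embedded, cells, spike_budgets,
                                   cell_K = c(1, 2, 3), seeds = 1:8,
                                   modes = c("joint", "sequential"),
                                   control = mid_control(), folds = 1L) {
  if (any(spike_budgets < 1)) stop("spike budgets must be at least one spike")
  N <- nrow(embedded); D <- ncol(embedded)
  rows <- list()
  for (K in cell_K) {
    cell <- cells[[as.character(K)]]
    truth <- cell$dimensions[, seq_len(K), drop = FALSE]
    proj <- cell_projections(cell, embedded)
    base <- expected_rate(cell, proj)
    for (budget in spike_budgets) {
      rates <- base * (budget / sum(base))   # scale gamma to hit the budget
      for (sd_i in seeds) {
        spikes <- simulate_spikes(rates, seed = derive_seed(sd_i, K, budget),
                                  model = "poisson")
        if (sum(spikes) == 0) next
        first <- NULL
        for (mode in modes) {
          fit <- mid(structure(embedded, class = c("embedded_stimuli",
                                                   "matrix", "array")),
                     spikes, K = K, mode = mode, folds = folds,
                     control = control, seed = derive_seed(sd_i, K, budget, 9),
                     first_dim = first)
          if (is.null(first)) first <- fit$first_dims  # share dim 1 across modes
          O <- subspace_projection(truth, fit$dimensions)$O
          rows[[length(rows) + 1]] <- data.frame(
            K = K, D = D, n_spikes = sum(spikes), budget = budget,
            ratio = K * D / sum(spikes), mode = mode, seed = sd_i, O = O,
            info = mean(fit$fold_info))
        }
      }
    }
  }
  do.call(rbind, rows)
}
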