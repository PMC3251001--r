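#' Run a packaged model-cell experiment end to end
#'
#' Reproduction drivers for the model-cell studies: each experiment
#' generates its stimulus ensemble, builds the corresponding model cell,
#' simulates spikes, runs the designated fits under the jackknife protocol,
#' and reports subspace overlap, percent information explained, and SNR
#' summaries with jackknife errors.
#'
#' \describe{
#'   \item{`fig1_noise`}{2D OR-threshold Gabor cell on white noise;
#'     sequential and joint 2D fits.}
#'   \item{`fig1_natural`}{same cell on the naturalistic surrogate (used
#'     when no external movie is supplied).}
#'   \item{`fig2_joint3d`}{3D divisive cell on the naturalistic surrogate;
#'     joint 3D fit.}
#'   \item{`fig3_ppr`}{same data as `fig2_joint3d`; PPR baseline vs joint.}
#'   \item{`fig4_convergence`}{spike-budget convergence study over
#'     `K = 1, 2, 3` cells.}
#' }
#'
#' @param name experiment name (see Details).
#' @param T,H,W,n_lags stimulus geometry (defaults 20000 frames, 16 x 16,
#'   3 lags).
#' @param seed master seed; all randomness derives from it.
#' @param control a [mid_control()].
#' @param ensemble optional externally supplied [stimulus_ensemble()] for
#'   the `*_natural` variants; when absent the naturalistic surrogate is
#'   generated (with a notice, since the original movies are external).
#' @param spike_budgets,conv_seeds,conv_K settings for `fig4_convergence`.
#' @param out_dir optional directory: results are written as CSV plus a JSON
#'   run manifest.
#' @return A list of class `"mid_experiment"` with a `results` data frame,
#'   the fits, and the manifest.
#' @export
run_figure_experiment <- function(name = c("fig1_noise", "fig1_natural",
                                           "fig2_joint3d", "fig3_ppr",
                                           "fig4_convergence"),
                                  T = 20000, H = 16, W = 16, n_lags = 3,
                                  seed = 1L, control = mid_control(),
                                  ensemble = NULL,
                                  spike_budgets = NULL, conv_seeds = 1:8,
                                  conv_K = c(1, 2, 3), out_dir = NULL) {
  name <- match.arg(name)
  t0 <- Sys.time()
  natural <- name != "fig1_noise"
  if (natural && is.null(ensemble)) {
    if (name %in% c("fig1_natural"))
      message("No external movie supplied; using the naturalistic surrogate ",
              "ensemble in its place.")
    ensemble <- generate_naturalistic(T, H, W,
                                      seed = derive_seed(seed, "stim"))
  } else if (!natural) {
    ensemble <- generate_white_noise(T, H, W, seed = derive_seed(seed, "stim"))
  }
  emb <- embed_spatiotemporal(ensemble, n_lags)
  D <- ncol(emb)

  out <- switch(name,
    fig1_noise = ,
    fig1_natural = {
      cell <- make_model_cell(H, W, n_lags, "or_threshold")
      resp <- simulate_cell_response(cell, ensemble,
                                     seed = derive_seed(seed, "spikes"))
      ispk <- info_per_spike(resp$rates)
      fit_seq <- mid(emb, resp$spikes, K = 2, mode = "sequential",
                     control = control, seed = seed)
      fit_joint <- mid(emb, resp$spikes, K = 2, mode = "joint",
                       control = control, seed = seed,
                       first_dim = fit_seq$first_dims)
      res <- rbind(
        experiment_row(name, "sequential", resp$cell, fit_seq, emb,
                       resp$spikes, ispk),
        experiment_row(name, "joint", resp$cell, fit_joint, emb,
                       resp$spikes, ispk))
      list(results = res, fits = list(sequential = fit_seq,
                                      joint = fit_joint),
           cell = resp$cell, i_spike = ispk)
    },
    fig2_joint3d = ,
    fig3_ppr = {
      cell <- make_model_cell(H, W, n_lags, "divisive")
      cell <- calibrate_gain(cell, emb)
      resp <- simulate_cell_response(cell, ensemble,
                                     seed = derive_seed(seed, "spikes"))
      ispk <- info_per_spike(resp$rates)
      fit_joint <- mid(emb, resp$spikes, K = 3, mode = "joint",
                       control = control, seed = seed)
      res <- experiment_row(name, "joint", cell, fit_joint, emb,
                            resp$spikes, ispk)
      fits <- list(joint = fit_joint)
      if (name == "fig3_ppr") {
        fit_p <- fit_ppr(emb, resp$spikes, K = 3,
                         seed = derive_seed(seed, "ppr"))
        Op <- subspace_projection(cell$dimensions, fit_p$dimensions)$O
        pinf <- percent_info_explained(fit_p$dimensions, emb, resp$spikes,
                                       ispk)$percent
        res <- rbind(res, data.frame(experiment = name, mode = "ppr",
                                     K = 3, D = D, n_spikes = sum(resp$spikes),
                                     O = Op, O_se = NA_real_,
                                     pct_info = pinf, pct_info_se = NA_real_))
        fits$ppr <- fit_p
      }
      list(results = res, fits = fits, cell = cell, i_spike = ispk)
    },
    fig4_convergence = {
      if (is.null(spike_budgets)) spike_budgets <- D * c(0.5, 1, 2, 4)
      cells <- list(
        "1" = make_model_cell(H, W, n_lags, "quadratic_1d"),
        # 2D cell: divisive form with zero suppression (rate depends only on
        # the first two dimensions; the inert third is dropped for scoring)
        "2" = make_model_cell(H, W, n_lags, "divisive", omega = 0),
        "3" = calibrate_gain(make_model_cell(H, W, n_lags, "divisive"), emb))
      tab <- convergence_experiment(emb, cells, spike_budgets,
                                    cell_K = conv_K, seeds = conv_seeds,
                                    control = control)
      list(results = tab, fits = NULL, cell = cells, i_spike = NA_real_)
    })

  manifest <- list(command = name, seed = seed,
                   config = unclass(control),
                   geometry = list(T = T, H = H, W = W, n_lags = n_lags,
                                   D = D),
                   ensemble_kind = attr(ensemble, "kind"),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  out$manifest <- manifest
  out$name <- name
  class(out) <- "mid_experiment"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$results,
                     file.path(out_dir, paste0(name, "_results.csv")),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(name, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# one summary row: overlap with truth and held-out percent information
experiment_row <- function(name, mode, cell, fit, emb, spikes, ispk) {
  Of <- vapply(fit$fold_dims, function(dm)
    subspace_projection(cell$dimensions, dm)$O, 0)
  pi <- percent_info_explained(fit, emb, spikes, ispk)
  data.frame(experiment = name, mode = mode, K = fit$K,
             D = nrow(fit$dimensions), n_spikes = fit$n_spikes,
             O = mean(Of), O_se = stats::sd(Of) / sqrt(length(Of)),
             pct_info = pi$percent, pct_info_se = pi$se)
}

#' @export
print.mid_experiment <- function(x, ...) {
  cat(sprintf("Experiment %s (%s ensemble)\n", x$name,
              x$manifest$ensemble_kind))
  print(x$results, row.names = FALSE)
  invisible(x)
}
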