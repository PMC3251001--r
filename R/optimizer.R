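#' Optimizer control parameters
#'
#' Defaults follow the reference protocol: 1200 iterations per dimension
#' with the bin count stepping 6 -> 11 in six equal stages (every 200
#' iterations at the default length), temperature cooling by 0.95 per
#' iteration, previously found dimensions refreshed every 100th iteration
#' during joint optimization, and a 4-fold jackknife.
#'
#' @param iterations line-search iterations per dimension.
#' @param bins_lo,bins_hi bin-count schedule endpoints (6 and 11).
#' @param cooling multiplicative temperature decay per iteration, in (0,1).
#' @param refresh_period joint mode: earlier dimensions get one update step
#'   every this many iterations.
#' @param conv_tol,conv_steps convergence is declared after `conv_steps`
#'   consecutive proposals changing the objective by less than `conv_tol`
#'   bits; the temperature is then reheated and the point perturbed.
#' @param stall_steps a restart is also triggered when the best objective
#'   seen has not improved by `conv_tol` for this many iterations (escape
#'   from flat or spurious ridges).
#' @param reheat_factor temperature multiplier on reheat.
#' @param perturb_scale size of the random perturbation on reheat, relative
#'   to the (unit) current dimension.
#' @param line_evals objective evaluations per golden-section line search.
#' @param t0_steps greedy steps used to estimate the initial temperature
#'   (set so the median early |dI| is accepted downhill ~50% of the time).
#' @param objective `"kl"` (mutual information) or `"renyi2"`.
#' @param eval_bins bin count for final/held-out evaluation (11).
#' @return List of class `"mid_control"`.
#' @export
mid_control <- function(iterations = 1200L, bins_lo = 6L, bins_hi = 11L,
                        cooling = 0.95, refresh_period = 100L,
                        conv_tol = 1e-5, conv_steps = 10L, stall_steps = 40L,
                        reheat_factor = 100, perturb_scale = 0.5,
                        line_evals = 12L, t0_steps = 10L,
                        objective = c("kl", "renyi2"), eval_bins = 11L) {
  stopifnot(iterations >= 1, bins_lo >= 2, bins_hi >= bins_lo,
            cooling > 0, cooling < 1, refresh_period >= 1)
  objective <- match.arg(objective)
  structure(list(iterations = as.integer(iterations),
                 bins_lo = as.integer(bins_lo), bins_hi = as.integer(bins_hi),
                 cooling = cooling, refresh_period = as.integer(refresh_period),
                 conv_tol = conv_tol, conv_steps = as.integer(conv_steps),
                 stall_steps = as.integer(stall_steps),
                 reheat_factor = reheat_factor, perturb_scale = perturb_scale,
                 line_evals = as.integer(line_evals),
                 t0_steps = as.integer(t0_steps),
                 objective = objective, eval_bins = as.integer(eval_bins)),
            class = "mid_control")
}

# bin count at iteration `it` of `total`: bins_lo..bins_hi in equal stages
bin_schedule <- function(it, total, bins_lo, bins_hi) {
  levels <- bins_hi - bins_lo + 1L
  period <- ceiling(total / levels)
  min(bins_lo + (it - 1L) %/% period, bins_hi)
}

# objective of candidate projections (others | pv), freshly binned
.obj_value <- function(pv, others, spikes, B, objective) {
  proj <- if (is.null(others)) cbind(pv) else cbind(others, pv)
  bd <- bin_distributions(proj, spikes, bins = B)
  if (objective == "kl") mutual_information(bd) else renyi2_divergence(bd)
}

# golden-section maximization of f over [0, hi] with n evaluations;
# returns list(t, value) of the best point seen (t = 0 excluded).
golden_line_max <- function(f, hi, n) {
  gr <- (sqrt(5) - 1) / 2
  a <- 0; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  best_t <- if (f1 >= f2) x1 else x2
  best_f <- max(f1, f2)
  for (i in seq_len(max(0L, n - 2L))) {
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
      if (f1 > best_f) { best_f <- f1; best_t <- x1 }
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
      if (f2 > best_f) { best_f <- f2; best_t <- x2 }
    }
  }
  list(t = best_t, value = best_f)
}

# project v onto the orthogonal complement of the (orthonormal) columns of C
orth_complement <- function(v, C) {
  if (is.null(C) || ncol(C) == 0) return(v)
  v - C %*% crossprod(C, v)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-14) stop("cannot normalize a zero vector")
  v / n
}

# one greedy gradient + line-search step on a single dimension, holding the
# projections in `others` fixed; returns the (possibly unchanged) dimension
greedy_step_dim <- function(S, spikes, v, pv, others, B, control,
                            step0 = 0.5) {
  proj <- if (is.null(others)) cbind(pv) else cbind(others, pv)
  scheme <- binning_scheme(proj, B)
  a <- gradient_frame_weights(proj, spikes, scheme, ncol(proj))
  g <- cv(S, a)
  g <- g - sum(g * v) * v
  gn <- sqrt(sum(g^2))
  if (gn < 1e-14) return(list(v = v, pv = pv, improved = FALSE))
  d <- g / gn
  pd <- mv(S, d)
  I0 <- .obj_value(pv, others, spikes, B, control$objective)
  phi <- function(t) .obj_value((pv + t * pd) / sqrt(1 + t^2), others,
                                spikes, B, control$objective)
  ls <- golden_line_max(phi, max(2 * step0, 0.25), control$line_evals)
  if (ls$value > I0) {
    nm <- sqrt(1 + ls$t^2)
    list(v = unit((v + ls$t * d) / nm), pv = (pv + ls$t * pd) / nm,
         improved = TRUE)
  } else list(v = v, pv = pv, improved = FALSE)
}

#' Anneal one dimension of the information objective
#'
#' The inner engine shared by all fits: simulated annealing plus gradient
#' ascent with golden-section line searches.  Uphill moves are always
#' accepted; downhill moves with probability `exp(dI / T)`; `T` cools by
#' `cooling` each iteration and, on convergence, is reheated while the
#' point is perturbed by a large random step.
#'
#' Three modes share this engine.  With `earlier = NULL` it fits the first
#' dimension against the one-dimensional objective.  In `"sequential"` mode
#' the new dimension still faces the one-dimensional objective, but both the
#' gradient and every trial point are projected onto the orthogonal
#' complement of `earlier`, which is never revised.  In `"joint"` mode the
#' candidate is the last column of the full projection set, the
#' multidimensional objective is maximised, and every `refresh_period`
#' iterations each earlier dimension receives one greedy update step.
#'
#' @param S `N x D` training stimulus matrix.
#' @param spikes aligned spike counts.
#' @param v0 starting dimension (need not be normalised).
#' @param earlier `D x m` matrix of previously found dimensions or `NULL`.
#' @param mode `"sequential"` or `"joint"` (ignored when `earlier` is NULL).
#' @param control a [mid_control()].
#' @param iterations override of `control$iterations`.
#' @return List with `v` (best unit dimension), `earlier` (possibly revised
#'   in joint mode), `value` (objective at the final bin count), `trace`
#'   (objective per iteration) and `accepted` (number of accepted moves).
#' @keywords internal
anneal_dimension <- function(S, spikes, v0, earlier = NULL,
                             mode = c("sequential", "joint"),
                             control = mid_control(), iterations = NULL) {
  mode <- match.arg(mode)
  total <- if (is.null(iterations)) control$iterations else as.integer(iterations)
  obj <- control$objective
  joint <- !is.null(earlier) && mode == "joint"
  constraint <- if (!is.null(earlier) && mode == "sequential") earlier else NULL
  others <- if (joint) mmat(S, earlier) else NULL

  v <- unit(orth_complement(v0, if (is.null(earlier)) NULL else earlier))
  pv <- mv(S, v)
  Tcur <- NA_real_               # greedy until estimated from early steps
  dI_hist <- numeric(0)
  step_prev <- 1
  conv_count <- 0L
  since_best <- 0L          # iterations without the chain improving itself
  restart_fails <- 0L
  chain_best <- -Inf        # best point since the last restart
  trace <- numeric(total)
  accepted <- 0L
  B_cur <- -1L
  I_cur <- NA_real_
  v_best <- v; pv_best <- pv; I_best <- -Inf
  earlier_best <- earlier; others_best <- others

  for (it in seq_len(total)) {
    B <- bin_schedule(it, total, control$bins_lo, control$bins_hi)
    if (B != B_cur) {
      # re-anchor objective values at the new binning and restart the chain
      # from the better of the current and the best-so-far point, so an
      # excursion late in a stage cannot discard the climb
      B_cur <- B
      I_cur <- .obj_value(pv, others, spikes, B, obj)
      I_best <- .obj_value(pv_best, others_best, spikes, B, obj)
      if (I_best > I_cur) {
        v <- v_best; pv <- pv_best
        if (joint) { earlier <- earlier_best; others <- others_best }
        I_cur <- I_best
      } else {
        v_best <- v; pv_best <- pv
        earlier_best <- earlier; others_best <- others
        I_best <- I_cur
      }
      chain_best <- I_cur
    }

    if (joint && it %% control$refresh_period == 0L) {
      for (j in seq_len(ncol(earlier))) {
        oth_j <- cbind(others[, -j, drop = FALSE], pv)
        st <- greedy_step_dim(S, spikes, earlier[, j], others[, j], oth_j,
                              B, control, step0 = step_prev)
        if (st$improved) {
          earlier[, j] <- st$v
          others[, j] <- st$pv
        }
      }
      I_cur <- .obj_value(pv, others, spikes, B, obj)
    }

    proj <- if (is.null(others)) cbind(pv) else cbind(others, pv)
    scheme <- binning_scheme(proj, B)
    a <- gradient_frame_weights(proj, spikes, scheme, ncol(proj))
    g <- cv(S, a)
    g <- g - sum(g * v) * v    # scale direction is flat: remove it
    g <- orth_complement(g, constraint)
    gn <- sqrt(sum(g^2))
    dI <- 0

    if (gn > 1e-14) {
      d <- g / gn
      pd <- mv(S, d)
      phi <- function(t) {
        nm <- sqrt(1 + t^2)
        .obj_value((pv + t * pd) / nm, others, spikes, B, obj)
      }
      # bracket follows the accepted step size but never collapses: a floor
      # keeps macroscopic moves reachable when the landscape is locally flat
      ls <- golden_line_max(phi, max(2 * step_prev, 0.25), control$line_evals)
      dI <- ls$value - I_cur
      accept <- dI >= 0 ||
        (!is.na(Tcur) && Tcur > 0 && stats::runif(1) < exp(dI / Tcur))
      if (length(dI_hist) < control$t0_steps) {
        dI_hist <- c(dI_hist, abs(dI))
        if (length(dI_hist) == control$t0_steps)
          Tcur <- max(stats::median(dI_hist), 1e-9) / log(2)
      }
      if (accept) {
        nm <- sqrt(1 + ls$t^2)
        v <- unit(orth_complement((v + ls$t * d) / nm, constraint))
        pv <- (pv + ls$t * pd) / nm
        I_cur <- ls$value
        step_prev <- max(ls$t, 0.05)
        accepted <- accepted + 1L
      }
      if (I_cur > chain_best + control$conv_tol) { since_best <- 0L
                                                   restart_fails <- 0L }
      if (I_cur > chain_best) chain_best <- I_cur
      if (I_cur > I_best) {
        I_best <- I_cur; v_best <- v; pv_best <- pv
        earlier_best <- earlier; others_best <- others
      }
    }
    if (!is.finite(I_cur)) stop("objective became non-finite during annealing")

    if (!is.na(Tcur)) Tcur <- Tcur * control$cooling
    trace[it] <- I_cur
    since_best <- since_best + 1L

    # converged on a (possibly local) maximum, or stalled without improving
    # the best point: reheat and perturb the optimal point by a large step,
    # letting the gradient carry the chain to another, possibly better
    # maximum; the best point itself is retained
    conv_count <- if (abs(dI) < control$conv_tol) conv_count + 1L else 0L
    if ((conv_count >= control$conv_steps ||
         since_best >= control$stall_steps) && it < total) {
      if (!is.na(Tcur)) Tcur <- Tcur * control$reheat_factor
      # escalate the perturbation while restarts keep failing to improve the
      # best point: local step, then a large step, then a fresh random
      # direction, cycling
      pert <- stats::rnorm(length(v))
      v <- switch((restart_fails %% 3L) + 1L,
                  unit(v_best + control$perturb_scale * unit(pert)),
                  unit(v_best + 4 * control$perturb_scale * unit(pert)),
                  unit(pert))
      v <- unit(orth_complement(v, constraint))
      pv <- mv(S, v)
      I_cur <- .obj_value(pv, others, spikes, B, obj)
      restart_fails <- restart_fails + 1L
      conv_count <- 0L
      since_best <- 0L
      chain_best <- I_cur   # patience restarts with the new chain
    }
  }
  list(v = v_best, earlier = earlier_best, value = I_best, trace = trace,
       accepted = accepted)
}

# spike-triggered average of a training fold, as a starting point
spike_triggered_average <- function(S, spikes) {
  cv(S, as.numeric(spikes)) / sum(spikes)
}
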