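#' Minimal projection pursuit regression baseline
#'
#' Fits the additive ridge model `r(s) ~ rbar + sum_k f_k(s . v_k)` by
#' sequential least squares: each term is fitted to the residual between the
#' spike counts and the prediction of all previous terms, alternating (a)
#' re-estimation of the ridge function `f` by bin averages of the residual
#' against the current projection and (b) a gradient line-search step on the
#' dimension `v` that reduces the squared error `chi^2`.  One forward pass
#' is followed by optional back-fitting sweeps.  This is the core sequential
#' least-squares method; no multi-resolution refinement or term deletion is
#' performed.
#'
#' @param embedded `N x D` embedded stimulus matrix.
#' @param spikes aligned per-frame spike counts.
#' @param K number of ridge terms (<= 3).
#' @param ridge_bins equal-width bins for the piecewise-constant ridge
#'   functions (default 15).
#' @param max_alternations alternation limit per term.
#' @param tol relative `chi^2` improvement below which a term stops.
#' @param backfit_passes additional sweeps re-fitting each term against the
#'   residual of all the others (default 1).
#' @param line_evals golden-section evaluations per dimension step.
#' @param seed seed for the random starting dimensions.
#' @return Object of class `"mid_ppr"`: list with `dimensions` (`D x K`,
#'   unit columns), `ridges` (per-term bin values and edges), `intercept`
#'   (mean rate), `chi2_trace`, `fitted`.
#' @export
fit_ppr <- function(embedded, spikes, K = 1L, ridge_bins = 15L,
                    max_alternations = 20L, tol = 1e-6, backfit_passes = 1L,
                    line_evals = 12L, seed = 1L) {
  if (K > 3) stop("K is limited to 3")
  S <- unclass(embedded)
  y <- as.numeric(spikes)
  N <- nrow(S); D <- ncol(S)
  rbar <- mean(y)
  rs <- local_rng(derive_seed(seed, "ppr"))
  on.exit(restore_rng(rs))

  dims <- matrix(0, D, K)
  ridges <- vector("list", K)
  contrib <- matrix(0, N, K)         # fitted ridge values per term
  chi2_trace <- numeric(0)
  resid0 <- y - rbar

  for (k in seq_len(K)) {
    res <- resid0 - if (k > 1) rowSums(contrib[, seq_len(k - 1), drop = FALSE]) else 0
    tm <- fit_ppr_term(S, res, ridge_bins = ridge_bins,
                       max_alternations = max_alternations, tol = tol,
                       line_evals = line_evals)
    dims[, k] <- tm$dimension
    ridges[[k]] <- tm$ridge
    contrib[, k] <- tm$fitted
    chi2_trace <- c(chi2_trace, tm$chi2_trace)
  }
  for (pass in seq_len(backfit_passes)) {
    for (k in seq_len(K)) {
      res <- resid0 - rowSums(contrib[, -k, drop = FALSE])
      tm <- fit_ppr_term(S, res, v0 = dims[, k], ridge_bins = ridge_bins,
                         max_alternations = max_alternations, tol = tol,
                         line_evals = line_evals)
      dims[, k] <- tm$dimension
      ridges[[k]] <- tm$ridge
      contrib[, k] <- tm$fitted
      chi2_trace <- c(chi2_trace, tm$chi2_trace)
    }
  }
  structure(list(dimensions = dims, ridges = ridges, intercept = rbar,
                 chi2_trace = chi2_trace,
                 fitted = rbar + rowSums(contrib), K = K,
                 ridge_bins = ridge_bins),
            class = "mid_ppr")
}

#' Fit a single PPR ridge term to residual rates
#'
#' Alternates ridge re-estimation (bin means of the residual over
#' equal-width projection bins) with a golden-section line search along the
#' `chi^2` gradient `-2 sum_i (res_i - f(x_i)) f'(x_i) s_i`, where `f'` is a
#' finite-difference derivative of the binned ridge.  `chi^2` is
#' non-increasing across alternations by construction.
#'
#' @param embedded `N x D` stimulus matrix.
#' @param residual_rates residual to describe (must not be constant).
#' @param v0 optional starting dimension (default: a random unit vector).
#' @inheritParams fit_ppr
#' @return List with `dimension` (unit vector), `ridge` (list of `values`,
#'   `edges`), `fitted`, `chi2_trace`.
#' @export
fit_ppr_term <- function(embedded, residual_rates, v0 = NULL,
                         ridge_bins = 15L, max_alternations = 20L,
                         tol = 1e-6, line_evals = 12L) {
  S <- unclass(embedded)
  res <- as.numeric(residual_rates)
  if (stats::sd(res) < 1e-14) stop("residual is constant; nothing to fit")
  v <- if (is.null(v0)) stats::rnorm(ncol(S)) else v0
  v <- unit(v)
  pv <- as.vector(S %*% v)
  chi2 <- function(fv) sum((res - fv)^2)
  ridge <- ridge_fit(pv, res, ridge_bins)
  fv <- ridge_eval(ridge, pv)
  c2 <- chi2(fv)
  trace <- c2
  step_prev <- 0.5

  for (alt in seq_len(max_alternations)) {
    # gradient step on the dimension
    fp <- ridge_slope(ridge, pv)
    g <- as.vector(crossprod(S, -2 * (res - fv) * fp))
    g <- g - sum(g * v) * v
    gn <- sqrt(sum(g^2))
    if (gn > 1e-14) {
      d <- -g / gn                      # descend chi^2
      pd <- as.vector(S %*% d)
      phi <- function(t) {
        x <- (pv + t * pd) / sqrt(1 + t^2)
        rg <- ridge_fit(x, res, ridge_bins)
        -chi2(ridge_eval(rg, x))
      }
      ls <- golden_line_max(phi, 2 * step_prev, line_evals)
      if (-ls$value < c2) {
        nm <- sqrt(1 + ls$t^2)
        v <- unit((v + ls$t * d) / nm)
        pv <- (pv + ls$t * pd) / nm
        step_prev <- max(ls$t, 1e-4)
      }
    }
    ridge <- ridge_fit(pv, res, ridge_bins)
    fv <- ridge_eval(ridge, pv)
    c2_new <- chi2(fv)
    trace <- c(trace, c2_new)
    if (c2 - c2_new < tol * max(c2, 1e-12)) { c2 <- c2_new; break }
    c2 <- c2_new
  }
  list(dimension = v, ridge = ridge, fitted = fv, chi2_trace = trace)
}

# piecewise-constant ridge: bin means of res over equal-width bins of x
ridge_fit <- function(x, res, bins) {
  r <- range(x)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  edges <- seq(r[1], r[2], length.out = bins + 1)
  idx <- pmin.int(pmax.int(findInterval(x, edges, rightmost.closed = TRUE),
                           1L), bins)
  vals <- rep(0, bins)
  agg <- rowsum(res, idx)
  cnt <- tabulate(idx, bins)
  occ <- as.integer(rownames(agg))
  vals[occ] <- agg[, 1] / cnt[occ]
  list(values = vals, edges = edges)
}

ridge_eval <- function(ridge, x) {
  bins <- length(ridge$values)
  idx <- pmin.int(pmax.int(findInterval(x, ridge$edges,
                                        rightmost.closed = TRUE), 1L), bins)
  ridge$values[idx]
}

# finite-difference slope of the binned ridge at each point
ridge_slope <- function(ridge, x) {
  vals <- ridge$values
  B <- length(vals)
  h <- ridge$edges[2] - ridge$edges[1]
  sl <- numeric(B)
  if (B >= 3) sl[2:(B - 1)] <- (vals[3:B] - vals[1:(B - 2)]) / (2 * h)
  sl[1] <- (vals[2] - vals[1]) / h
  sl[B] <- (vals[B] - vals[B - 1]) / h
  idx <- pmin.int(pmax.int(findInterval(x, ridge$edges,
                                        rightmost.closed = TRUE), 1L), B)
  sl[idx]
}

#' @export
print.mid_ppr <- function(x, ...) {
  cat(sprintf("Projection pursuit regression: %d ridge terms, D = %d\n",
              x$K, nrow(x$dimensions)))
  cat(sprintf("  intercept (mean rate) %.4f, final chi^2 %.4f\n",
              x$intercept, utils::tail(x$chi2_trace, 1)))
  invisible(x)
}

#' @export
coef.mid_ppr <- function(object, ...) object$dimensions

#' Predict rates from a fitted PPR model
#' @param object a `"mid_ppr"` fit.
#' @param newdata optional `N x D` embedded stimuli.
#' @param ... unused.
#' @return Expected spikes per frame (intercept plus the ridge terms).
#' @export
predict.mid_ppr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  S <- unclass(newdata)
  p <- object$intercept
  for (k in seq_len(object$K))
    p <- p + ridge_eval(object$ridges[[k]],
                        as.vector(S %*% object$dimensions[, k]))
  p
}
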