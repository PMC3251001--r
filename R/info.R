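#' Project embedded stimuli onto candidate dimensions
#'
#' @param embedded `N x D` embedded stimulus matrix.
#' @param dimensions `D x K` matrix (or length-D vector) of candidate
#'   dimensions.
#' @return `N x K` matrix of projection values `x = s . v`.
#' @export
project_stimuli <- function(embedded, dimensions) {
  dimensions <- as.matrix(dimensions)
  if (nrow(dimensions) != ncol(embedded))
    stop("dimension length must equal stimulus dimensionality D")
  unclass(embedded) %*% dimensions
}

#' Equal-width binning scheme over observed projections
#'
#' Edges span the observed range of each projection column, split into
#' `bins` equal-width intervals.  Values on the boundary fall in the upper
#' bin; every projection maps to exactly one bin.
#'
#' @param projections `N x K` projection matrix.
#' @param bins number of bins per dimension (>= 2; the optimizer steps this
#'   from 6 to 11).
#' @return List of class `"binning_scheme"` with `bins`, `K`, `edges` (list
#'   of length-`bins+1` edge vectors) and `width` per dimension.
#' @export
binning_scheme <- function(projections, bins = 11L) {
  projections <- as.matrix(projections)
  if (bins < 2) stop("need at least 2 bins")
  edges <- lapply(seq_len(ncol(projections)), function(k) {
    r <- range(projections[, k])
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)   # degenerate: all equal
    seq(r[1], r[2], length.out = bins + 1)
  })
  structure(list(bins = as.integer(bins), K = ncol(projections),
                 edges = edges,
                 width = vapply(edges, function(e) e[2] - e[1], 0)),
            class = "binning_scheme")
}

# map projections to per-dimension bin indices (1..B), clamped to the range
bin_indices <- function(projections, scheme) {
  projections <- as.matrix(projections)
  B <- scheme$bins
  idx <- matrix(0L, nrow(projections), ncol(projections))
  for (k in seq_len(ncol(projections))) {
    e <- scheme$edges[[k]]
    i <- findInterval(projections[, k], e, rightmost.closed = TRUE)
    idx[, k] <- pmin.int(pmax.int(i, 1L), B)
  }
  idx
}

# collapse K-column bin indices to a single cell id in 1..B^K
cell_ids <- function(idx, B) {
  id <- idx[, 1]
  if (ncol(idx) > 1)
    for (k in 2:ncol(idx)) id <- id + (idx[, k] - 1L) * B^(k - 1)
  id
}

#' Histogram estimates of P(x) and P(x | spike)
#'
#' Bins the projections of all frames (giving `P_x`) and the spike-weighted
#' projections (giving `P_x_spike`) on a common equal-width grid.
#'
#' @param projections `N x K` projection matrix (K in 1..3).
#' @param spikes per-frame spike counts aligned with the rows.
#' @param scheme a [binning_scheme()]; by default one is built from
#'   `projections` with `bins` bins.
#' @param bins bins per dimension when `scheme` is NULL.
#' @return Object of class `"binned_distributions"`: list with `P_x`,
#'   `P_x_spike` (arrays over `B^K` cells), `counts`, `spike_weights`,
#'   `n`, `n_spikes`, `mean_rate`, `K`, `scheme`.
#' @export
bin_distributions <- function(projections, spikes, scheme = NULL, bins = 11L) {
  projections <- as.matrix(projections)
  if (length(spikes) != nrow(projections))
    stop("spikes must align with projection rows")
  if (sum(spikes) <= 0) stop("need at least one spike")
  if (is.null(scheme)) scheme <- binning_scheme(projections, bins)
  B <- scheme$bins; K <- ncol(projections)
  ncell <- B^K
  ids <- cell_ids(bin_indices(projections, scheme), B)
  counts <- tabulate(ids, ncell)
  sw <- numeric(ncell)
  pos <- which(spikes > 0)
  if (length(pos)) {
    agg <- rowsum(as.numeric(spikes[pos]), ids[pos])
    sw[as.integer(rownames(agg))] <- agg[, 1]
  }
  n <- nrow(projections); ns <- sum(spikes)
  structure(list(P_x = counts / n, P_x_spike = sw / ns, counts = counts,
                 spike_weights = sw, n = n, n_spikes = ns,
                 mean_rate = ns / n, K = K, scheme = scheme),
            class = "binned_distributions")
}

#' Empirical piecewise-constant gain function
#'
#' On every occupied bin, `g = mean_rate * P(x|spike) / P(x)`; unoccupied
#' bins are `NA` (undefined, not zero).  The occupancy-weighted mean of `g`
#' equals the mean rate by construction.
#'
#' @param binned a [bin_distributions()] result.
#' @return Object of class `"gain_function"`: list with `g` (length `B^K`,
#'   `NA` where unoccupied), `mean_rate`, `scheme`, `K`.
#' @export
estimate_gain <- function(binned) {
  g <- rep(NA_real_, length(binned$P_x))
  occ <- binned$P_x > 0
  g[occ] <- binned$mean_rate * binned$P_x_spike[occ] / binned$P_x[occ]
  structure(list(g = g, mean_rate = binned$mean_rate,
                 scheme = binned$scheme, K = binned$K),
            class = "gain_function")
}

#' Mutual information captured by a set of dimensions (bits per spike)
#'
#' Kullback-Leibler divergence of the spike-conditional projection
#' distribution from the prior one, summed over occupied bins; bins with
#' `P(x|spike) = 0` contribute zero (the `p log p` limit).
#'
#' @param binned a [bin_distributions()] result.
#' @return Information in bits (>= 0).
#' @export
mutual_information <- function(binned) {
  ps <- binned$P_x_spike; px <- binned$P_x
  k <- ps > 0
  sum(ps[k] * log2(ps[k] / px[k]))
}

#' Renyi divergence of order 2 between P(x|spike) and P(x)
#'
#' The least-squares-equivalent objective: `log2` of the mean of
#' `(P(x|spike)/P(x))^2` under `P(x)`, i.e.
#' `log2( sum_bins P(x|spike)^2 / P(x) )`.  Zero when the distributions
#' coincide; selectable as an alternative optimization objective.
#'
#' @param binned a [bin_distributions()] result.
#' @return Divergence value (dimensionless, >= 0).
#' @export
renyi2_divergence <- function(binned) {
  ps <- binned$P_x_spike; px <- binned$P_x
  k <- ps > 0
  log2(sum(ps[k]^2 / px[k]))
}

#' Rate-based information per spike (the data-processing bound)
#'
#' `I_spike = mean over frames of (r / rbar) * log2(r / rbar)`, computed from
#' known per-frame expected rates of a model cell.  This is the total
#' information carried by the firing rate and upper-bounds the information
#' captured by any projection set; it normalises "% information explained".
#'
#' @param rates nonnegative per-frame expected rates.
#' @return Bits per spike.
#' @export
info_per_spike <- function(rates) {
  if (all(rates == 0)) stop("all-zero rates carry no information")
  rbar <- mean(rates)
  z <- rates[rates > 0] / rbar
  sum(z * log2(z)) / length(rates)
}

#' Gradient of the binned information with respect to one dimension
#'
#' Assembles the information gradient from bin-wise conditional stimulus
#' averages: over occupied bins `b`,
#' `grad = sum_b P(b|spike) * d_k log2[P(b|spike)/P(b)] * (<s|b,spike> - <s|b>)`,
#' where `d_k` is a finite-difference derivative of the log-ratio across
#' neighbouring bins along axis `which_dim` (central differences where both
#' neighbours are valid, one-sided at edges).  Contributions are restricted
#' to bins that are occupied and whose neighbours used by the stencil are
#' occupied with nonzero spike mass, so the log-ratio is finite.
#'
#' @param embedded `N x D` embedded stimuli.
#' @param spikes per-frame spike counts.
#' @param dimensions `D x K` current dimension set.
#' @param which_dim axis along which to differentiate (1..K).
#' @param scheme optional [binning_scheme()]; default built from the current
#'   projections with `bins` bins.
#' @param bins bins per dimension when `scheme` is NULL.
#' @return Length-D numeric gradient vector (in bits per unit projection).
#' @export
info_gradient <- function(embedded, spikes, dimensions, which_dim = 1L,
                          scheme = NULL, bins = 11L) {
  if (nrow(as.matrix(dimensions)) != ncol(embedded))
    stop("dimension length must equal D")
  if (length(spikes) != nrow(embedded)) stop("spikes must align with rows")
  if (sum(spikes) <= 0) stop("need at least one spike")
  proj <- project_stimuli(embedded, dimensions)
  if (is.null(scheme)) scheme <- binning_scheme(proj, bins)
  w <- gradient_frame_weights(proj, spikes, scheme, which_dim)
  as.vector(crossprod(unclass(embedded), w))
}

# Per-frame weights a_i such that t(S) %*% a equals the bin-sum gradient
#   sum_b Psp(b) Dk(b) (<s|b,sp> - <s|b>)
# with <s|b,sp> = sum_{i in b} w_i s_i / W(b), <s|b> = sum_{i in b} s_i / n(b).
gradient_frame_weights <- function(proj, spikes, scheme, which_dim) {
  B <- scheme$bins; K <- ncol(as.matrix(proj))
  idx <- bin_indices(proj, scheme)
  ids <- cell_ids(idx, B)
  ncell <- B^K
  counts <- tabulate(ids, ncell)
  sw <- numeric(ncell)
  pos <- which(spikes > 0)
  if (length(pos)) {
    agg <- rowsum(as.numeric(spikes[pos]), ids[pos])
    sw[as.integer(rownames(agg))] <- agg[, 1]
  }
  n <- length(ids); ns <- sum(spikes)
  Psp <- sw / ns; Px <- counts / n
  L <- rep(NA_real_, ncell)
  v <- sw > 0                       # log-ratio finite only with spike mass
  L[v] <- log2(Psp[v] / Px[v])

  # derivative of L along axis which_dim on the flattened cell grid
  stride <- B^(which_dim - 1)
  pos_k <- idx[, which_dim]         # per-frame position along the axis
  h <- scheme$width[which_dim]
  cellpos <- cell_axis_position(ncell, B, which_dim)
  Dk <- numeric(ncell)
  occ <- counts > 0
  up <- seq_len(ncell) + stride; dn <- seq_len(ncell) - stride
  has_up <- cellpos < B; has_dn <- cellpos > 1
  ok_up <- has_up; ok_up[has_up] <- occ[up[has_up]] & v[up[has_up]]
  ok_dn <- has_dn; ok_dn[has_dn] <- occ[dn[has_dn]] & v[dn[has_dn]]
  central <- occ & ok_up & ok_dn
  Dk[central] <- (L[up[central]] - L[dn[central]]) / (2 * h)
  fwd <- occ & v & ok_up & !ok_dn
  Dk[fwd] <- (L[up[fwd]] - L[fwd]) / h
  bwd <- occ & v & ok_dn & !ok_up
  Dk[bwd] <- (L[bwd] - L[dn[bwd]]) / h
  use <- central | fwd | bwd

  a <- numeric(n)
  cf <- Psp * Dk
  cf[!use] <- 0
  # spike-triggered part: + cf(b) * w_i / W(b);  prior part: - cf(b) / n(b)
  a <- -cf[ids] / counts[ids]
  a[pos] <- a[pos] + cf[ids[pos]] * as.numeric(spikes[pos]) / sw[ids[pos]]
  a[!is.finite(a)] <- 0
  a
}

# position (1..B) of each flattened cell along the given axis
cell_axis_position <- function(ncell, B, axis) {
  ((seq_len(ncell) - 1) %/% B^(axis - 1)) %% B + 1
}

#' Objective value of a dimension set on data
#'
#' Convenience wrapper: projects, bins with fresh equal-width edges, and
#' evaluates the chosen objective.
#'
#' @param embedded,spikes data.
#' @param dimensions `D x K` dimension set.
#' @param bins bins per dimension.
#' @param objective `"kl"` (mutual information, bits) or `"renyi2"`.
#' @return Scalar objective value.
#' @export
info_objective <- function(embedded, spikes, dimensions, bins = 11L,
                           objective = c("kl", "renyi2")) {
  objective <- match.arg(objective)
  proj <- project_stimuli(embedded, dimensions)
  bd <- bin_distributions(proj, spikes, bins = bins)
  if (objective == "kl") mutual_information(bd) else renyi2_divergence(bd)
}
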