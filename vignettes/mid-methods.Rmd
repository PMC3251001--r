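---
title: "Estimating multicomponent receptive fields by information maximization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating multicomponent receptive fields by information maximization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(midest)
```

## The model and the estimation problem

A linear-nonlinear (LN) neuron responds to a high-dimensional stimulus
$\mathbf{s} \in \mathbb{R}^D$ (here: movie patches of `H x W` pixels over
`n_lags` frames, so $D = H \cdot W \cdot n_\mathrm{lags}$) only through its
projections onto a small number $K$ of *relevant dimensions*
$\hat e_1, \dots, \hat e_K$:

$$ r(\mathbf{s}) = \bar r \, g(\mathbf{s}\cdot\hat e_1, \dots,
   \mathbf{s}\cdot\hat e_K), $$

with $g$ an arbitrary nonnegative gain function and $\bar r$ the mean spike
rate per frame.  Estimating the model means finding the spanned subspace —
any non-degenerate recombination of the $\hat e_i$ is an equivalent
description — and then reading off the gain empirically as

$$ g(\mathbf{x}) = \bar r \, \frac{P(\mathbf{x} \mid \mathrm{spike})}
   {P(\mathbf{x})}, $$

a ratio of binned histograms of projection values over spike-triggered and
all frames.

`midest` estimates the dimensions by **maximally informative dimensions
(MID)**: maximizing the Kullback–Leibler divergence (in bits)

$$ I(v_1,\dots,v_K) = \sum_{\mathbf{x}} P(\mathbf{x}\mid\mathrm{spike})
   \log_2 \frac{P(\mathbf{x}\mid\mathrm{spike})}{P(\mathbf{x})} $$

over candidate dimension sets, which requires no assumption about stimulus
statistics — the property that matters for natural, non-Gaussian stimuli.
An order-2 Rényi divergence (the least-squares-equivalent objective) is
available as an alternative (`mid_control(objective = "renyi2")`).

Two search strategies are implemented by `mid()`:

* **sequential** — each new dimension maximizes the one-dimensional
  information, restricted to the orthogonal complement of all previously
  found dimensions, which are never revised;
* **joint** — the full $K$-dimensional information is maximized; most
  iterations update the newest dimension and every 100th iteration each
  earlier dimension receives one update step.

For Gaussian stimuli (correlated or not), conditional stimulus means are
linear in the projections, and the gradient of the one-dimensional
information at the within-subspace optimum has no out-of-subspace
component — sequential search is unbiased.  For non-Gaussian, correlated
stimuli the conditional means acquire nonlinear components and sequential
search (like any additive-model least-squares method, including projection
pursuit regression) develops a systematic bias that does not vanish with
more data.  Both facts are exercised as property tests in the package
(gradient components at the within-subspace optimum, shrinking with $N$ for
a correlated Gaussian ensemble, persisting for the non-Gaussian surrogate).

## Information gradient and its discretization

The gradient of the binned information with respect to dimension $v_k$ is
assembled from bin-wise conditional stimulus averages:

$$ \nabla_{v_k} I = \sum_{\mathbf{x}} P(\mathbf{x}\mid\mathrm{spike})
   \left[ \langle \mathbf{s}\mid\mathbf{x},\mathrm{spike}\rangle -
          \langle \mathbf{s}\mid\mathbf{x}\rangle \right]
   \partial_{x_k} \log_2
   \frac{P(\mathbf{x}\mid\mathrm{spike})}{P(\mathbf{x})}. $$

Numerical choices (the histogram discretization leaves them open):

* bin edges are equal-width over the observed projection range of the
  current training fold and are recomputed whenever a dimension changes;
* the log-ratio derivative uses central differences across neighbouring
  bins, one-sided at the edges of the grid;
* gradient contributions are restricted to bins that are occupied and whose
  stencil neighbours are occupied with nonzero spike mass, so the
  log-ratio is finite wherever it is differenced;
* bins with $P(\mathbf{x}) > 0$ but $P(\mathbf{x}\mid\mathrm{spike}) = 0$
  contribute zero to the information (the $p \log p$ limit); no pseudocounts
  are added.

The gradient implementation is validated against central finite differences
of the binned objective.  Because the binned objective is piecewise constant
in $v$ (a staircase: moves only change it when projections cross bin
edges), the finite-difference step must be moderate ($h = 0.15$ on the unit
sphere at $B = 15$ bins); at that scale the analytic and numerical gradients
agree to a few percent in direction and magnitude.

## The annealed line-search optimizer

Each iteration computes the gradient at the current point, projects it onto
the unit sphere (the objective is scale-invariant) and, in sequential mode,
onto the orthogonal complement of the earlier dimensions, then
golden-section line-searches along it (12 evaluations).  Uphill moves are
always accepted; downhill moves are accepted with probability
$\exp(\Delta I / T)$, and $T$ is cooled by a factor 0.95 per iteration.
The bin count steps from 6 to 11 in six equal stages over the run (every
200 iterations at the reference length of 1200), coarse-to-fine: few bins
first optimize the large-scale structure of the dimensions, more bins
refine it.

Design choices in the optimizer that the protocol leaves open:

* **Initial temperature** — estimated from the first ten (greedily
  accepted) steps so that the median early $|\Delta I|$ would be accepted
  downhill about half the time.
* **Line-search bracket** — twice the last accepted step, with a floor of
  0.25; without the floor a single tiny accepted step collapses the bracket
  and freezes the chain (this failure mode is easy to reproduce at
  $D = 768$).
* **Restarts** — when proposals stop changing the objective
  ($|\Delta I| < 10^{-5}$ bits ten times in a row) *or* the chain has not
  improved its own best point for 40 iterations, the temperature is
  multiplied by 100 and the chain restarts from the best point perturbed by
  a random step, with the perturbation escalating while restarts keep
  failing (half the norm, then twice it, then a fresh random direction).
  The best-so-far point is retained across restarts and across bin-stage
  changes (re-evaluated under the new binning, since information values at
  different bin counts are not comparable).
* **Starting points** — each dimension starts from the best (by objective
  value, at the coarse bin count) of a small candidate set: the training
  fold's spike-triggered average, the four leading eigenvectors — by
  absolute eigenvalue — of the spike-triggered covariance difference, and a
  randomly drawn spike-eliciting stimulus frame, all projected onto the
  allowed search space.  The STA alone is the classical choice, but it is
  zero in expectation for symmetric gain functions (all the model cells
  here are symmetric), and measured at $D = 768$ its noise-level start sits
  below the overlap at which the information gradient reliably out-pulls
  the training objective's overfit ridges; the covariance eigenvectors are
  the standard initialization in exactly that situation.  The start
  selection is deterministic given the fold and seed, and identical for
  joint and sequential search, which coincide at $K = 1$.
* **Normalization** — dimensions are renormalized after every accepted step;
  in sequential mode trial points are re-orthogonalized against earlier
  dimensions.

The heavy operations per iteration are two $N \times D$ matrix-vector
products (assembling the gradient and projecting the search direction);
the training matrix is held in single precision by compiled code
(products accumulated in double), which roughly halves the memory traffic
that bounds their speed.

The jackknife protocol fits each dataset four times, omitting a different
contiguous quarter; fold estimates are aligned (sign for $K=1$; orthogonal
Procrustes within the spanned subspace for $K>1$, since dimensions are
defined only up to recombination) and averaged; the average is then
orthonormalized.  Per-coefficient signal-to-noise maps are
|mean|/SD across the aligned fold estimates.  Fold-mean and SE are reported
for every score.

## Model cells

Three gain families drive the simulations, built on quadrature pairs of
spatial Gabor filters (identical orientation and spatial frequency, phases
$\pi/2$ apart) with a transient temporal profile, plus a third Gabor at the
orthogonal orientation for the suppressive dimension:

* `or_threshold` — spike if $|s_1 + n_1| > \theta$ **or**
  $|s_2 + n_2| > \theta$ with $n_i \sim N(0, \sigma^2)$; the spike
  probability is computed in closed form from Gaussian tails and spikes are
  Bernoulli.  $\theta$ and $\sigma$ are expressed in units of the projection
  SD on the simulation ensemble.  The reference description reports this
  cell's firing in Hz at a level that exceeds one spike per frame, which a
  binary rule cannot produce; the rates are therefore treated as
  non-normative, and $\theta$ defaults to $2\,\mathrm{SD}$ with
  $\sigma = 0.5\,\mathrm{SD}$ (moderately sparse firing), with
  `calibrate_gain()` available to hit any target probability.
* `divisive` — $r = \gamma\,(s_1^2 + s_2^2)/(1 + \omega s_3^2)$, Poisson
  spiking; `calibrate_gain()` solves $\omega$ from
  $\langle 1 + \omega s_3^2\rangle = 4.26$ (linear in $\omega$) and then
  scales $\gamma$ so $\langle r\rangle = 0.56$, the reference operating
  point.  Setting $\omega = 0$ gives the two-dimensional quadratic cell.
* `quadratic_1d` — $r = \gamma s_1^2$.

`info_per_spike()` computes the rate-based information
$\langle (r/\bar r)\log_2 (r/\bar r)\rangle$ from the known model rates —
the data-processing bound that normalizes "percent information explained".
Held-out percentages are computed per jackknife fold on its held-out
quarter, with bins refit on the held-out projections at $B = 11$ (the final
optimization bin count, kept for comparability across methods).  Estimator
noise can push individual folds slightly above 100%; values are reported,
not clamped.  Note a systematic feature measured in the test suite: with
equal-width bins spanning the sample range, the $B = 11$ histogram captures
about 89% of the rate information of the OR cell even from the exact model
dimensions at $N = 50{,}000$ — this binning loss is part of any
histogram-based percentage reported here.

## Synthetic stimulus ensembles

`generate_white_noise()` draws i.i.d. standard-normal pixels (then z-scores
the ensemble exactly).  `generate_naturalistic()` is a surrogate for
natural movies, which are not shipped with the package: each frame is
spatially filtered to a $1/f^2$ power spectrum, frames are mixed by an
AR(1) process (coefficient 0.6) for temporal correlation, and the pooled
marginal is rank-mapped onto a log-normal, producing the heavy tails and
nonlinear conditional means that drive the sequential-search bias; the
ensemble is z-scored overall.  The surrogate reproduces the second-order
and marginal statistics the bias analysis needs, but not the full
higher-order structure of real movies (no occlusions, shadows, or motion
streaks), so quantitative scores on the surrogate are not comparable to
scores obtained with actual natural movies — qualitative orderings
(joint over sequential, MID over PPR) are the reproducible content.
Surrogate parameters (exponent 2, AR 0.6, log-normal marginal) are stated
defaults, chosen once as a realistic operating point; they are not fitted
to any target.

## Projection pursuit regression baseline

`fit_ppr()` fits the additive model
$r(\mathbf{s}) \approx \bar r + \sum_k f_k(\mathbf{s}\cdot v_k)$ by
sequential least squares: each term alternates (a) re-estimating the ridge
function $f_k$ as bin means of the residual over 15 equal-width projection
bins with (b) a golden-section step along the $\chi^2$ gradient
$-2\sum_i (r_i - f(x_i)) f'(x_i)\,\mathbf{s}_i$, followed by one
back-fitting sweep.  $\chi^2$ is non-increasing by construction.  This is
deliberately the core sequential least-squares method — no multi-resolution
refinement or term deletion — so comparisons against it probe the additive
(separable) assumption itself, not implementation detail.

## Evaluation

`subspace_projection()` scores a reconstruction against the true dimensions
by the normalized projected volume
$|\det P| / \sqrt{\det G_\mathrm{model}\,\det G_\mathrm{recon}}$ ($P$ the
matrix of mutual inner products, $G$ the Gram matrices) and reports its
$K$-th root $O \in [0,1]$ — the linear overlap, invariant to recombination
within either set, equal to $|\cos|$ at $K = 1$ (so three dimensions each
recovered at 0.8 give $O = 0.8$ while the raw volume is $\approx 0.51$).

`convergence_experiment()` maps reconstruction quality against the sampling
ratio $K D / N_\mathrm{spikes}$ by scaling the firing rate to a grid of
spike budgets (equivalent to using fewer stimulus repetitions), running
joint and sequential fits over several seeds.  The joint curves for
different $K$ approximately collapse on this abscissa; sequential search on
the non-Gaussian surrogate stops improving with more spikes once its
systematic bias dominates.

## Problem sizes used by the packaged checks

Estimating hundreds of filter coefficients against a histogram objective is
the expensive regime of this method, and the packaged checks run the same
protocol at reduced problem sizes, chosen once as the package's verification
conditions:

* the test suite exercises the white-noise and surrogate experiments at
  $8 \times 8$ pixels (2–3 lags, $D = 128$–$192$), 12,000–25,000 frames and
  240–300 optimizer iterations per dimension; convergence and bias
  properties use $D \le 192$;
* the acceptance script runs the full $16\times16\times3$ ($D = 768$)
  white-noise experiment of the two-dimensional OR cell at the reference
  frame count ($T = 50{,}000$) with a shortened annealing schedule
  (600 iterations per dimension, bin stages of 100).

Undersampling is the known failure mode: when the spike count per fold
falls toward $K D$, overfit ridges of the training objective rival the true
maximum and any histogram-based search degrades (this is the content of the
convergence experiment, and the reason the packaged checks keep the
sampling ratio in the regime the method is designed for).

## Known limitations

* Histogram estimation limits joint fits to $K \le 3$ (the curse of
  dimensionality); `mid()` refuses larger $K$ unless overridden.
* The binned information estimator is biased upward on training data and
  loses a bin-quantization fraction of the true information; percentages
  are normalized by the exact rate-based bound and inherit that loss.
* The naturalistic surrogate is a statistical stand-in, not natural video;
  numbers printed in the reference study for real movies are not
  reproducible from it, only the qualitative orderings.
* Repeat-based estimation of the information per spike from recorded data
  (extrapolation over data fractions) is not implemented; `info_per_spike()`
  requires known model rates, so percent-information scores apply to
  simulated cells.
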