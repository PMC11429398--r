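---
title: "Methods: CCA fusion and Harris Hawks wrapper selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CCA fusion and Harris Hawks wrapper selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by **hawkfs**, the
assumptions behind it, every tunable parameter, and the numerical and
design decisions that determine its exact behaviour. The intended use
case is two-view classification: each sample carries two real-valued
feature vectors (for example, embeddings from two different deep
backbones applied to the same histopathology image) and a binary label.

## 1. Data model

A `feature_view` is a numeric matrix with feature identifiers; a
`labeled_dataset` bundles one or two views with integer 0/1 labels.
`read_feature_table()` / `write_feature_table()` round-trip these through
delimited text (comma or tab, auto-detected) with values written at 17
significant digits so that a write–read cycle reproduces doubles to
within 1e-12.

`holdout_split(dataset, fraction, seed)` draws a stratified holdout:
within each class, `floor(fraction * n_class + 0.5)` samples (round half
up) go to the test partition. With 2435 + 2511 samples and a 0.2
fraction this yields a 989-sample test set (487 + 502). The split is a
pure function of the seed.

## 2. CCA fusion

### Model

For centred views $X$ ($n \times d_x$) and $Y$ ($n \times d_y$) with
covariance blocks $C_{xx}, C_{yy}, C_{xy}$, canonical weights solve

$$C_{xx}^{-1} C_{xy} C_{yy}^{-1} C_{yx}\, W_x = \rho^2 W_x ,$$

with $W_y$ recovered from $W_x$. All $k = \min(d_x, d_y)$ pairs are
retained — the method is used as a *fusion* step, not a dimension
reducer, so no component-selection rule is applied. Fusion is either
`"concat"` (default), giving a $2k$-dimensional vector $(X W_x, Y W_y)$,
or `"sum"`, giving the $k$-dimensional $X W_x + Y W_y$. Concatenation is
the default because the headline configuration of the package — a
2048-d and a 1280-d deep-feature view — is meant to produce a 2560-d
fused vector.

### Numerical choices

* **Ridge regularization.** Each covariance block gets a ridge
  `ridge * mean(diag(C))` added to its diagonal; the default ridge is
  `1e-6`. This makes the fit well defined when $n \le d$, which is the
  normal regime for deep features.
* **Solver route.** The symmetric eigenproblem is formed on the
  *smaller* view via a Cholesky factor $U$ of its covariance:
  $M = U^{-\top} C_{yx} C_{xx}^{-1} C_{xy} U^{-1}$, solved with
  `eigen(symmetric = TRUE)`. The larger view's weights are recovered by
  a linear solve and renormalized so that $W^\top (C + rI) W = I$
  (metric orthonormality). This costs $O(d_{\min}^3)$ instead of
  $O(d_{\max}^3)$ and handles the 2048 x 1280 case in seconds.
* **Rank deficiency.** When $n - 1 < d$, components beyond the data rank
  have zero norm in the recovered weights. Those columns are completed
  to an orthonormal basis (in the whitened metric) by Gram–Schmidt plus
  QR, so the fused representation always has the full advertised
  dimension and the orthonormality contract holds exactly. Their
  canonical correlations are reported as computed (numerically zero or
  meaningless-small).
* **Sign convention.** Each weight pair is flipped so that the first
  non-negligible loading of the $X$-side column is positive, making
  fits reproducible across platforms.
* **Centering only.** Columns are centred, not scaled; CCA is invariant
  to per-view invertible linear maps, so scaling is unnecessary, and
  the per-feature scale of deep features is often meaningful.

A caution that the test suite makes explicit: with $n \ll d$ and a
ridge, canonical correlations of *pure noise* views are near 1 —
correlation strength is only interpretable relative to the $n/d$
regime. `predict()` applies the training means and weights to new data,
so fusion must be fit on the training partition only; the package's
`run_pipeline()` enforces this.

## 3. Harris Hawks optimization

`hho_optimize(objective, config)` minimizes a black-box function over a
box $[l, u]^d$ with $N$ hawks for $s$ iterations.

* **Energy schedule.** $E = 2 E_0 (1 - t/s)$ with $E_0 \sim U(-1,1)$
  redrawn once per iteration and shared by the population.
* **Phase switch.** Exploration when $|E| \ge 1$, exploitation when
  $|E| < 1$. (This is the canonical convention: early iterations, where
  $|E|$ is large, explore.)
* **Exploration.** With probability $q \ge 0.5$ a hawk perches relative
  to a random hawk, $m' = m_r - r_1 |m_r - 2 r_2 m|$; otherwise relative
  to the prey and the population mean,
  $m' = (m_{rab} - \bar m) - r_1 (l + r_2 (u - l))$.
* **Besiege.** With $r_e \ge 0.5$: hard besiege
  ($m' = m_{rab} - E |\Delta m|$-style collapse onto the prey as
  $E \to 0$) or soft besiege
  $m' = \Delta m - E\,|2(1 - r_e)\, m_{rab} - m|$; both replace the hawk
  unconditionally.
* **Rapid dives** ($r_e < 0.5$): candidate
  $A = m_{rab} - E\,|2(1-r_e)\,m_{rab} - \text{base}|$ and, only if $A$
  does not improve, $B = A + \text{Lévy}$; greedy acceptance, so at most
  two objective calls per dive and one if $A$ improves
  (`hho_dive_step()` exposes this contract directly).
* **Lévy flights** use Mantegna's algorithm with $\beta = 1.5$ and scale
  0.01.
* **Clipping.** Every move is hard-clipped to $[l, u]$ before
  evaluation; the objective never sees an out-of-box point.

### Elite updates (IHHO)

The improved variant re-ranks the population each iteration and applies
three extra moves, each accepted greedily (at most 3 extra evaluations
per iteration):

* **alpha** (best hawk): if $\tan(\pi(r - 0.5)) < 1 - t/s$ (a Cauchy
  draw compared with the remaining time) jump to the prey; otherwise
  move to prey $+\,(4 - 4t/s)\, r' (m_m - m_n)$, a difference step
  between two random hawks whose size shrinks over time.
* **beta** (second): with probability 0.5 keep, else move to the
  midpoint of the first and second hawks.
* **gamma** (third): with probability 0.5 the midpoint of two random
  hawks, else the mean of the three elites.

On smooth continuous benchmarks (the sphere) IHHO reaches markedly
lower optima than plain HHO; both variants are exposed.

## 4. Binary wrapper selection

`select_features()` runs the optimizer over $[0,1]^d$ where $d$ is the
number of candidate features; a position is binarized per evaluation:

$$\text{bit}_j = \mathbf{1}\{ r_j < S(8 (m_j - 0.5)) \},\qquad
  S(z) = 1/(1 + e^{-z}),$$

with i.i.d. $r_j \sim U(0,1)$ drawn from a counter-keyed substream so
that runs are exactly reproducible. The slope 8 makes the transfer
steep but not degenerate: $m_j = 0$ maps to selection probability
$S(-4) \approx 0.018$, $m_j = 1$ to $\approx 0.982$. An all-zero mask is
repaired by forcing the bit with the largest transfer value. A
deterministic thresholding mode (`binarize_mode = "deterministic"`) is
also provided.

A mask is scored on an internal validation split (default 20% of the
training data, stratified, seeded) by

$$J(\text{mask}) = \sigma\,(1 - \text{acc}) +
  (1 - \sigma)\,\frac{f_{SL}}{f_{FL}},\qquad \sigma = 0.99,$$

where acc is the accuracy of a $k=5$ nearest-neighbour classifier
(Euclidean metric). The KNN is hand-rolled to make tie-breaking
deterministic: distance ties resolve to the lower training index, vote
ties to the lower label. The selector returns the best mask *ever
evaluated*, not the final prey position, so the fitness trace is
non-increasing by construction.

### Behaviour on strongly separated data

Because accuracy enters $J$ through a validation set of modest size, on
strongly separated data (large per-feature effect sizes) the accuracy
term saturates at 1 for many small subsets, and the $(1-\sigma)$
sparsity term then dominates: the selector collapses to a minimal
sufficient subset rather than recovering *all* informative features.
This is the objective working as specified — $J$ rewards sparsity among
accuracy-equivalent masks — and is why the test suite asserts strong
*precision* enrichment and high downstream accuracy rather than full
recall on such data. Users who want high recall should lower `sigma`'s
complement pressure indirectly by using harder data, a larger
validation fraction, or repeated runs with `run_selection_many()`.

## 5. Synthetic generator

`synthetic_spec()` fixes the study conditions; `generate_two_view()`
materializes them. Defaults: $n = 400$ samples, $d_x = 60$, $d_y = 40$,
5 informative features per view, effect size 3, cross-view latent
correlation $\rho = 0.5$, balanced classes, seed 1.

* Labels are a fixed count `round(n * balance)` of ones, permuted.
* Informative feature: $\text{label} \cdot e + \rho g + \sqrt{1-\rho^2}\,\varepsilon$
  with a latent $g$ *shared across views*, so the views are genuinely
  correlated and CCA has structure to find.
* Optional redundant features are random linear combinations of the
  informative ones plus unit noise; remaining features are $N(0,1)$.
* `rectify = TRUE` clips values at zero, mimicking post-ReLU features.
* `bayes_separation(spec)` returns the closed-form Mahalanobis
  separation $e\sqrt{m / (1 - \rho^2 + \rho^2 m)}$ of one view's
  informative block, useful for placing a given spec on the
  easy–hard axis.

The generator is the scope of every empirical claim in the test suite:
passing tests show the pipeline recovers planted structure *of this
generator* at the stated sizes; they do not certify performance on real
histopathology features.

## 6. Statistics

`run_selection_many()` repeats selection over consecutive seeds and
collects accuracies, subset sizes and final fitnesses.
`two_sample_ttest()` is a pooled (or Welch) two-sample t-test delegating
to `stats::t.test`; `cohens_d()` is the pooled-SD standardized mean
difference in closed form; `box_summary()` reports type-7 quantiles.
Zero-variance inputs raise a classed error rather than returning `NaN`.

## 7. Reproducibility

Every stochastic entry point takes a `seed` and restores the caller's
RNG state, so library calls never perturb a user's random stream. The
wrapper's binarization draws come from a substream keyed by
`(seed, evaluation counter)`, making results independent of evaluation
order details. `run_pipeline()` records every stage's seed in
`manifest.json`, and identical configurations reproduce artifacts byte
for byte.

## Limitations

* Binary labels only; multi-class would need a different fitness.
* CCA fusion is linear; nonlinear relationships between views are only
  captured insofar as they have a linear component.
* Canonical correlations are not interpretable as evidence of shared
  structure when $n \ll d$ (see Section 2).
* The wrapper's objective evaluates masks on a single internal split;
  no cross-validation is performed inside the fitness, by design (cost).
* The optimizer offers no convergence guarantee; defaults
  (`n_hawks = 20`, `max_iters = 100`) are study conditions, not tuned
  recommendations for arbitrary problems.
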