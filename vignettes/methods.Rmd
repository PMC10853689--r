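---
title: "Methods behind tricotkit: design, ranking models and segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind tricotkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tricotkit)
```

## The tricot format

A tricot trial distributes the levels of a technology (varieties, practices,
products) across participants in blind packages of three, labelled A, B and
C. Each participant reports, per trait, which of their three options was
best and which worst. The format trades per-observer precision for breadth:
many small blocks spread over real farms, seasons and management styles.
Everything in this package follows from two consequences of that format:
blocks are incomplete (three of `t` options) and the data are rankings, not
measurements.

## Design generation

### Criteria

For `n` packages over `t` options we target three properties:

* **A-optimality.** Build the *concurrence graph*: options are nodes, and
  each block adds one unit of edge weight to each of its three option
  pairs. The average variance of pairwise worth contrasts is proportional
  to the **Kirchhoff index** of this graph,
  \(Kf = t \sum_{i=2}^{t} 1/\mu_i\) over the nonzero eigenvalues of the
  weighted Laplacian — equivalently the sum of effective resistances over
  all node pairs. Minimizing `Kf` makes the comparison network
  well-connected and maximally robust to randomly missing blocks; a
  disconnected graph has `Kf = ∞` (some contrasts are inestimable).
* **Sequential balance.** Field logistics hand out consecutively numbered
  packages per village or per day, so every prefix of consecutive packages
  should be near-uniformly replicated. We report the worst prefix
  imbalance (max − min replication over the first `b` packages, maximized
  over `b`) and require ≤ 2: the canonical published 20-package example
  itself attains 2, so a bound of 1 would reject accepted practice.
* **Position balance.** Position effects (the A plot may get systematic
  attention) are neutralized by letting each option occupy positions A, B
  and C with near-equal frequency; we bound the deviation from the fair
  share (replication/3, rounded) by 1, again the level the published
  example attains.

### Algorithm

The criteria are stated in the literature; the construction is ours, in
three phases, fully determined by the seed:

1. **Sequential greedy.** Blocks are filled in order, always taking the
   three options with the lowest current replication, breaking ties by the
   lowest concurrence with options already in the block, then at random.
   Sequential balance holds by construction.
2. **Kirchhoff local search.** Single-item swaps between two blocks (which
   leave all replication counts unchanged) are accepted only when they
   strictly decrease `Kf` and preserve prefix imbalance ≤ 2, until a full
   pass accepts nothing or `500·n` swaps have been evaluated. For trials
   with more than 60 packages a pass samples `20·n` candidate block pairs
   and pre-screens swaps by whether they even out the squared concurrence
   weights, skipping the spectral evaluation otherwise; an exhaustive pass
   over all block pairs costs `O(n²)` eigendecompositions, which is
   pointless when phase 1 already leaves the concurrence matrix within one
   unit of uniform. For the small designs where exhaustive search over all
   block multisets is feasible, the two-phase generator reproduces the
   global optimum (see the acceptance tests).
3. **Position assignment.** Each block's three options are mapped to
   A/B/C greedily (choosing the permutation that least inflates current
   position occupancy), followed by repair sweeps over the six within-block
   permutations minimizing squared deviation from each option's fair
   share.

Degenerate corner: with `t = 3` every block is the full option set and only
phase 3 matters.

## From best/worst to rankings

Positions are resolved to option names through the design, and:

* best + worst → the full strict order (best ≻ middle ≻ worst);
* best only → best ≻ {other two, tied};
* worst only → {other two, tied} ≻ worst;
* neither → the record is dropped (and counted).

Partial reports are retained because the Plackett–Luce likelihood handles
them exactly and tricot trials must tolerate plot loss. Which convention to
use for worst-only records is not settled in the literature; we adopt the
symmetric one above.

## The Plackett–Luce model

Each option has worth `w_i > 0`. A strict ranking arises by successive
choice: the first-ranked item is drawn with probability proportional to
worth, then the next among the remainder, and so on, giving
\[
P(i_1 \succ \dots \succ i_k) \;=\; \prod_{j=1}^{k-1}
  \frac{w_{i_j}}{\sum_{l \ge j} w_{i_l}} .
\]
`w_i/(w_i + w_j)` is the head-to-head outperformance probability reported
to trial managers. Log-worths are centered to sum to zero for
identifiability.

**Likelihood of partial rankings.** A best-only record contributes its one
realized top choice. A worst-only record contributes the exact marginal
probability that the reported option ranks last — the sum over the two
compatible strict orders. No tie model (Davidson-style) is ever needed for
the shapes tricot data can produce.

**Fitting.** Hunter's MM iteration
\(w_i \leftarrow \text{wins}_i \big/ \sum_{s: i \in A_s} 1/\sum_{j \in A_s} w_j\)
is monotone in the objective and renormalized each step (geometric mean 1).
Worst-only records are handled by an EM wrapper: their two latent orders are
weighted by posterior probability each iteration, preserving monotonicity of
the observed likelihood. Convergence is declared when the gradient max-norm
falls below `tol = 1e-8` (default; `max_iter = 10000`). The gradient comes
free from the update quantities (`g_i = wins_i − w_i · denom_i`), so the
check costs nothing.

**Estimability and regularization.** The MLE is finite iff the directed
win graph (an edge `i → j` when `i` is ranked strictly above `j` somewhere)
is strongly connected. With `regularization = 0` we test this and refuse to
fit otherwise, naming the strongly connected components. The default
`regularization = 0.5` instead adds, per option, a win and a loss of that
weight against a ghost reference item (whose worth is estimated and then
discarded) — the pseudo-ranking device of the reference implementation of
this model, whose default weight we also adopt; it is configurable and
documented rather than hidden. Reported log-likelihoods are always the
exact, unpenalized data likelihood at the fitted worths.

**Standard errors** come from the numerically differentiated observed
information on the sum-to-zero scale (central differences, step `1e-4`),
reported only for unregularized fits since the penalized curvature would
understate uncertainty.

## Plackett–Luce trees and forward selection

Preference heterogeneity is detected by recursive partitioning: at each
node every covariate is scanned — numeric covariates at midpoints of sorted
unique values (quantile-thinned past 50 candidates), categorical ones
one-vs-rest — and each feasible split (both sides ≥ `min_node_size`,
default 30) is scored by the likelihood ratio
`2(ℓ_left + ℓ_right − ℓ_pooled)`. The best split is accepted iff its
Bonferroni-adjusted χ²(t−1) p-value (adjusted over the number of
covariates) is ≤ `alpha = 0.05`, recursing to `max_depth = 3`.

The χ² reference is approximate: maximizing over thresholds inflates the
statistic. We do not correct for this beyond Bonferroni; instead the null
behavior is validated by simulation in the test suite (homogeneous data
yield a single leaf in ≥ 90% of runs at `alpha = 0.05`). Users wanting
strict type-I control should treat reported p-values as screening
quantities. Full structural-change (M-fluctuation) tests of the
model-based-partitioning literature are a deliberate non-goal here; the LR
machinery is transparent, fast at tricot scale, and testable against
simulation.

**Forward selection** scores a candidate covariate set by `k`-fold
(default 5) cross-validated held-out log-likelihood: folds are formed at
the package level (seeded), a tree restricted to the candidate set is grown
on the training folds, each held-out ranking is routed down to its leaf and
scored under that leaf's worths. Starting from the no-split null model,
the covariate giving the largest strict improvement is added until none
improves. Strict improvement (> 0) is the stopping rule, so all-noise
covariate sets usually select nothing.

## Agro-climatic indices

Daily weather (date, tmin, tmax, precipitation) is user-supplied; windows
are half-open `[planting, planting + duration)` and must be gap-free. Three
conventional indices are computed, each configurable:

| index | definition | default |
|---|---|---|
| `gdd` | Σ max(0, (tmax+tmin)/2 − t_base); optional tmax cap | t_base = 10 °C, no cap |
| `max_dry_spell` | longest run of days with precip < threshold | 1 mm/day |
| `heat_days` | days with tmax strictly > t_crit | 35 °C |

These are the standard simple formulations of the agro-climatology index
packages; nothing is rescaled before entering the covariate table.

## The synthetic trial generator

`synthesize_trial()` states a world: a generated design, a balanced binary
environment covariate, environment-specific log-worths
`(1−e)·w + e·rev(w)` (so `e = 0` is homogeneity and `e = 1` a full
preference reversal — the canonical crossover-interaction signal), and
responses sampled from the exact Plackett–Luce choice process at a given
response rate. Default baseline log-worths are evenly spaced over [0, 1], a
moderate spread typical of fitted variety trials.

What it deliberately does **not** emulate: observer error beyond PL noise,
trait correlation, spatial autocorrelation, non-random attrition, or
covariate measurement error. A green simulation test therefore establishes
that the estimators recover the model they assume — not that real trials
satisfy those assumptions.

## Numerical choices, in one place

* Laplacian eigenvalues below `1e-9` relative to the largest are structural
  zeros; more of them than one means a disconnected graph, `Kf = ∞`.
* The pseudoinverse route to `Kf` uses the rank-one shift
  `(L + J/t)^{-1} − J/t` and a BFS connectivity check, keeping it fully
  independent of the spectral route; the two agree to `1e-9` on random
  graphs in the tests.
* Swap acceptance requires a `Kf` decrease of at least `1e-12`
  (tie-breaking noise does not churn the design).
* MM objective decreases beyond `1e-8` raise a warning (they indicate a
  bug, and the monotonicity property is tested).
* Worth ties in reports are broken alphabetically, so report bytes are a
  pure function of inputs.
* All randomness (design, simulation, fold assignment) flows through one
  seed and is restored after use; the caller's RNG state is never
  disturbed.

## Known limitations

* Precision of fitted log-worths is bounded by the information in blocks
  of three: with a few hundred blocks the per-option standard error is
  roughly 0.1 on the log scale (the tests compute this via the observed
  information), so small worth differences need large trials — a property
  of the format, not of the estimator.
* The LR-tree p-values are approximate (see above); depth and node-size
  defaults are conservative for typical trial sizes of 100–500 packages.
* Rankings longer than three and tie likelihoods are out of scope; the
  data model is deliberately the tricot one.
* The design local search is a heuristic: it certifies local optimality
  under its swap neighborhood, with global optimality verified only at
  exhaustively checkable sizes.
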