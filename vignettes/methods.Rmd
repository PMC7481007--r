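---
title: "Minimally dependent subspaces: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimally dependent subspaces: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During a delayed-saccade task with an intervening distractor, lateral
prefrontal (LPFC) population activity holds two kinds of information at
once: the remembered target location (working memory, present from target
offset to the saccade) and the upcoming movement plan (motor preparation,
arising once the last sensory event — distractor offset — makes the timing
of the Go cue predictable). A decoder trained on Delay-1 activity fails on
Delay-2 activity and vice versa ("code morphing"), yet the information
itself is stable. This package implements the decomposition that explains
the morphing: the two delays' condition-mean activity patterns are a 2x2
mixture of two underlying *elements* — one for memory, one for
preparation — that are minimally statistically dependent on each other.

## The mixing model and its estimator

For each of the `k` analysed target locations, trial- and time-averaged,
baseline-subtracted activity gives two neurons x conditions matrices,
`D1` (Delay 1) and `D2` (Delay 2). The model is

    D1 = M + a P
    D2 = b M + P

with scalar mixing coefficients `a` (fraction of preparation activity
already present in Delay 1) and `b` (fraction of memory activity
persisting into Delay 2). The diagonal is fixed at one because a global
rescaling of either element changes nothing statistically, so only the
ratios are identifiable. Inverting the system for a candidate `(a, b)`
(`unmix_pair()`) gives candidate elements; `fit_mixing()` searches for the
pair whose flattened elements have the least mutual information.

MI is estimated by discretising each flattened element into equal-width
bins over its own range — the bin count follows Sturges' rule,
`ceiling(1 + log2(N))`, a deliberately conservative choice that keeps all
bins populated at the `N = neurons x conditions` sample sizes involved —
and summing `p(x, y) log2(p(x,y) / (p(x) p(y)))` over non-empty cells of
the joint histogram. Because the bins are range-relative, the estimate is
invariant to affine rescaling of either argument; a constant input is
defined to carry zero information (with a warning). Equal-frequency
binning is available as an option (`binning = "frequency"`).

**Optimizer.** The histogram objective is piecewise constant in `(a, b)`,
so derivative-based search is unreliable. `fit_mixing()` therefore runs a
coarse grid scan (default step 0.02 over the default bounds
`[-0.5, 1.5]`) and many randomly initialised Nelder-Mead refinements
(1000 by default, matching the multi-start convention for this problem;
the tests and examples use fewer because the basin structure is coarse and
a few dozen starts find the same optimum). The singular curve `a b = 1`
and the box bounds are enforced by penalty. Restart spreads are reported
both over all restarts and over near-optimal ones, since the two
conventions differ and neither is canonical.

**When is the decomposition identifiable?** This is the most important
statistical caveat in the package. If the true elements are jointly
Gaussian, then *every* `(a, b)` on the curve where the unmixed pair is
uncorrelated produces exactly independent elements — minimum MI is
attained on a whole ridge, and the generative coefficients cannot be
singled out (we verified this directly: under a Gaussian fixture the
fitted coefficients scatter along the predicted ridge). The method works
on neural data because trial-averaged rate tuning is strongly
non-Gaussian (sparse, skewed, rectified). The parametric test generator
(`parametric_ground_truth()`) therefore uses centred-exponential element
entries by default, which restores a unique, correctly located optimum;
the Gaussian variant is kept as an option for studying the degenerate
case. Near the optimum the objective remains a plateau of micro-basins:
optimizer quality should be judged by the attained MI value, not by the
argmin's third decimal.

## Subspaces and their geometry

The orthonormal bases of the column spaces of the fitted `M` and `P`
(`build_subspace()`, thin SVD, singular values below `1e-8` of the
largest treated as zero) define the memory and preparation subspaces.
Because the span of an estimated element gives *unit weight* to every
linearly independent direction — however small its singular value — any
systematic residual in an element surfaces at full strength in decoding.
This matters for the simulators (below).

Geometry tools follow standard constructions: principal angles from the
SVD of the product of the two bases (singular values clamped to `[0, 1]`
before `acos`; the per-rank chance distributions come from orthonormalised
Gaussian matrices); per-neuron loading weights as row norms of a basis
(their squares sum to the subspace dimension); the inter-to-intra cluster
distance ratio as the grand mean of pairwise distances between cluster
means over the grand mean of within-cluster pairwise distances, Euclidean
throughout, bootstrapped with 250 points per cluster by default; variance
explained as the projected fraction of mean-centred variance; and the
orthogonal complement ("null space") of the union span, in which the
time-averaged condition means collapse to numerical zero — the
completeness argument for the two subspaces. The axis-clustering test maps
each neuron's weight pair to `atan2(w_mem, w_prep)` in `[0, 90]` degrees
and bootstraps the fraction beyond 67.5 or below 22.5 degrees with a
random 10% exclusion per draw. Exclusivity flags use the log weight ratio
(symmetric, unlike the raw ratio) at two standard deviations from its
mean.

## Decoding

Cross-temporal decoding trains a linear discriminant at each time bin of
a pseudo-population and tests it at every other bin. Pseudo-populations
treat neurons as independently sampled: per neuron and condition the trial
pool is split at random into two disjoint halves, and train/test
pseudo-trials draw from their own half (with replacement when the half is
smaller than the request), with source-trial indices retained so
disjointness is checkable. The LDA uses class means, a pooled within-class
covariance with a ridge of `1e-6 x trace/dim` (the pseudo-population
regime is near-singular without it), and class-frequency priors. In the
full space the training bin is PCA-denoised to the components explaining
95% of variance (components from the training split only); with a
subspace projection, both splits are instead projected onto the subspace
basis. Time bins default to 100 ms; scalar summaries such as "Delay 1
accuracy" average the grid cells whose train and test bins both fall in
that window. Error-trial decoding fits on correct-trial activity (unmixed
with correct-trial elements and coefficients, per the error formulas) and
reports accuracy on the error set, dropping conditions with no error
trials with a warning.

## Statistics

The bootstrap comparison p-value is `(1 + X)/(N + 1)`. "Overlap" is not
uniquely defined for two samples; the default rule counts points of the
higher distribution at or below the lower one's maximum plus points of
the lower distribution at or above the higher one's minimum, capped at
`N`. Under this rule disjoint distributions give `p = 1/(N+1) < 0.001` at
`N = 1000`, and a configuration in which x% of the points overlap gives
`p ~ x/100`; a threshold-free paired-reversal variant is available and the
counting rule used is recorded on the result. Hedges' g uses the pooled
SD and the small-sample correction `1 - 3/(4(n1+n2) - 9)`.

Selectivity classification runs, per neuron, a two-way
location-by-epoch ANOVA (type-II sums of squares via `car::Anova`, so the
balanced and unbalanced cases agree) on the two delay windows
(800–1300 ms and 2100–2600 ms — the second window deliberately differs
from the 2000–2500 ms unmixing window; both are kept as named epochs and
each analysis uses its own), plus two one-way location ANOVAs. Cells
tuned in Delay 2 but not Delay 1 are `pure_preparation` — this rule is
applied first, because such cells also trip the two-way interaction and
the three classes are meant to be disjoint; then `mixed` (all three
two-way effects), then `pure_memory` (location effect without
interaction). No multiple-testing correction is applied across cells,
matching the per-cell alpha = 0.05 convention. On null neurons the
location effect rejects at the nominal 5% rate; the composite labels have
no single 5% null rate (the two pure classes together reject about 9%
under the null), which is why calibration is asserted on the location
effect itself.

## The synthetic generators

Three generators provide data with known structure.

**Parametric generator** — the direct realisation of the mixing model
with known elements, coefficients, and i.i.d. Gaussian single-trial noise.
It is exact by construction and is the fixture for recovery,
null-space, and algebraic tests (element distribution discussed above).

**Ring bump attractor** — two 80-unit ring populations (memory,
preparation) with a configurable shared fraction, rectangular excitatory
kernels (half-width 5) with uniform within-ring inhibition, eight input
channels of 10 adjacent units each, and the rate dynamics
`tau dr/dt = -r + phi(W r + W_in I + sigma)` integrated by forward Euler
(`tau` 20 ms, `dt` 2 ms) with divisive normalization: after every step all
units are rescaled by `mean(r)/mean(r0)`, so the population-mean rate
equals its baseline exactly, in every bin — the constancy property the
decomposition builds on. The target epoch drives the memory ring at the
target location; the distractor epoch drives the preparation ring at the
*target* location (movement preparation) and the memory ring at the
distractor's different label at 50% strength. Rates convert to Poisson
spike counts at `rate_scale` spikes/s per model-rate unit (default 2,
which places full-space Delay-1 decoding in the noisy ~60% regime rather
than at ceiling); a rates-only output mode bypasses spiking.

The activation is piecewise: 0 below 0, `x^2` on `[0, 1]`, and an upper
branch above 1. `phi()` defaults to the linear branch `4x - 3`, but the
attractor configuration defaults to the saturating branch
`sqrt(4x - 3)` (both equal 1 at the knot): with the linear branch a
bump's effective gain grows with its height (`phi(kh)/h = 4k - 3/h`), so
two bumps sharing one normalization pool are mutually unstable and the
distractor-epoch preparation bump extinguishes the memory bump — the
saturating branch makes the two-bump state an attractor, which is the
regime the decomposition describes. Kernel amplitudes
(`w_plus = 0.2`, `w_minus = -0.02`), input amplitude (0.8), and noise SD
(0.05) were calibrated once so a 10-unit input ignites a bump that
persists with a stable peak through both delays, and then frozen.

What the bump model does *not* deliver: its Delay-2 memory component is
not an exact scalar multiple of the Delay-1 component. The bump's
equilibrium profile changes with its normalization-rescaled height (the
activation is not homogeneous), and the 50%-strength distractor input
perturbs the memory ring, leaving a residual that shrinks only slowly
with trial count. Since subspace construction weights every independent
direction equally, this residual direction enters the preparation
subspace at unit weight, and Delay-1 memory activity remains decodable
there well above chance at any signal-to-noise level where memory
decoding itself works. The acceptance suite asserts the at-chance
expectation anyway and documents the miss; treat preparation-subspace
Delay-1 decoding on bump data as a known model-mismatch diagnostic, not a
bug in the unmixing. Passing results on this simulator therefore
demonstrate the full pipeline's behaviour under approximate — not exact —
scalar mixing, which is also the realistic regime.

**Linear subspace model** — 112 linear rate units with
`W = Q Lambda Q^-1`, 17 unit eigenvalues (1 baseline + 8 memory + 8
preparation stable directions; the rest uniform on (0,1)). Structured
eigenvectors follow the generating recipe (baseline entries uniform on
(0,1), memory/preparation entries uniform on (1,2), hence positive-mean
preparation directions whose arrival in Delay 2 engages the
normalization and lowers memory decodability); the bulk eigenvectors come
from a scaled random orthogonal frame rather than raw Gaussians, because
an ill-conditioned `Q` makes `W` strongly non-normal with realisation-
dependent transient amplification. Inputs are injected along the stable
eigenvectors (`input_amp = 0.1` for 300 ms contributes an eigen-
coefficient of about 1.5, comparable to baseline), so deposited
information persists exactly — this is the generator for which scalar
mixing holds to numerical precision. Its all-positive eigenvector
families do, however, share row structure through the normalization,
which dominates the histogram-MI objective; the package's tests
therefore assert the model's dynamical claims (eigenvalue count,
eigen-direction persistence, the normalization-driven decrease of memory
decoding from Delay 1 to Delay 2 in the generative memory subspace)
rather than coefficient recovery on this generator.

Neither simulator models error trials (the task model has no failure
mode); error-trial analyses are exercised on degraded inputs —
label-permuted or noise-inflated copies of correct trials — which
separate the two readings of an error-trial decoding drop (specific
information loss vs non-specific noise increase) exactly as the
intra-cluster variance control does on real data.

## Containers and sizes

Datasets are trials x neurons x time-bins spike-count tensors with a
per-trial table (target, distractor, outcome, saccade onset), written to a
plain-text dataset directory (`counts.csv`, `trials.csv`, `meta.yaml`) —
integer counts round-trip bit-exactly. Epoch windows are half-open
`[start, end)` intervals in ms relative to target onset (the pre-saccade
window, 150–0 ms before saccade onset, is aligned per trial). Rates are
counts scaled to spikes/s before averaging.

Test and example problem sizes are deliberately modest — tens of trials
per condition, one or two pseudo-population repeats, a few hundred
bootstrap draws — chosen so the full suite exercises every stage,
including two complete simulate-unmix-decode pipelines, in a few minutes;
the defaults exposed on each function (1000 restarts, 1000 bootstraps,
100 decoding repeats, 250 pseudo-trials per condition) are the
full-strength settings a real analysis would use.

## Known limitations

- The 2x2 mixing model assumes each element is common to both delays up
  to a scalar; dynamics that reshape a representation (as the bump
  attractor does mildly) violate this and leak into the complementary
  subspace — see above.
- Histogram MI at Sturges resolution has an intrinsic displacement of the
  optimum of a few hundredths in `(a, b)` at the 226 x 7 scale;
  reported coefficients are conventionally rounded to two decimals.
- Pseudo-populations destroy within-session noise correlations by
  construction; nothing here speaks to simultaneous-recording structure.
- The uncorrelated-label generalisation pairs element entries through
  every (neuron, label-1, label-2) cell with positive joint probability;
  with unequal label cardinalities other pairings are conceivable, and
  only the one-to-one special case has a closed-form reduction (to the
  paired 2x2 model) that pins the convention down.
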