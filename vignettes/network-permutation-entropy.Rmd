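---
title: "Network permutation entropy: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network permutation entropy: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npentropy)
```

## The model

All statistics in this package start from the same front end. A series
`x(1..N)` is embedded at unit lag into `N-d+1` overlapping vectors
`X(i) = (x(i), ..., x(i+d-1))`. Each vector is reduced to its ordinal
pattern — the permutation of indices that sorts it into increasing order —
so amplitude information is discarded and only the relative ordering
survives. Permutation entropy (PE) is the Shannon entropy of the pattern
frequencies, normalized by `ln(d!)`; weighted PE (WPE) replaces unit counts
with the vector's population variance; improved PE (IPE) quantizes
amplitudes into `L` levels so each vector becomes one of `L^d` words,
normalized by `ln(L^d)`.

These pattern-pooling statistics treat vectors as independent draws. The
network permutation entropy (NPE) instead asks whether a vector *recurs*:
vector `i` is connected to the first earlier vector with the identical
pattern whose signed variance weight lies within a tolerance `error`, and
the earlier node's score is incremented from a tiny floor (`1e-5`). After
the scan, the scores are normalized into a node distribution `P` and

$$\mathrm{NPE} = -\frac{1}{\ln(N-d+1)} \sum_i P_i \ln P_i.$$

A periodic series revisits the same few (pattern, weight) states, so all
mass accumulates on at most period-many hub nodes and NPE approaches 0; a
noise-like series rarely recurs at a tight tolerance, the scores stay near
the uniform floor, and NPE approaches 1. The signed weight matters: two
vectors with the same ordinal pattern but opposite skew (interior mean
above vs. below the vector mean) carry weights of opposite sign and will
not connect at a small tolerance.

Assumptions worth keeping in mind: the series is univariate, sampled
uniformly, and long enough that `N-d+1 >> d!`; the embedding lag is fixed
at 1; and the tolerance is expressed in the units of the signal's
*variance*, so it must be rescaled as `a^2 * error` if the signal is
rescaled by `a` (this covariance is asserted as a test property).

## Tunable parameters

* **`d` (embedding dimension)**, integer 3–9. The interior-mean sign rule
  needs at least one interior element, so `d >= 3`; base-10 pattern codes
  are collision-free only for `d <= 9`. Practical work uses 3–7; sweeps
  default to `d = 5`. For `d = 3` the interior is the single middle
  element — the literal reading of the rule, confirmed by reproducing all
  ten signs of the worked example's weight list.
* **`error` (weight tolerance)**, same units as the signal variance,
  `>= 0`. Smaller values make connections rarer and push NPE up. The
  package default is 0.005, appropriate for signals of order unity and
  length ~10^3; long-series reference computations use 0.0005. Because
  every result depends on it, all output paths echo it.
* **`L` (IPE levels)**, integer `>= 2`, default 4. Larger `L` makes IPE
  more amplitude-sensitive at the cost of a sparser word distribution.
* **`score_floor`**, default `1e-5`. Keeps never-matched nodes at a tiny
  positive probability so the entropy sum is well defined; exposed as an
  argument but there is no reason to change it in normal use.

## Tie-breaking and other numerical choices

* **Equal values** in a vector are ranked by original position (stable
  sort, earlier index first). This makes `(4,5,4)` the pattern `132` and an
  all-constant vector the identity pattern.
* **Weight comparison** uses the absolute difference
  `|w_i - w_j| <= error`. A one-sided reading would connect every pair with
  `w_i < w_j` regardless of distance, which contradicts both the worked
  example and the periodic-series reference values.
* **First match** means the scan continues past same-pattern vectors that
  fail the weight test; it stops only when both conditions hold. Only the
  earlier node's score is incremented; the later node can never be matched
  by a future scan anyway (any future vector reaches the earlier hub
  first), a fact asserted as a test property rather than assumed.
* **Logarithms** are natural throughout; normalized entropies are
  base-invariant, and `0 ln 0 := 0`.
* **IPE quantization**: bin width `Delta = (max - min)/L`, the top bin
  closed (the maximum maps to `L-1`); relative symbols
  `S_k = S_1 + floor((x_k - x_1)/Delta)` clamped to `[0, L-1]`. Floor is
  the only reading that keeps the first column integer-valued.
* **Degenerate inputs** raise errors rather than silently returning 0: a
  constant signal has no quantization range (IPE) and zero total weight
  (WPE), and a series shorter than `d` cannot be embedded.
* **Scan complexity**: candidates are indexed by pattern code so each
  vector only scans same-pattern predecessors, in order. The output is
  contractually identical to the naive all-pairs scan, which the test suite
  checks edge-for-edge on a randomized corpus of signals of length <= 30.

## Signal generators

The generators are deterministic fixtures standing in for classes of real
signals: `periodic_signal()` (regular rhythms), `random_signal()` (i.i.d.
uniform noise, the only seeded generator), `logistic_series()` (discrete
chaos, `x <- mu x (1-x)`), `simplified_lorenz_series()` (continuous chaos
with a single bifurcation parameter `c`), and `fractional_henon_series()`
(a Caputo fractional-difference map with power-law memory).

Unstated integration details were fixed once as typical values for these
system families and are all configurable: the flow uses fixed-step RK4
(via deSolve) with `h = 0.01`, a transient of 10^4 steps, and initial
state `(0.3, 0.2, 0.1)`; the logistic map starts at `x0 = 0.3` with a
transient of 10^3 (avoiding the measure-zero degenerate orbit through
0.5, which triggers a warning). The RK4 route is checked against a
stage-by-stage hand evaluation of one step and for fourth-order
self-convergence.

The fractional Hénon map is evaluated through its discrete convolution
solution with kernel `phi(k) = Gamma(k+nu) / (Gamma(nu) Gamma(k+1))`,
computed by the multiplicative recurrence
`phi(0) = 1, phi(k) = phi(k-1) (k-1+nu)/k` — stable for long memories,
and accurate to ~2e-13 relative at `k = 10^4` (a direct log-gamma
evaluation is itself only good to ~1e-11 there, which bounds how tightly
the two routes can be compared). At `nu = 1` the kernel is identically 1,
the convolution telescopes exactly to the classic Hénon recurrence, and
the package takes that O(n) path; the full-memory path is O(n^2) and is
capped at `n = 5000` unless overridden. Chaotic sensitivity means the
convolution and recurrence forms agree to fine tolerance only over short
horizons (~30 steps) before rounding differences are amplified; the test
suite checks both regimes at their appropriate horizons.

The Lyapunov-exponent helper for the logistic map clamps the derivative
magnitude at the smallest positive double before taking logs, so
superstable regions report large negative values instead of `-Inf`.

What the synthetic fixtures do *not* emulate: measurement noise on top of
deterministic dynamics, nonstationarity, line artifacts, or the amplitude
distributions of real EEG. Passing the suite demonstrates the estimators'
correctness and their discriminative ordering on clean signal classes —
noise above chaos above periodicity — not clinical performance on
recordings.

## Drivers

`sliding_profile()` computes the chosen entropy independently per window
(`floor((N - window)/step) + 1` windows, each fully inside the signal; NPE
networks never span windows). The window count is always derived from the
actual series length rather than fixed, since archive segment lengths vary.
`sweep_1d()`/`sweep_2d()` regenerate a fresh series per grid cell with
inclusive endpoints (a count can be given instead of a step when a
specific grid size is wanted); cells whose trajectory diverges are flagged
`NA` rather than aborting the sweep, and cells are pure functions of their
parameters, so evaluation order is irrelevant.

## Problem sizes in the test suite

The reference regression uses the period-5 series at its published length
(20,480 samples, `d = 3..6`). Property checks run on short signals
(corpus of lengths 10–30 against the brute-force network oracle),
Lyapunov estimation on 10^5 iterates, and the qualitative sweep
reproductions on deliberately coarse grids: a 22-point logistic `mu` sweep
at series length 10^3 and an 11x11 `(a, nu)` Hénon plane at length 500.
These sizes were chosen as the smallest grids on which the claimed
qualitative contrasts (periodic window below the chaotic band; elevated
complexity toward `nu = 1` at chaotic `a`; noise-vs-periodic NPE gap
> 0.3) are stable and visible.

## Known limitations

* Patterns ignore ties' amplitudes entirely; heavily quantized signals
  with massive tie fractions funnel into few patterns and can depress all
  pattern-based entropies.
* The tolerance is absolute, so NPE values are comparable across signals
  only after variance normalization or with a tolerance chosen per signal
  scale.
* The O(n^2) worst case of the network scan (all vectors sharing one
  pattern at a loose tolerance) is mitigated but not removed by pattern
  indexing.
* Fractional-order sweeps are qualitative: initial conditions and step
  sizes for the published parameter planes are not uniquely determined, so
  only the shape of the complexity landscape, not per-cell values, is
  reproducible.
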