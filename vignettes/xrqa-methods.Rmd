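---
title: "Cross-recurrence quantification with xrqa: models, parameters, design"
author: "xrqa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-recurrence quantification with xrqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrqa)
```

## The model

Cross-recurrence quantification analysis (CRQA) treats two time series as
trajectories of two systems and asks where, and with what temporal
structure, one system revisits states the other has visited. Where
cross-correlation summarises *co-variation* of two signals, cross-recurrence
summarises *co-visitation*: the density and geometry of the set of time-index
pairs (i, j) at which the two trajectories come close.

The pipeline is:

1. **Delay embedding.** A scalar series $X(t)$ is unfolded into
   $m$-dimensional delay coordinates
   $(X(t), X(t+\tau), \dots, X(t+(m-1)\tau))$, reconstructing a phase space
   from one measurement channel. `embedSeries()` produces the
   $T-(m-1)\tau$ reconstructed points.
2. **Distances and thresholding.** The Euclidean distance between every
   point of series 1 and every point of series 2 is compared with a radius
   $\varepsilon$; cell $(i, j)$ of the cross-recurrence plot is recurrent
   when $D_{ij} \le \varepsilon$ (`crossRecurrenceMatrix()`). Categorical
   sequences use $m = 1$, $\tau = 1$ and a radius near zero (0.001 by
   default), so that exactly the identical-state pairs recur.
3. **Quantification.** From the maximal runs of recurrent cells along
   diagonals (offset $d = j - i$ constant) and verticals (column constant),
   `rqaMeasures()` computes the seven classical measures: recurrence rate
   (RR), determinism (DET), mean and maximal diagonal line length (L,
   Lmax), diagonal length entropy (ENTR, natural log), laminarity (LAM)
   and trapping time (TT).

One sign convention holds everywhere: profile lag $\ell$ compares $x(t)$
with $y(t-\ell)$, so **negative lags mean series 1 leads series 2**, and a
recurrent point on plot diagonal $d$ contributes to lag $\ell = -d$. A
confederate driving a participant with a one-step delay therefore peaks at
$\ell = -1$, and the same convention is used by the diagonal recurrence
profile, the contingency stack, the phi profiles and the cross-correlation
profile, so their argmax lags are directly comparable.

## Parameters that matter

* `delay` ($\tau$, samples) and `embedDim` ($m$, count): phase-space
  reconstruction. Defaults are 1 and 1 — correct for categorical
  sequences; continuous data should use `optimizeParams()` (below).
* `radius` ($\varepsilon$, in the units of the distance matrix): the
  neighbourhood size defining recurrence. Default 0.001, the categorical
  exact-match limit. For continuous data a radius achieving a 2–5%
  recurrence rate is the conventional working range.
* `rescale`: optionally divides the distance matrix by its mean (or
  maximum) and expresses it in percent, making radii comparable across
  datasets with different amplitude scales. Default `"none"`; whether a
  given published radius assumes rescaled distances varies between tools,
  so the choice is explicit rather than implied.
* `normalize`: optional per-series z-scoring before embedding, default
  `"none"` (categorical data are never z-scored).
* `theilerWindow` (tw, diagonals): masks $|j-i| \le tw - 1$; `tw = 1`
  removes exactly the main diagonal. Intended for auto-recurrence, where
  trivial self-neighbourhood inflates the line structure; for
  cross-recurrence of two distinct series the default 0 is appropriate
  because the line of coincidence is exactly the synchrony being measured.
* `minline` (samples, default 2): minimum run length for DET, L, Lmax,
  ENTR, LAM, TT.

Degenerate plots are a result, not an error: an empty matrix reports
RR = DET = LAM = ENTR = 0 and L = Lmax = TT = NaN. NaN (not 0) is used for
the undefined means so that averaging over windows cannot silently dilute.

## Lag profiles and windowed analysis

`diagonalRecurrenceProfile()` computes the recurrence rate per lag over
$\ell \in [-W, W]$, dividing by the number of valid comparisons
$T - |\ell|$ at each lag (a fixed-$T$ denominator would deflate the edge
lags). Ties for the maximum resolve to the smallest absolute lag, then the
negative one, so output is deterministic. For event sequences,
`excludeNonevent` drops pairs where *both* series sit in the named
non-event state from the numerator: recurrence then counts co-occurring
events rather than shared silence, which otherwise dominates sparse event
series.

`windowedRecurrenceProfile()` tracks coupling over the time course: in
windows of `windowSize` advanced by `step`, the within-window profile over
$\pm$`lagWindow` is averaged into one value per window. The lag window
must be smaller than the window itself; trailing partial windows are
dropped rather than padded. `windowedCRQA()` instead computes all seven
measures per window; a degenerate window yields NaN measures without
aborting the sweep.

`contingencyStack()` gives the categorical-series view: per lag, an
$S \times S$ table counting state co-occurrences. Its diagonal sum over
the states shared by the two series, divided by the table total,
reproduces `diagonalRecurrenceProfile()` exactly (this dual-path identity
is asserted in the test suite over random inputs). The state list is the
union of both alphabets with shared states first; states unique to one
series can never contribute matches but remain as "not-k" mass for
`phiProfile()`, which collapses each table to 2x2 over $\{k, \neg k\}$ and
applies the Pearson phi coefficient
$\phi = (ad-bc)/\sqrt{(a+b)(c+d)(a+c)(b+d)}$. The qualitative behaviour
required of a per-state association measure — increasing in matched visits
to $k$ and to $\neg k$, decreasing in mismatches — identifies phi only up
to monotone transformation; Pearson phi is used because it is the
established 2x2 coefficient with exactly those monotonicities.

## Parameter selection for continuous series

`optimizeParams()` composes three steps, each also available separately:

1. **Delay** (`amiDelay()`): average mutual information between $x(t)$ and
   $x(t+\ell)$ from a 10-bin equal-width 2-D histogram (bin count
   exposed; 10 is a conventional coarse default that keeps the estimator
   stable at a few hundred samples). The selected delay is the first
   *prominent* local minimum: lower by 1% of the curve's range than every
   value within three lags on either side. The prominence requirement
   exists because a noiseless quantized signal produces micro-dips on the
   steep initial descent of the AMI curve that are artifacts of binning,
   not minima of the underlying curve. If no minimum exists the first lag
   where the onward decrease falls below `levelTol` (default 5% of
   AMI(0)) is used — for structureless noise this correctly returns 1.
   The two series' delays are merged by `combineDelays()`: the rounded
   mean when they are within a factor of 2 of each other, otherwise the
   larger (both thresholds exposed; the factor-2 reading of "considerably
   longer" is an interpretation).
2. **Dimension** (`fnnEmbedding()`): Kennel-style false nearest
   neighbours with distance-ratio tolerance 10 and acceptance fraction 5%
   (the standard constants). The first dimension whose false-neighbour
   fraction drops below the cutoff, or at which the fraction stops
   decreasing, is selected, and the larger of the two series' dimensions
   is kept. Separations at floating-point noise level relative to the
   signal scale are treated as exact revisits, not false neighbours;
   without this guard a noiseless periodic signal mislabels its exact
   revisits. The neighbour search uses at most `maxPoints` (default 1000)
   leading phase-space points, bounding the quadratic cost.
3. **Radius** (`radiusSearch()`): a deterministic grid of `nSamples`
   (default 20) equally spaced radii spanning from zero up to the
   distance-quantile at which roughly `startRR` = 25% of cell pairs
   recur, evaluated exactly (by sorted-vector counting in one dimension,
   blocked accumulation otherwise — the full distance matrix is never
   materialized). Candidates are scanned from the smallest radius upward
   and the first with recurrence rate inside `targetRR` (default 2–5%)
   is returned; scanning upward makes the result monotone under widening
   of the target band. If the grid steps over the band, the bracketing
   interval is re-sampled at finer granularity up to `maxRounds` (3)
   times; an unreachable band raises an error carrying the full
   evaluation trace. The grid is deterministic, so no seed is involved.

For two independent standard-normal series the searched radius can be
checked against a closed form: $RR(r) = 2\Phi(r/\sqrt{2}) - 1$, so a 2–5%
band corresponds to radii in $[0.0355, 0.0887]$. The acceptance tests
verify the search lands inside this band at $T = 10000$.

## The coupled-agent simulator

`simulateCoupledBinary()` generates the two-agent system used throughout
for validation: a confederate C emits a binary event with base rate `pC`
or repeats its previous event with probability `pCC`; a participant S
responds to C's event with probability `pSC`, emits spontaneously with
`pS`, or repeats with `pSS`. Each rule draws its own uniform variate.
Defaults are the high-coupling study condition: `pC = 0.25`, `pS = 0.05`,
`pCC = pSS = 0.05`, `pSC = 0.33`, 1000 steps; the low condition sets
`pC = 0.05`.

S responds to C's *previous* step by default (`coupling = "previous"`).
A same-step reading of the generating rules is also defensible and is
available behind `coupling = "same"`; the previous-step default is chosen
because the system it is meant to emulate is explicitly a leader–follower
pair with a one-step lead, which only the previous-step variant produces
(the coupling peak then sits at lag −1 on both the cross-correlation and
the recurrence profile).

C's event rate has the two-state Markov stationary value
$p_C / (1 - (1-p_C)\,p_{CC})$, used as a calibration oracle in the tests.

What the simulator emulates — and what it does not: it produces sparse,
weakly autocorrelated, unidirectionally coupled event series. Real
behavioral series add bidirectional coupling, non-stationarity, richer
state alphabets and measurement noise; passing the simulator-based tests
therefore validates the machinery (sign conventions, counting,
denominators, seeding), not the empirical adequacy of CRQA for any
particular dataset.

```{r simulated-example}
sim <- simulateCoupledBinary(seed = 42)
drp <- diagonalRecurrenceProfile(sim$C, sim$S, maxLag = 5,
                                 datatype = "categorical",
                                 excludeNonevent = "0")
drp
```

## Numerical choices and degenerate inputs

* Distances use the quadratic-form expansion with clamping of small
  negative squares; exact-match semantics for identical one-dimensional
  values are preserved exactly.
* Recurrence matrices are stored as sparse coordinate patterns
  (`Matrix::ngCMatrix`); dense distance matrices are refused above a size
  guard (`options(xrqa.maxDense = )`, default 4000) so a mistyped length
  cannot exhaust memory.
* RR's denominator is always the full matrix area, also under a Theiler
  mask (masked cells count as non-recurrent): the simplest contract
  consistent with RR as plot density.
* ENTR uses the natural logarithm; with a single distinct qualifying line
  length it is exactly 0.
* A Theiler window at least the matrix size, a lag window at least the
  comparable length, radius < 0, non-finite values in continuous input,
  and disjoint categorical alphabets are rejected with explicit errors;
  empty recurrence sets and all-excluded numerators are legal results.
* Unequal-length series: matrix construction runs on the full rectangle;
  profile and contingency operations truncate to the common overlap.

## Problem sizes in the validation suite

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under a minute while keeping every check
statistically meaningful: 20 simulator runs of 1000 steps for the
coupling-lag and calibration checks, 20 random pairs of length up to 200
(dimensions 1–3) for the exact agreement between the vectorized pipeline
and a loop-based reference (mean absolute difference below $10^{-9}$ per
normalized measure), 50 random categorical pairs for the
contingency/profile identity, and $T = 10000$ for the Gaussian radius
band. These sizes are the package's own validation design, documented
here so that results are reproducible as stated.

## Known limitations

* Euclidean distance only; no joint recurrence, recurrence networks or
  order-pattern variants.
* The line-measure extraction assumes the Theiler mask has already been
  applied; masked cells simply do not appear as recurrent.
* `amiDelay()`'s histogram estimator is biased upward for short series;
  with fewer than a few hundred samples the FNN step, not AMI, usually
  dominates parameter quality.
* The radius search targets a recurrence-rate band — it is a working
  heuristic, not a theoretically optimal radius selection.
* Inference (surrogate pairs, shuffling baselines, growth-curve modeling
  of profiles) is out of scope; the package produces the descriptive
  quantities such approaches would consume.
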