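---
title: "Calibrating agent-based cell models with multilevel grid sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating agent-based cell models with multilevel grid sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcalib)
```

## The calibration problem

Agent-based simulators of cell populations are configured through an XML
settings file and observed through snapshots of cell positions. Their
parameters — speeds, biases, rates — rarely map one-to-one onto measurable
quantities, so they are fitted by comparing simulation output against
target data. Because the models are stochastic and expensive, and gradients
of their outputs are unavailable or meaningless, `cellcalib` treats the
simulator as a black box $m(\theta)$ and fits two parameters at a time by a
derivative-free grid search with iterative refinement.

The objective is the summed squared error
$\mathrm{SSE}(\theta) = \sum_i (m(\theta)_i - y_i)^2$ against the target
vector $y$. Two alignment rules are available:

* **paired** (`"sse"`): entries are compared positionally. Appropriate when
  both vectors are indexed by the same grid, e.g. population counts over
  time.
* **sorted** (`"sse_sorted"`): both samples are sorted ascending before
  differencing (for equal sizes), or reduced to 21 empirical quantiles at
  0, 5, …, 100% (for unequal sizes). Final cell positions have no natural
  pairing between simulation and target; sorting makes the comparison
  permutation-invariant — a quantile-matching distance between the two
  empirical distributions. This pairing rule is this package's choice, not
  a community standard; users comparing positional data should be aware the
  metric sees only the marginal distribution of the chosen coordinate.

## The multilevel sweep

Level $k$ spans, on each axis $j$, the interval
$[c_j(1-p_k),\, c_j(1+p_k)]$ around the current center $c$ with $n$
linearly spaced points (endpoints included), clipped to the parameter
bounds. All $n^2$ cells are evaluated; the first argmin in row-major order
(axis 1 outer) becomes the next center, and the range fraction shrinks
geometrically, $p_{k+1} = s \, p_k$.

Tunable parameters, their defaults and the reasoning:

* `points_per_direction` ($n$): no default; 5–8 is typical. Cost grows as
  $n^2$ per level.
* `percent_per_direction` ($p_1 \in (0,1]$): the initial relative search
  range; 0.5 means ±50% around the initial guess.
* `shrink_factor` ($s = 0.5$): constant range cannot refine, so the range
  halves each level by default. Larger $s$ is safer when the initial guess
  may be poor (the basin must stay inside the shrinking window), smaller
  $s$ converges faster when it is good.
* `lower_bounds` (`c(0, 0)`) and `upper_bounds` (unbounded): grid values
  are clipped, never rejected. Rates, speeds and capacities are nonnegative,
  hence the default floor; a migration bias needs `upper_bounds` of 1,
  otherwise refinement around a best point near 1 would propose invalid
  values. An axis whose points all clip to one value collapses to a single
  point with a warning.
* `replicate_aggregation` (`"mean"`, or `"median"`): replicate metric
  vectors are combined elementwise per grid cell *before* the error is
  computed. The black box itself never aggregates — it returns one metric
  per replicate — so other schemes can be layered on top.

Numerical and degenerate-input choices:

* The multiplicative range means a center at 0 spans a zero-width interval;
  that axis collapses (warning) rather than erroring, and the sweep
  continues in one dimension.
* With an even $n$ the current center is not itself a grid point; this is
  accepted as-is (an $8 \times 8$ level has no center cell).
* Ties are broken by the first minimum in row-major order, deterministically.
* A failed simulation scores $+\infty$ with a warning instead of aborting
  the level; only a level where *every* cell fails is an error.
* Settings-file edits serialize numbers with full round-trip precision
  (shortest decimal that reparses to the same double), so no precision is
  lost across levels; target CSVs are written the same way.

### Seeds and reproducibility

Every grid cell at every level is evaluated with the same base seed, and
replicate $i$ within a cell uses seed $+\,i-1$ (for external executables
the seed is exported as the `CALIB_SEED` environment variable). Sharing the
base seed across cells is a common-random-numbers scheme: the stochastic
error surface becomes a deterministic, smooth function of the parameters,
which is what a grid comparison needs. Target data generated by the fixture
models take their own, separate seed — target data play the role of
experimental observations and never share randomness with calibration
runs. A full sweep is bitwise reproducible given its configuration and
seed.

## The settings schema

`load_config()` validates every modeled numeric field at parse time:
domain voxel lengths `dx`, `dy`, `dz` strictly positive and each maximum
above its minimum; overall times and time steps positive; substance
diffusion/decay/initial/boundary values positive; cell volume, mechanics
and motility fields positive except `fluid_fraction`, `calcified_fraction`
and `migration_bias`, which live in the closed interval $[0, 1]$; cycle and
death phase lists elementwise positive. One reading decision: the domain
row of the upstream constraint tables lists the voxel lengths as
"dx/dy/dt"; this package reads the third entry as `dz` — a voxel has three
lengths, and a time step in the domain block has no meaning. Cycle and
death models may specify either phase durations or phase transition rates;
the parser accepts whichever the file provides (per death model), leaves
the other list empty, and rejects files providing both for the same model,
since the two parameterizations are redundant.

Everything outside the schema — `user_parameters`, `custom_data`, units
attributes, comments — is preserved verbatim on write-back: the tool edits
the file, it does not own it.

## What the fixture models emulate — and what they do not

The package must be testable end-to-end without a compiled simulator, so it
ships two generators whose defaults define the reference study conditions.

**Logistic growth**: $N(t) = K N_0/(N_0 + (K-N_0)e^{-rt})$ with $N_0 = 10$
and observation grid $t = 0, 1, \ldots, 100$ (time units). Deterministic,
instant to evaluate, and exactly recoverable: a sweep whose grid contains
the generating $(r, K)$ scores zero there.

**Chemotaxis**: $n = 100$ cells in a $500 \times 500$ µm domain, started
10 µm off the low-y wall, walking for 120 min at `dt` = 0.1 min with
persistence time $\tau$ = 1 min under a static linear gradient pointing
+y. Direction per step: $d = \mathrm{normalize}((1-b)\xi + b\hat g)$, with
the random unit vector $\xi$ redrawn with probability $dt/\tau$ per step.
These sizes were chosen so that the reference regime (speed 2 µm/min, bias
0.9) carries cells across roughly half the domain — far from both walls.
The discretization requires $dt \le \tau$; coarser steps are rejected.

The fixtures deliberately omit almost everything a real simulator does:
no cell mechanics or volume exclusion, no proliferation or death coupled to
the walk, no reaction–diffusion solve (the gradient is static), and
deterministic starting positions. Passing tests therefore demonstrate that
the *calibration machinery* — config editing, black-box plumbing, snapshot
quantification, grid refinement — is correct, not that any particular
biological simulator is identifiable or well-calibrated by these settings.

### A worked identifiability limitation

The chemotaxis fixture exposes a genuine and instructive failure mode of
final-position calibration. The mean displacement along the gradient is
$\mathrm{speed} \cdot f(b) \cdot \mathrm{duration}$, where $f(b)$ is the
mean +y component of the normalized direction. At high bias with short
persistence time the *spread* of final y across the population is tiny
(direction fluctuations average out over 1200 steps — fractions of a
micron at $b = 0.9$), so the observed distribution is close to a point mass
at the mean: the data effectively identify only the product
$\mathrm{speed} \cdot f(b)$. All parameter pairs along that ridge fit
almost equally well, and the sweep converges onto whichever ridge point its
refinement path reaches — systematically trading higher speed against
lower bias (or vice versa), at any seed. The package's regression tests
assert the qualitative behavior that *is* identifiable (mean final y
strictly increasing in bias and in speed; deterministic limit at $b = 1$;
zero drift at $b = 0$), and the sweep machinery itself is verified against
exhaustive enumeration on synthetic surfaces where the minimum is unique.
The practical lesson for users calibrating real motility models is to pick
observables that break such ridges — e.g. displacement at several time
points, or both coordinate axes — before trusting a two-parameter fit.

## Problem sizes in the test suite

The suite runs the logistic example at full size (7 levels × 64 cells,
101-point curves — it is closed-form), the chemotaxis example at its
reference size (4 levels × 25 cells of 100-cell simulations), Monte-Carlo
symmetry checks at 1500 cells × 600 steps, and the exhaustive-argmin
cross-check over 100 random grids. These sizes keep the full suite under
half a minute on one CPU while leaving no stage of the pipeline untested at
its documented defaults.

## Known limitations

* Exactly two parameters per sweep; the refinement geometry is defined on a
  plane. Higher-dimensional calibration belongs to external optimizers,
  for which `black_box` objects are a ready-made objective.
* Greedy recentering can lose a basin that falls outside the shrunken
  window of a later level; there is no backtracking. A larger
  `shrink_factor` or an extra coarse level is the remedy.
* The multiplicative range geometry degenerates when an initial parameter
  is 0 (that axis never expands); recenter slightly off zero instead.
* The snapshot reader handles the tabular CSV dialect only; binary cell
  matrices produced by some simulators must be converted upstream.
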