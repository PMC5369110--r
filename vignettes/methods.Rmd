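---
title: "Methods: cluster detection, exposure comparison and purpose estimation for intersection-level cycling counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster detection, exposure comparison and purpose estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclexposure)
```

This vignette is the package's own account of its models and of the design
choices made where the methodology was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The data model

The atomic observation is a **node**: a street intersection with projected
coordinates, an all-purpose cycling activity count and a commuting activity
count for a reference year. Crowdsourced aggregates of this kind contain
invalid records; `clean_nodes()` removes nodes with a zero total and nodes
whose commuting count exceeds the total, and `infer_noncommute()` derives
the non-commuting count as the difference. Cleaning is idempotent and order
preserving, and commuting + non-commuting = total at every clean node.

Nodes aggregate to an **areal partition** (the analog of census output
areas) by point-in-polygon assignment. A point on a shared boundary is
assigned to the containing polygon with the lexicographically smallest id —
a deterministic, input-order-independent tie-break; a point outside every
polygon is unassigned. Pollutant concentrations live on a **1 km × 1 km
grid** of annual-mean PM₁₀ and PM₂.₅; a grid cell enters the study region
only when strictly more than half of its area lies inside the boundary (a
cell at exactly 50% is excluded — the rule is a strict inequality). Nodes
outside every retained cell are excluded from exposure statistics rather
than imputed, since no defensible imputation rule exists for a 1 km
background field.

Contiguity is **queen**: two areas are neighbors iff their boundaries share
at least one point, the usual convention for irregular census geographies
and the more inclusive of the two standard rules (rook would drop corner
contacts). All geometry is planar in projected meters — at city scale,
geodesic corrections are far below the 1 km grid resolution.

## 2. Cluster detection: Gi\* and AMOEBA

The attribute is the per-area **non-commuting rate**
`num_non/(num_non + num_com)`, undefined for areas without activities;
undefined areas are removed before clustering and reported separately. For
a study region *M* of *N* areas with values *x*, mean x̄ and standard
deviation *S*, a candidate region *R* of *n* areas scores

$$G^*(R) = \frac{\sum_{i\in R} x_i - n\bar{x}}{S\sqrt{(Nn - n^2)/(N-1)}}.$$

*S* is the population (divisor-*N*) standard deviation, the standard
Getis–Ord convention.

**Growth.** From each seed area, in each direction (high/low), the
algorithm repeatedly sorts the region's outer neighbors by value
(descending for high, ascending for low; ties broken by area id for
determinism), evaluates adding each *prefix* of the sorted list, adopts the
prefix that most improves G\* and stops when no prefix improves it. The
prefix device is what makes growth over thousands of areas tractable; it
is greedy, so the grown region is a lower bound on the best contiguous
region. The test suite quantifies the gap by exhaustive enumeration on 2×4
lattices: the best-over-all-seeds greedy region attains the global
contiguous optimum in ≈96% of random three-valued configurations and never
exceeds it.

**Significance.** Each candidate's p-value is Monte-Carlo: values are
permuted uniformly over all areas, the region's |G\*| recomputed, and
`p = (1 + #{|G*_perm| ≥ |G*_obs|})/(n_perm + 1)` — never zero, two-sided in
magnitude, deterministic given the seed. Since x̄ and S are permutation
invariant, a permutation reduces to drawing a uniform n-subset of the value
multiset, which is how it is computed. Defaults are 999 permutations and
α = 0.01. Under a uniform null this estimator is super-uniform
(Pr(p ≤ 0.05) ≤ 0.05 up to Monte-Carlo error), which the suite checks with
10⁴ replicates.

**Solution assembly.** Candidates with p < α are ranked by |G\*|; a kept
ecotope excludes every later candidate sharing any area (the published
analyses report disjoint mapped clusters but no resolution rule — greedy
by strength is the simplest deterministic one). Kept high ecotopes get
solution values +1, +2, …, low ecotopes −1, −2, …; everything else 0, and
`classify_solution()` maps sign to high/outside/low.

## 3. Exposure comparison

Without trip durations, inhaled dose cannot be computed; the exposure
concept is **instantaneous**: each activity inherits the annual-mean
concentration of the cell containing its node. Per-purpose means are then
activity-count-weighted means over nodes, and the **high-exposure
percentage** is the activity fraction in cells whose annual PM₂.₅ strictly
exceeds the WHO guideline of 10 µg/m³ (a cell at exactly the guideline is
not high). The WHO PM₁₀ guideline (20 µg/m³) is carried in the summary for
reference.

The purpose comparison is a two-sample Wilcoxon rank-sum test on the
activity-expanded samples (each node's concentration repeated by its count
per purpose). Expansion is never materialised: the statistic is computed
from weights via midranks, with the tie-corrected normal approximation and
continuity correction — grid-valued concentrations generate heavy ties, so
the tie correction matters. For expanded sizes ≤ 20 the permutation
distribution is enumerated exactly. Equality with the literal
expanded-sample test is asserted in the suite to 10⁻¹² in the statistic and
10⁻¹⁰ in p on random weighted fixtures. The headline alternative is
one-sided "non-commuting lower" (the direction the motivating analyses
test); the two-sided p is always reported alongside. When every expanded
observation is tied (e.g. a perfectly flat surface) the test degenerates
and p = 1 is returned.

Cluster-type × pollutant-band tables use half-open bands [lo, hi) with
default edges 0/10/12/14/∞ (PM₁₀) and 0/8/9/10/∞ (PM₂.₅); the area-level
concentration is that of the cell containing the area centroid (the
published tabulations overlay areas on grids without stating a rule;
centroid containment is deterministic and resolution-appropriate). Columns
sum to 100%.

## 4. Purpose estimation

Features per node: the all-purpose count, Euclidean distances to the
nearest greenspace point, nearest waterbody point and the city centre, and
the number of bus stops within 100 m (boundary-inclusive, distance ≤ 100).
`screen_correlations()` reports each feature's Pearson r with the
non-commuting count and flags |r| < 0.1 as not linearly correlated — the
screening that motivates fitting nonlinear models alongside OLS.

Four models are compared under shuffled k-fold cross-validation (default
k = 10): OLS (`stats::lm`), a single-hidden-layer perceptron (`nnet`, 64
units, standardized inputs and response, weight decay 10⁻⁴, max 500
iterations), RBF support-vector regression (`e1071`, cost 1, internal
standardization) and a random forest (`ranger`, 500 trees, single thread).
Hyperparameters are fixed documented defaults — no tuning — because the
comparison of interest is linear vs nonlinear capacity, not a leaderboard.
Whether the motivating analyses standardized inputs for MLP/SVM is
unstated; this package standardizes and says so. Stochastic fits are
seeded; fold splits and per-fold fit seeds all derive from one root seed.
The score is the Pearson correlation between pooled out-of-fold predictions
and the observed counts (each row predicted exactly once); per-fold mean r
is reported for transparency.

## 5. The synthetic-study generator

The generator defines the study conditions under which the pipeline is
exercised; its defaults are fixed and not revisited per experiment.

* **Extent and partition:** 10 km × 10 km, 20 × 20 rectangular areas.
  Rectangles stand in for irregular census areas because only contiguity
  matters to AMOEBA, and a lattice has a known queen adjacency for oracle
  tests.
* **Counts:** activity totals are geometric — the discrete analog of the
  exponential tail such crowdsourced counts display on a log-linear CCDF —
  with success probability `1 − exp(−count_tail_rate)`, conditioned ≥ 1.
  The default rate 0.2 gives mean ≈ 5.5 activities per node (≈27,000
  activities at 5,000 nodes). No public calibration of the tail exists, so
  the rate is a free configuration parameter.
* **Commuting share:** interpolated linearly in distance from the centre
  between `commute_share_centre` and `commute_share_edge` (default both
  0.6), then *replaced* inside planted regions by the region's share
  (default: one 3 km × 3 km block at share 0.2, the planted
  high-recreation cluster). Replacement, not multiplication, is used so a
  planted share of 0.2 against a 0.6 background yields area rates near
  0.8 vs 0.4 — a controlled, interpretable effect. The commuting count is
  a binomial split of the total at that share.
* **PM surface:** `pm10 = base + amplitude·exp(−d/scale) + noise`
  truncated at 0 (defaults 10 + 5·exp(−d/3000 m), noise sd 0.3), and
  `pm25 = 0.75·pm10 + independent noise`, truncated at 0. The defaults
  put PM₁₀ in ≈10–15 µg/m³ and PM₂.₅ in ≈7.5–11.3 µg/m³, declining from
  the centre, with a compact centre region above the 10 µg/m³ PM₂.₅
  guideline — the qualitative situation in the motivating study area. The
  0.75 ratio is chosen so that guideline exceedance exists reliably; at
  0.70 the surface tops out so close to 10 that exceedance depends on the
  noise draw and the high-exposure percentages degenerate.
* **Invalid records:** `floor(fraction·n)` nodes (default 2%) are
  corrupted, half to zero totals and half to commuting > total — exactly
  the two classes cleaning removes, so corrupted-id recovery is testable.
* **Planted purpose relationship:** optionally, the non-commuting count is
  a deterministic linear function of the total and the features (rounded,
  clamped to [0, total]) instead of a binomial draw, giving an exact truth
  for estimation-recovery tests. With heavier totals (tail rate 0.05) the
  rounding noise is negligible and OLS recovers r ≥ 0.999.
* **Seeding:** all randomness flows from one root seed through fixed named
  streams (node placement, counts, noise injection, environment layers, PM
  noise, purpose noise) via `split_seed()`, so identical configurations
  reproduce byte-identical bundles and partial regenerations are stable.

What the generator does **not** emulate: street-network topology (nodes are
uniform points, not intersections of a road graph), temporal structure
(annual aggregates only), spatially autocorrelated PM noise, irregular area
shapes, and the behavioral heuristics by which commuting flags are set in
real apps. Passing recovery tests therefore demonstrates correctness of the
algorithms under the stated statistical structure, not fidelity to any
particular city's data.

## 6. Numerical choices and degenerate inputs

* Geometry uses a 10⁻⁹ m tolerance for boundary and contiguity tests;
  polygon areas use the shoelace formula and rectangle clipping uses
  Sutherland–Hodgman, which is exact for the axis-aligned cells used here.
* Gi\* requires n < N and S > 0; a constant attribute or a region equal to
  the whole study area is an error, and `run_amoeba()` on constant rates
  returns an all-outside solution rather than erroring.
* The permutation p-value compares with a 10⁻¹² slack so that exact ties
  between permuted and observed |G\*| count as exceedances
  (conservative).
* Model fitting with a constant training response short-circuits to
  predicting that constant: `nnet` and `svm` cannot standardize a
  zero-variance response, and the constant is the correct prediction for
  every model.
* `kfold_split` balances fold sizes to within one row; k must lie in
  [2, n].

## 7. Problem sizes used by the checks

The shipped tests and the acceptance script run the reference study at
5,000 nodes on a 20 × 20 partition with 999 permutations (cluster recovery
in a few seconds), exposure scenarios with ≈27,000 activities,
cross-validation at n ≈ 5,000 for all four models, exhaustive ecotope
oracles on 2 × 4 lattices, and 10⁴-replicate null calibration of the
permutation p-value at 99 permutations each. These sizes were chosen so
that every Monte-Carlo bound in the tests has comfortable margin while a
full run stays in the minutes range on a laptop core.

## 8. Known limitations

* Instantaneous exposure ignores trip duration and inhaled dose; it is the
  right statistic only when durations are unavailable.
* The areal partition induces the usual modifiable-areal-unit sensitivity;
  no sensitivity analysis across partitions is provided.
* AMOEBA's permutation null does not account for the selection effect of
  growing regions to maximize |G\*|; with strong planted effects this is
  immaterial (the planted cluster dominates), but on pure-noise data weak
  spurious ecotopes can reach nominal significance. The suite's
  super-uniformity check covers the p-value of a *fixed* region, which is
  what the estimator promises.
* The greedy growth is not an exact optimizer; its optimality gap is
  quantified only on small lattices where enumeration is feasible.
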