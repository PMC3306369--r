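---
title: "Models and methods in paleomacro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in paleomacro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records how each analysis in the package is defined, which
choices were genuinely open when it was written, and what the synthetic data
used by the tests do and do not establish about real data.

## Parsimony

Tree length is computed by a minimum-change dynamic programme over states
(a unit-cost Sankoff pass, in compiled code). We use it instead of the
classical intersection/union two-pass because it is exact on polytomies and
extends to additive characters by swapping the unit cost for |i−j| (Farris
intervals). The two algorithms coincide on binary trees with unordered
characters, which the test suite confirms against an independent
implementation. Conventions:

* a missing cell ("?") carries the full state universe — it can never add a
  step of its own;
* a polymorphic cell ("{01}") carries its state set;
* the inapplicable symbol "-" is missing by default, with a reader option to
  treat it as one extra distinct state, because matrix conventions differ
  between authors and the choice materially changes comparable-cell counts;
* all characters are unordered by default; per-character additive flags can
  be supplied. Nothing in a typical matrix header records ordering, so the
  conservative default is no ordering assumptions.

The heuristic search is the standard two-phase design: a random addition
sequence (replicate *r* draws its order from `seed + r`, making runs
bit-reproducible), greedy stepwise insertion, then TBR branch swapping
(bisect every branch, reattach every pair of edges of the two fragments),
keeping every distinct tree at the current best length. Tree identity is
the set of non-trivial bipartitions of the unrooted topology, with no
zero-length-branch collapsing, so "number of shortest trees" is defined
purely topologically; different programs' collapsing rules make tree
*counts* only loosely comparable across implementations, and we do not
promise to match any particular one. The outgroup is used only to root
output trees, never in scoring.

Bremer support is computed by reverse-constraint search — rerun the same
search while rejecting, as candidate optima, any tree containing the clade;
the decay index is the difference between the constrained and unconstrained
optima. This has a deterministic memory bound, unlike retaining pools of
suboptimal trees. The equal-length pool can be capped (`max_trees_held`);
the cap bounds swap effort on flat likelihood plateaus and, in our checks
against exhaustive enumeration on 7-taxon problems, does not change the
best length found.

Ensemble CI/RI/RC use per-character minimum steps (number of required
states minus one, polymorphic cells resolved by a minimum hitting set) and
maximum steps (scored cells minus the most common state's frequency), summed
over all included characters.

## Time calibration

Ages are Ma before present everywhere, durations Myr; larger numbers are
older. Tips sit at their first appearance (FAD) by default — diversity
counting and trend fitting both treat a taxon as existing from its first
record — with a range-midpoint option. Initial node ages follow the
oldest-descendant rule. Two smoothing variants resolve the resulting
zero-length branches:

* **mbl** (default): a single postorder pass forces every branch to at
  least `min_duration` by pushing parents older;
* **equal**: each maximal run of zero branches shares the duration of the
  closest positive ancestral branch equally; only ancestors move, and only
  older, so no child constraint can break.

Both are implemented because published protocols differ and rarely print
their constants; `min_duration` and `root_extension` default to 1 Myr,
common practice for Lower Jurassic-scale datasets where stage boundaries
are known to roughly that precision. Polytomies calibrate as hard
polytomies; no resolution is imposed.

## Diversity

A lineage's span is its branch's [parent age, child age] interval, extended
on terminal branches to the tip's last appearance. A bin counts every span
overlapping it; a branch crossing a bin with no tip in it is exactly the
ghost-lineage contribution. Bins are half-open — closed at the older bound,
open at the younger — so a lineage ending exactly on a shared boundary is
counted in exactly one bin per age instant (a lineage genuinely spanning
both bins still counts in both, which is the point of the estimate).
Any-overlap counting, rather than presence at bin midpoint, is the default
because narrow bins are the intended use; midpoint counting is a trivial
specialisation (zero-width bins).

Taxa known from ranges but absent from the matrix are added by range
overlap only. Multispecific OTUs can be expanded to member-species ranges
via a lookup table rather than hard-coded taxonomy, so genus- and
species-level estimates come from the same machinery.

## Disparity

Pairwise dissimilarity is the proportion of mutually scored characters
whose state sets are disjoint. A shared state in a polymorphic overlap
counts as *not different*: any stricter rule would let a taxon differ from
itself under re-scoring. Taxa with no mutually scored characters against
someone (disjoint anatomical coverage, e.g. cranium-only vs postcranium-
only) make cells undefined; `drop_undefined_taxa()` removes the worst
offender greedily until none remain and logs the order.

Principal coordinates use Gower double-centering of −d²/2. Cladistic
dissimilarities are generally non-Euclidean, so negative eigenvalues
appear; the Cailliez constant — the smallest additive constant making the
configuration Euclidean, obtained as the largest real eigenvalue of the
standard 2n×2n companion matrix — is added to all off-diagonal entries
before re-embedding. The tests verify both that full-dimensional scores
reconstruct the corrected distances to 1e−8 and that the constant matches
an independent implementation. Axes are retained while the eigenvalue
exceeds 1e−10 — the count is data-driven, not fixed, because it simply
reflects the taxon count of the matrix at hand (and is reported for
comparison).

Per-interval metrics are the mean pairwise dissimilarity (on the *raw*
dissimilarities, matching its definition; the corrected distances exist
only for the ordination) and the sum of per-axis sample variances
(n−1 denominator), which equals ½·mean squared corrected distance·n/(n−1)
and is robust to sample-size variation. Rarefaction draws taxa without
replacement at a common sample size — by default the smallest bin's count,
equalising sampling across bins — and reports percentile 2.5/97.5 bounds;
percentile rather than normal-theory intervals because the resampled
metric distributions are visibly skewed at small n. The seed is recorded in
the result's attributes.

## Trait models

Three models of a continuous trait on the calibrated tree:

* **stasis**: tips i.i.d. normal(mean, variance) — the tree is ignored;
  2 parameters;
* **BM**: multivariate normal, mean = root state, covariance σ²C with C the
  shared-path-duration matrix; 2 parameters;
* **BM+trend**: mean = root state + μ·(root-to-tip duration); 3 parameters.
  Refused on ultrametric trees, where the depth column is constant and μ is
  unidentifiable — fossil (non-ultrametric) tips are what make the trend
  estimable at all.

Within-taxon measurement error enters as sd² on the covariance diagonal; a
single sd can be supplied (e.g. 55 mm for trunk length, the empirical
within-species value used with such data) or one per tip. On the ln scale
the sd is transported per tip by the delta method (sd/value): a single
raw-scale sd cannot be correct across a 680–3400 mm size range after
logging. Mean parameters are profiled out by generalised least squares; the
step variance is the single remaining dimension and is optimised on the log
scale with `stats::optimize` (golden-section with parabolic refinement) to
1e−10, via Cholesky factorisations. Model comparison uses
AICc = −2lnL + 2k + 2k(k+1)/(n−k−1) and Akaike weights.

Units: step variance in trait²/Myr, step mean in trait/Myr, stasis
variance in trait².

## The synthetic-data generator

The generator emulates the statistical shape of an early-radiation dataset:
by default 32 taxa × 207 characters with states 0–2 and 40% missing cells
(the observed state range of such matrices; the missing fraction is typical
of matrices dominated by incomplete fossils), tip ranges inside a
205–180 Ma window over three bins (earliest Hettangian, Sinemurian, lower
Toarcian), and trunk-length traits using the directional-model parameter
scale reported for such data (step mean 16.1 mm/Myr, step variance
20 mm²/Myr, measurement sd 55 mm, root 680 mm; stasis mean 1381 mm).

Topologies are random; node ages descend from the window's older bound by
exponential waits (rate 0.25/Myr, i.e. mean 4 Myr between splits — chosen
so ~30 taxa fit a ~25 Myr window), truncated at the younger bound; observed
ranges are exponential with mean 2 Myr. Characters evolve under a symmetric
k-state Markov process along branch durations; traits are drawn from the
*exact* multivariate normal each model defines, so the generator and the
fitters close the loop by construction. A single master seed feeds each
component through fixed offsets, so modules are testable in isolation.

What the generator does **not** emulate: correlated characters or
morphological integration, character-rate heterogeneity, non-random
(taphonomically structured) missingness beyond the optional whole-block
masks, diversity-dependent branching, or biogeography. Passing tests
therefore demonstrate algorithmic correctness and statistical calibration
under the stated model, not robustness to these real-data features.

Two property tests pick regimes deliberately: topology recovery uses a
character-rich, moderate-rate matrix (500 characters, 0.015 changes/Myr)
so that even the short internal branches produced by exponential waits are
marked by several characters while homoplasy stays mild; model-recovery
closure tests simulate with zero measurement sd, since identifiability of
the process variance is the property under test and 55 mm of noise on a
~20 mm²/Myr process would be a test of sample size, not of the fitter.

## Problem sizes

The test suite and the acceptance script validate the search against
exhaustive enumeration at 7 taxa (945 topologies, 20 seeded runs),
consensus recovery at 8 taxa × 500 characters, ordination identities at
14–16 taxa with 40% missing data, trait recovery on 28-tip trees (200–500
replicates), and the full pipeline at 10–16 taxa — sizes at which every
stage has an independent ground truth and the whole suite runs in well
under a minute of compute per component.

## Known limitations

* The split machinery encodes tip sets in 64-bit masks: at most 52 taxa per
  search. Matrices of that size are the intended scale; beyond it the
  search would need a different tree-identity encoding.
* TBR neighbourhoods are enumerated explicitly; with the equal-length pool
  uncapped, flat landscapes (little informative data) can make searches
  slow. Cap the pool for exploratory runs.
* No implied weighting, ratchet, likelihood or Bayesian tree inference; no
  tip-dating or stochastic calibration; no OU or rate-shift trait models;
  no sampling-standardised taxic diversity. These are outside the
  package's scope.
* Reported tree counts use no branch collapsing and therefore need not
  match programs that collapse zero-length branches.
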