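---
title: "Methods: navigation-game optimality and structure-function prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: navigation-game optimality and structure-function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navopt)
```

## The navigation game

The package is built around a game-theoretic null model of wiring-efficient
brain communication. Each node (brain region) is a player that chooses which
other nodes to connect to. Communication is *greedy routing*: a message at
node `u` destined for `w` is handed to whichever of `u`'s neighbours is
closest (in the supplied metric) to `w`, and so on, with no knowledge of the
global topology. Handing off to a candidate neighbour `v` lets `u`
ultimately reach the navigation set

S(v; u) = { w : dist(v, w) < dist(u, w) },

the nodes strictly closer to `v` than to `u` (note `v` is always a member,
since dist(v, v) = 0). A player wants to reach *every* other node while
paying for as few connections as possible, so its optimal strategy is a
**minimum set cover**: the smallest family of navigation sets whose union is
all other nodes. Playing this strategy independently at every node and
pooling the chosen connections into one undirected graph yields the Nash
equilibrium network (NNG): no node can reach more targets or drop an edge
without losing navigability. Two provable consequences anchor the test
suite: greedy routing succeeds for *every* ordered pair on the equilibrium
network (navigability exactly 1), and the edge count is minimal for that
property.

`min_set_cover()` solves the cover problem exactly by branch and bound with
a greedy upper bound and dominance pruning, which is exercised against
exhaustive subset enumeration in the tests. Approximate covers are
deliberately not offered: optimality scores would silently drift.

**Tie-breaking.** Minimum covers need not be unique. Among all optima the
solver returns the lexicographically smallest neighbour index set, found by
a feasibility-guided refinement after the optimal cardinality is known.
This makes `build_nng()` deterministic, which the round-trip tests and the
planted-label generator rely on. Different optima could shift the
optimality ratio slightly on adversarial geometries; on the random layouts
used here we have not observed competing optima changing edge counts.

**Edge direction.** Each node's choices are pooled into one undirected
graph and |M| counts undirected edges, matching the symmetric structural
matrices the classification is compared against.

## Edge classification and derived metrics

Against a real (or synthetic) weighted structural matrix, an NNG edge
present in the structure (weight strictly positive — no threshold) is
*optimal* (T); a structural edge absent from the NNG is *nonoptimal*; an
NNG edge with zero structural weight is a *false positive* (F). Optimality
is |T|/|M|, so |T| + |F| = |M| holds identically. Hemisphere-style
restricted geometries are handled by `build_nng(D, blocks = ...)`, which
plays the game separately per block; this is equivalent to running the
construction on each block's distance submatrix, a property the tests
check.

Partition metrics divide optimal edge counts by structural edge counts
within and between node communities; zero denominators are reported as
missing (NA) rather than zero, because "no edges" is not evidence about the
optimality of edges. Regional optimality (RO) is the per-node optimal minus
nonoptimal degree, normalized by total structural degree into [-1, 1].
False positives never enter denominators — they do not exist in the real
network. Internetwork denominators use unordered network pairs.

## The spectral structure-to-function map

Functional connectivity is predicted as a rotated matrix polynomial of the
structural matrix,

F̂ = R (Σ_{r=0..k} a_r S^r) Rᵀ,  RᵀR = I, det R = +1.

Powers of S accumulate walk (path) information, so higher orders inject
longer communication paths into the prediction. The Frobenius-optimal fit
for symmetric matrices has a closed form, which we use instead of gradient
descent over (a, R): eigendecompose S and F with eigenvalues sorted
descending, set R = U_F U_Sᵀ, and regress F's eigenvalues on the Vandermonde
matrix of S's eigenvalues (powers 0..k) by ordinary least squares. The
closed form is deterministic, fast, and its two contracts — rotation
invariants and residual monotonicity in k — are directly testable.

Choices the closed form forces us to make explicit:

* **Eigenvalue pairing** is by descending value, not magnitude, preserving
  the order statistics of correlation-like matrices. No sign or pairing
  convention changes F̂ itself (F̂ depends only on U_F and the fitted
  polynomial), but it does change the reported R; the determinant is fixed
  to +1 by flipping the eigenvector pair attached to the
  smallest-magnitude structural eigenvalue.
* **Repeated eigenvalues** make R non-unique; any orthonormal basis is
  accepted and R absorbs within-eigenspace rotations, leaving F̂ unchanged.
* **k ≥ n** produces a rank-deficient Vandermonde; the fit warns and
  zero-fills unidentifiable coefficients.

The default order is k = 5: on fixed (S, F) the residual is non-increasing
in k by construction, and in practice the gain plateaus beyond order ~5, so
higher orders only add degrees of freedom. Prediction quality is scored by
Pearson correlation of strictly-upper-triangle entries, and topologically
by the Betti-0 persistence score below.

## Betti-0 persistence scoring

`betti0_curve()` thresholds a matrix at every edge density λ ∈ [0, 1]
(keeping the ⌊λE⌋ strongest of the E = n(n-1)/2 off-diagonal entries) and
counts connected components with a union-find. The score

SSE_β = (1/n²) ∫₀¹ (β₀(λ) - β̂₀(λ))² dλ

is computed by the trapezoidal rule; the default grid has one knot per edge
rank, so the piecewise-constant curves are represented exactly and the
tests can compare against a brute-force integral to 1e-12. Edges are
ranked by signed weight descending (strongest correlations first), ties
broken by (i, j) index; `absolute = TRUE` ranks by magnitude instead.
Because the construction is rank-based, the score is invariant under any
common strictly increasing transform of both matrices' weights.

## Distance controls

Two controls separate "optimal connections predict function" from "short
edges predict function":

1. **Generative distance model.** `sample_distance_network()` grows a
   network edge-by-edge with probability ∝ dist^(-η) (weighted sampling
   without replacement), matching the real network's edge count.
   `fit_generative_model()` scores a candidate η by the maximum
   Kolmogorov-Smirnov distance between real and synthetic distributions of
   degree, local clustering, betweenness, and edge length, then refines by
   sampling new η values from the 1-D Voronoi cells (nearest-neighbour
   intervals) of previous samples with probability ∝ 1/energy, for two
   rounds. The search range [-1, 10], 32–64 initial samples and 2 rounds
   are configuration defaults, not claims; the parameter-recovery test
   (planted η* = 3 recovered within ±1) shows they are adequate at n = 100.
   The four-statistic energy follows the generative-modelling literature
   the distance rule comes from; the subset is configurable.
2. **Distance regression.** `regress_out_distance()` projects each column
   of a predicted matrix onto the orthogonal complement of the distance
   matrix's column space via the Moore-Penrose pseudoinverse. It is an
   orthogonal projector (idempotent, residuals orthogonal to D), which the
   tests verify to 1e-10. The raw formula is column-wise and need not
   return a symmetric matrix; a `symmetrize` flag averages with the
   transpose, off by default so the default matches the formula.

## PLS of gene expression against regional optimality

`pls_fit()` is a NIPALS-style PLS1: predictor columns are mean-centered and
z-scored (microarray scales are heterogeneous; disable with
`scale = FALSE`), the response is centered, and components are extracted by
iterative deflation. Per-component variance explained in both blocks, the
component-1 score vector, and its Spearman correlation with the response
are reported. An installed independent PLS implementation is used in the
test suite to cross-check component scores; it is never the implementation.
Significance uses a permutation null on the row (label) assignment with the
add-one estimator p = (1 + #{null ≥ observed}) / (1 + n_perm), so p is
never exactly zero and the type-I rate is calibrated (checked by a KS test
against uniformity under a pure-noise null). Ten-fold cross-validated R² is
reported per component count but never used to select components:
component 1 is always the component carried to the permutation test.

## What the synthetic generator emulates — and what it does not

The generators plant ground truth so every downstream stage has a known
answer:

* `gen_coords()`: uniform-box layouts (100-unit cube, mm-scale) or two
  Gaussian blobs (two hemispheres); duplicate points are resampled.
* `gen_structural()`: the NNG over the coordinates is the planted optimal
  core; each game edge is dropped with probability `p_drop` (these return
  as false positives); `ceiling(p_extra * m)` non-game edges are added
  with probability ∝ distance, so planted nonoptimal edges are long-range,
  as direct long-range tracts are. Weights are `exp(-dist/d0)` (d0 =
  median pairwise distance) plus Unif(0, 0.1) noise, clipped to
  [0.05, 1] — bounded, GFA-like, decaying with distance; the exact shape
  is irrelevant to the downstream math. Defaults `p_extra = 0.3`,
  `p_drop = 0` give cohorts whose nonoptimal fraction (~23% of edges) is
  commensurate with the optimality levels reported for real connectomes.
* `gen_functional()`: the forward model R(Σ a_r S^r)Rᵀ plus symmetric
  Gaussian noise; R is the identity or a uniform random rotation (QR of a
  Gaussian matrix, sign-fixed, det corrected to +1). The default
  coefficients `default_poly_coef(5)` = (0, 1, 0.2, 0.05, 0.01, 0.002)
  decay fast enough that the polynomial is strictly increasing on the
  spectral range of typical weighted structural matrices. That makes the
  eigenvalue pairing identifiable, so the closed-form fit recovers
  noiseless forward data exactly — the property the recovery tests assert.
* `gen_rest_task_pair()`: rest is the forward model on the optimal-only
  submatrix; task applies it to `2 * S_nonoptimal + 0.1 * S_optimal`. The
  damping factor deserves a note. For the generator to *guarantee* that
  nonoptimal connections predict the task state best, the nonoptimal block
  must dominate the task matrix in Frobenius norm. Under the
  distance-decaying weight model optimal edges are roughly three times
  more numerous and individually heavier, so a mild damping (e.g. 0.5)
  leaves the task matrix optimal-dominated and the intended dissociation
  does not materialize; at 0.1 the nonoptimal block dominates the squared
  norm by more than 40:1 and the orderings hold per subject. The
  multipliers are exposed (`task_weights`) for sensitivity analyses.
* `gen_expression()`: `n_signal` columns equal the RO vector plus noise
  (unit loading), the rest are standard normal; columns are shuffled so
  signal genes are not positionally identifiable.

None of this mimics MRI physics, tractography biases, spatial
autocorrelation of expression, or real co-expression structure. Passing
tests therefore demonstrate *internal correctness and calibration* — the
game is solved exactly, the fit recovers its own forward model, the
permutation test is uniform under the null — not that real connectomes are
79% optimal. Quantities reported on real-data scales in the literature
(optimality near 0.79, prediction r near 0.97) require the restricted
imaging and microarray datasets and are out of scope here.

## Numerical choices and degenerate inputs

* Structural "edge exists" means weight > 0 exactly; no epsilon threshold.
* Greedy routing requires strictly decreasing distance to the target each
  hop, so it terminates without cycle detection; on equilibrium networks
  the rule is vacuous (routing always succeeds).
* Zero-variance upper triangles make the correlation score NA (missing)
  rather than an error; constant matrices still return a spectral model.
* Zero structural degree makes RO missing; zero denominators make
  partition ratios missing.
* Paired t-tests with zero within-pair variance are flagged `degenerate`
  with a signed infinite statistic instead of erroring.
* Repeated-measures ANOVA uses Greenhouse-Geisser adjusted p-values
  (via `car`); an all-identical score matrix short-circuits to F = 0,
  p = 1 before reaching the solver.
* All generators and searches take explicit seeds; cohort subjects get
  sub-seeds from a fixed integer splitting rule (`subject_seed`), so
  every table in `analysis/` is bit-reproducible.

## Problem sizes

The shipped analyses and tests run on 25–60-node networks (10-subject
cohorts), 100-node generative-model fits, and 40 × 100–200 expression
matrices with 199–999 permutations. These sizes keep the full pipeline in
the minutes range on one CPU while leaving every statistical property
(exactness, calibration, recovery, orderings) measurable; nothing in the
implementation is specific to them, and 234-node inputs run with the same
code paths.

## Known limitations

* The exact cover solver is exponential in the worst case; it is fast on
  geometric navigation-set instances up to a few hundred nodes but is not
  a general-purpose ILP replacement.
* The closed-form spectral fit is the Frobenius optimum only under the
  descending-eigenvalue pairing; if the true generating polynomial is
  non-monotone on the spectrum, the pairing (hence recovery) can break.
  The default forward coefficients avoid this regime by construction.
* With noiseless synthetic data the correlation score saturates near 1 for
  every mask, so condition differences are small (if consistent);
  conclusions from the synthetic cohort are about orderings, not effect
  sizes.
* Plain label permutation is the null for the PLS test; spatially
  autocorrelation-preserving nulls are not implemented.
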