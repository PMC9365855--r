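---
title: "Methods: models, null ensembles, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, null ensembles, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vulnmap relates parcellated cortical-abnormality maps (one group-level
effect size per region) to two families of regional predictors — local
molecular attributes and global connectome metrics — and quantifies how
abnormality propagates along structural connections. This vignette
records the models, their assumptions, the numerical conventions, and
the design decisions that were genuinely open, so that a reader can
judge what the package's passing tests do and do not establish.

## The regression model and dominance analysis

Each abnormality map is z-scored and regressed, by ordinary least
squares with intercept, on a z-scored region-by-predictor table (seven
predictors per family in the canonical setup). The model is deliberately
linear and unregularised: with n = 68 regions and p = 7 predictors,
anything richer invites overfitting, and comparability across maps
matters more than raw predictive power. Fits are summarised by adjusted
R², and the design matrix is required to be full rank — collinear
columns are a user error, reported by name, not silently dropped.

Dominance analysis attributes the fit to individual predictors by
enumerating all 2^p − 1 submodels and averaging, per predictor, the R²
increase it contributes to submodels of each size. We compute increments
on the plain R² scale, because that is the only scale on which the
contributions provably sum to the full-model R²; a proportionally
rescaled variant that sums to adjusted R² is reported alongside, since
contributions are usually quoted on that scale. The two statements
"dominances are averaged R² increments" and "dominances sum to adjusted
R²" cannot both hold exactly, and this pair of outputs is our
reconciliation. No per-predictor significance is attached: a dominance
is meaningful only relative to the other predictors in the model. The
enumeration is guarded at p ≤ 20; the test suite verifies the
implementation against an independent brute-force enumerator that goes
through `lm()` on every subset.

Out-of-sample performance uses a distance-dependent split: per
iteration, a uniformly random source region is drawn, the floor(0.75 n)
regions nearest to it (source included, distance ties broken by region
order) form the training set, and the Pearson correlation between
predicted and observed abnormality on the remaining quarter is recorded.
Splitting by spatial proximity rather than at random prevents
autocorrelated maps from leaking across the split; the resulting
correlations are accordingly pessimistic relative to random splits.
Iterations with degenerate test variance are recorded as missing with a
warning rather than fabricated.

## Neighbour abnormality, spreading, and epicentres

Mean neighbour abnormality of region i is the sum of d_j · SC_ij over
the structurally connected neighbours j, divided by the *count* N_i of
those neighbours (not the summed weight); the functional variant
additionally multiplies each term by FC_ij. Two conventions were open
and are exposed as options with these defaults:

* **Orientation.** All spreading and epicentre code requires maps
  oriented so that larger = more abnormal, and refuses to run otherwise;
  `flip_map()` converts thinning-negative effect maps. Ranking raw
  signed values versus magnitudes genuinely changes epicentre maps, so
  the package forces the caller to make the orientation explicit rather
  than guessing.
* **Signed FC.** The functional weighting uses signed FC values as they
  come; an `abs_fc` switch is provided. With signed FC a negatively
  coupled neighbour reduces exposure, which is the more conservative
  reading.

The spreading statistic is the Pearson correlation between a map and its
neighbour-abnormality map; significance is a two-sided spin test in
which the *map* is permuted and the neighbour operator re-applied (the
operator is linear, so each permutation costs one matrix-vector
product). Epicentre likelihood is the mean of the node-abnormality rank
and the neighbour-abnormality rank (ascending, average ranks for ties),
which makes it invariant under any strictly increasing transform of the
map. Cross-disorder aggregation supports elementwise median, mean, and
top-half frequency, with merge groups (e.g. left/right variants of one
disorder) averaged into a single map first so a duplicated pattern
cannot dominate the aggregate.

## Disorder similarity

The disorder-similarity matrix correlates, for every pair of regions,
their across-disorder abnormality profiles. Each map is z-scored before
the profile correlation. This matches the provenance of such maps
(effect sizes distributed on a common z scale) and gives the matrix a
property the raw computation lacks: invariance to shifting or positively
rescaling any single map. Regions whose z-scored profile is constant
have no defined correlation and are masked with a warning. Feature
similarity (molecular, connectomic, receptor, gene) is computed the same
way, with an option to restrict to one hemisphere for annotations that
are only reliable there; leave-one-out influence is 1 minus the
upper-triangle correlation between the full and the reduced similarity
matrix.

Matrix–matrix comparisons correlate upper triangles and obtain
significance by conjugating one matrix with each spin permutation (rows
and columns together), which preserves that matrix's internal structure
while breaking its alignment with the other. The distance-regression
alternative fits the upper-triangle entries on pairwise centroid
distance (linear by default; an exponential-decay option falls back to
linear if the nonlinear fit fails to converge) and re-packs residuals
symmetrically.

## Null ensembles

**Spin permutations.** Per repetition a uniform random rotation (QR of a
Gaussian matrix with sign fix, determinant +1) is applied to one
hemisphere's unit-sphere coordinates and its mirror image — conjugation
by the x-reflection — to the other; each region then takes the value of
the nearest rotated source region within its own hemisphere. The
assignment is deliberately *not* forced to be a bijection: nearest-
neighbour reassignment can duplicate or drop values, which is the
behaviour implied by reassigning each parcel "the value of the closest
rotated parcel". Masked regions draw from the nearest unmasked source.
No value ever crosses hemispheres; regenerating with the same seed is
bit-identical. Spin nulls are known to err on the generous side (null
distributions can be slightly too wide); no correction is applied.

**Distance-binned rewiring.** Edges are binned by centroid distance
(auto bin count: round(sqrt(edge count))) and double-edge swaps
(a,b)+(c,d) → (a,d)+(c,b) are attempted 10,000 times per ensemble
member, accepted only when both new edges are absent, create no
self-loop, and land in the same distance bin. Weights travel with their
edges. Degree sequence and per-bin edge counts are conserved *exactly*,
which the tests audit member by member.

One property of this null deserves emphasis. The in-bin constraint is
severe: on the canonical synthetic network the ensemble equilibrates at
only a few percent of edges moved, so the null networks remain close to
the source network. When the tested network is the empirical one — the
usual usage — the observed contrast is therefore not exchangeable with
the null contrasts, and the connected-versus-unconnected test is
conservative under no effect (it under-rejects; it never inflates false
positives). The calibration experiment in the acceptance suite
consequently draws the *tested* network from the same rewiring process
as the nulls, the design under which uniform p-values are actually the
correct expectation, and a separate test pins down the conservative
(never anticonservative) behaviour of the data-centred usage. p-values
everywhere use the add-one estimator (1 + #extreme)/(n + 1), so p = 0 is
impossible.

## Group-consensus connectome

Within each edge-length bin — built separately for intra- and
inter-hemispheric edges so callosal connections are not crowded out by
the more numerous short intra-hemispheric ones — the k most frequently
occurring edges are retained, where k is the rounded mean number of
edges a single subject has in that bin. The bin count heuristic, "square
root of the mean binary density", is read as the square root of the mean
per-subject *edge count*: read literally as a fraction in [0, 1] it
yields less than one bin, which is degenerate, so the count reading is
the only workable one (and it is overridable via `n_bins`). Frequency
ties are broken by higher mean weight, then shorter length — an
arbitrary but fixed rule that makes the consensus fully deterministic.
The weighted variant averages log weights over the subjects that possess
the edge and min–max-scales the result into (0, 1] over retained edges.

## Graph metrics

Path-based metrics (betweenness, closeness) use the length transform
length = 1/weight, the dominant convention for streamline-density
weights. Betweenness is normalised by (n−1)(n−2) on ordered pairs so
values lie in [0, 1]; closeness is reported as the *mean shortest-path
distance* (smaller = more central), matching how the quantity enters the
predictor table. Weighted clustering is the Onnela form: weights
max-normalised, triangle intensity the cube-root geometric mean,
averaged over ordered neighbour pairs; nodes of degree < 2 get 0. Mean
first passage time is defined in steps of the discrete-time
strength-proportional walk and computed from the fundamental matrix
(stationary distribution proportional to strength), averaged over
targets excluding the diagonal; the Kemeny start-independence identity
(stationary-weighted row means equal across starts) is used as a
correctness invariant in the tests, alongside a random-walk simulation
oracle. All seven metrics are assembled, in fixed column order, into a
z-scored connectomic predictor table.

## The synthetic study, and what it does not emulate

The generator exists so that every stage has a ground truth. Its
geometry is a unit sphere with mirrored hemispheres — regions are placed
by a Fibonacci lattice on one half-sphere and x-negated onto the other —
*because* the spin test assumes spherical projection: in this model the
spin null is exact rather than approximate. Network labels come from k
mirrored seed points, so every intrinsic network is bilateral.

Defaults were fixed once to mimic the scale of the canonical empirical
setup: 34 regions per hemisphere, 70 subjects, target binary density
0.25, seven predictors per family, thirteen disorder maps. Subject
connectomes draw each edge independently with probability proportional
to exp(−distance/decay) calibrated to the target density; the decay
length defaults to 1 (the sphere radius), the steepest scale at which
the calibration remains feasible at 25% density — steeper decays push
the required probability above 1 at the near-coincident mirrored midline
pairs, and the generator then refuses rather than silently clamping.
Weights are log-normal, emulating the heavy tail of streamline counts.
Functional networks mix the z-scored communicability of the
strength-normalised SC with an independent smooth symmetric random
field, under a single coupling parameter. Molecular maps are zero-mean
Gaussian-process draws with covariance exp(−distance/ℓ), z-scored.

Abnormality maps come from two forward models. The linear model y = Xβ +
ε records its planted population R² = β'Σβ/(β'Σβ + σ²) with Σ the
empirical predictor covariance, and `noise_for_r2()` inverts that
relation. The diffusion model applies the resolvent (I − αŴ)⁻¹ to an
epicentre indicator, with Ŵ the row-normalised SC and α < 1, then takes
a square root, scales to unit SD, and adds Gaussian noise. The square
root is a deliberate saturation: the raw resolvent of a point seed
leaves the seed carrying roughly 1/α² times the mass of any neighbour,
one extreme-leverage point that caps the node–neighbour Pearson
correlation near 0.1 however small the noise — while excluding the seed
the correlation is 0.99. A monotone compression preserves the
indicator limit at α → 0, the location of the maximum, and every
rank-based property of the map, while letting the spreading statistic
see the structure it is meant to detect; the square root is the mildest
power that does so at the canonical α = 0.4, noise 0.1. Unit-SD scaling
makes `noise_sd` a relative (fraction-of-signal) noise level. This
forward model is a test harness, not a mechanistic claim about disease.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: tractography biases (false
positives/negatives, length and gyral biases), subject-level abnormality
(only group-level maps exist here), non-Gaussian and non-stationary
spatial autocorrelation, hemispheric asymmetries beyond mirroring,
measurement error structure in PET/transcriptomic annotations, and any
true biological coupling between molecular maps and connectome topology
beyond what distance induces. Results on real data inherit all of those
caveats.

## Numerical conventions and degenerate inputs

* Symmetry tolerance for networks is 1e-8 (silently symmetrised by
  averaging below it, an error above); the diagonal is always zeroed.
* Sphere coordinates must have unit norm within 1e-8.
* Z-scoring uses the sample SD and refuses constant columns by name;
  repeated z-scoring is idempotent within 1e-12.
* The E:I ratio divides class sums of z-scored features (sum and mean
  aggregation give identical ratios for equal class sizes; the
  aggregator is exposed); regions whose denominator magnitude falls
  below 1e-10 are masked and reported, never divided through.
* PC1 gradients fix their sign so the loadings sum nonnegative (first
  loading nonnegative on ties): regression fits are sign-invariant, so
  only reproducibility is at stake.
* Disconnected networks are an error for path and walk metrics, with
  component sizes in the message; isolated regions are masked (with a
  warning) in neighbour abnormality rather than treated as zero.
* Canonical region order is left hemisphere then right, label-sorted
  within hemisphere, fixed at parcellation construction; readers align
  by label and refuse missing, extra, or duplicate regions.
* All stochastic operations take an explicit integer seed and are
  bit-reproducible given it.

## Problem sizes in the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the canonical study at 68
regions and 70 subjects; recovery experiments use 100 seeded runs,
calibration experiments 200 runs at 500 nulls, dominance cross-checks 50
random p = 5 problems, and the graph-metric oracles exhaustive
enumeration on 8-node graphs plus simulation with tens of thousands of
walks. These sizes give Monte-Carlo error comfortably below the margins
being asserted while keeping a full run in the tens of seconds.

## Known limitations

Dominance analysis is exponential in p (guarded at 20). The rewiring
null mixes slowly under fine distance bins and degenerates to the
identity on saturated graphs. The spin test requires a spherical
projection and both hemispheres non-empty; maps with masked regions use
nearest-unmasked reassignment, which slightly biases the null toward
smoothness at mask boundaries. The F-type comparison of two fits is a
plain variance ratio with no exact sampling distribution claimed. The
package is resolution-agnostic but has only been exercised at
68-region scale; nothing is claimed about other atlases.
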