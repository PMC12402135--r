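---
title: "Methods: resting-state cortico-subcortical convergence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state cortico-subcortical convergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convorg)
```

convorg analyses how many functionally distinct cortical regions converge
onto individual subcortical regions in resting-state functional
connectomes, and what that convergence implies for network robustness.
This vignette documents the statistical model behind each stage, the
tunable parameters, the design decisions taken where a choice was
genuinely open, and the limits of what the synthetic tests demonstrate.

## Partial-correlation functional connectivity

Dependence between regional time series is estimated as a *partial*
correlation: for each target region $X_i$, the mean-centred series of all
other $N-1$ regions enter an ordinary least-squares regression with no
intercept, and the coefficient $\beta_{j,i}$ measures the unique influence
of region $j$ on region $i$ after controlling for every other region.
Marginal correlation would attribute shared variance to every correlated
pair; the regression formulation suppresses these indirect routes and so
controls false positives. Self-dependence is not modelled (zero diagonal),
and no intercept is needed because sessions are mean-centred per ROI
before concatenation (`prepare_subject()`, which also discards the first
`n_discard = 100` volumes of each session while tissue magnetization
stabilizes).

Group inference is a random-effects analysis: an entry-wise one-sample
t-test of the subject-level $\beta_{j,i}$, Bonferroni-corrected by the
number of regressors per model ($N-1$), at a nominal two-sided
`alpha = 0.05` (the convergence analyses below re-threshold at 0.01, the
stricter level at which the converging sets are defined). The binary
matrix $C$ is directed — $C_{j,i}$ need not equal $C_{i,j}$ — and no stage
symmetrizes it silently: graph metrics use an explicit `"or"`
symmetrization by default, while convergence uses the strict `"and"`
(bidirectional) rule, both exposed as the `symmetrize` argument.
The weighted matrix holds the mean significant beta per edge, rescaled by
its maximum absolute value into $[-1, 1]$. Degenerate edges with zero
between-subject variance are resolved by the infinite-t limit: a non-zero
constant beta is significant, an all-zero edge is not.

Edges with a significant *negative* beta are kept as edges throughout:
the binary matrix records significance, not sign, and the downstream graph
analyses are sign-blind. The sign survives in the weighted matrix.

## Surrogate test of genuine cross-dependence

Autocorrelated series can show spurious instantaneous correlation.
`phase_randomize()` builds surrogates with the exact amplitude spectrum of
each series (hence its autocorrelation, mean and variance) but random
Fourier phases, independently per region, destroying any true cross-series
dependence. `surrogate_null_test()` compares the observed mean
off-diagonal $|\beta|$ against the distribution of the same statistic over
`n_surrogates` surrogate panels, reporting the permutation p-value
$(1 + \#\{\text{surrogate} \ge \text{observed}\})/(n_\text{surr}+1)$.

A pooled-variance two-sample t-test over the raw $|\beta|$ values is also
computed and recorded. It is not the primary decision statistic: the
$|\beta|$ values within one panel share a data realization and are
mutually correlated, so the pooled test treats dependent values as
independent and rejects far too often — on fully independent AR(1) panels
we measured roughly a quarter of runs rejecting at the nominal 5% level,
while the permutation p-value is calibrated (~5%). The calibration
property the package tests (at least 90% non-significant over 50
independent-panel repeats) refers to the permutation p-value. The smallest
achievable p is $1/(n_\text{surr}+1)$, so detecting dependence at 0.01
requires at least 100 surrogates (the default).

## Consensus community detection

Communities are found by Louvain modularity maximization at resolution
$\gamma$ (`louvain_once()`, one seeded run). Because single runs are local
optima, `consensus_partition()` repeats the optimization `n_init` times
(default 1000), forms the agreement matrix of co-assignment frequencies,
zeroes entries at or below `tau = 0.95` (strictly more than 95% of runs),
and re-clusters the thresholded agreement matrix until all runs coincide
(cap: 50 iterations, then an error with diagnostics — silent
non-convergence is never returned). Seeds for run $k$ are `seed + k - 1`,
so results are a pure function of the inputs.

Numerical conventions: the adjacency is symmetrized as $(A + A^T)/2$;
negative weights (possible in the normalized weighted matrix) are clipped
to zero for the optimization, which requires non-negative weights — the
modularity reported for a partition refers to that clipped graph. A graph
with no edges yields singleton communities with $Q = 0$.

Model selection sweeps $\gamma$ from 0 to 2 in steps of 0.1 over both the
binary and the weighted matrix (`gamma_sweep()`). The criterion is the
*network assignment confidence score*: the mean silhouette over nodes,
with node-to-node distance defined as $d = 1 - w$ on the normalized
weighted matrix (strongest connectivity = zero distance; the simplest
monotone map, and configurable by supplying `weights`). Silhouettes are
always evaluated on the weighted matrix, including for partitions obtained
from the binary matrix, so confidences are comparable across matrix types.
A silhouette needs at least two communities; single-community solutions
get `NA` confidence and can never be selected. A node alone in its
community scores 0. Ties in confidence are reported in full and resolved
to the smallest $\gamma$ (binary matrix first) for the representative
solution; the sweep also reports whether the binary and weighted best
partitions coincide, which they do on well-separated planted structure.

## Null-model validation

`rewire_null_ensemble()` generates degree-preserving random graphs by
double-edge swaps (default 10 attempted swaps per edge), asserting exact
degree-sequence preservation per member. `null_comparison()` tests the
real network's metrics against the ensemble distributions with one-sample
t-tests: optimized modularity (Louvain re-run per member with a derived
seed — so the null asks "how modular does an equally-degreed random graph
*look* when you try to modularize it"), characteristic path length
(largest component when a member disconnects, recorded), and per-node
within-module degree and participation under the real partition.
Direction ("above"/"below") is reported alongside |t|, since the sign
convention of such null t-statistics is arbitrary. Zero-variance null
distributions fall back to exact comparison.

## Hub typology

Within-module degree z-score $z_i$ standardizes a node's within-community
degree against its community ($\sigma_m = 0 \Rightarrow z_i = 0$);
participation $P_i = 1 - \sum_m (k_{im}/k_i)^2$ measures spread over
communities ($k_i = 0 \Rightarrow P_i = 0$). Classification: connector hub
($P > 0.5$, $z > 0$), non-hub connector ($P > 0.5$, $z \le 0$), provincial
hub ($P \le 0.5$, $z > 0$), non-hub otherwise; boundaries are non-strict
on the low side. The community context is caller-supplied because it
matters: participation with respect to the three subcortical communities
and with respect to all whole-brain communities are different questions,
asked as two calls with different partitions.

## Convergence and distance statistics

Convergence is deliberately non-directional: an edge $c_{r,s}$ between
cortical node $r$ and subcortical node $s$ requires significance in *both*
directions of the directed binary matrix (the recurring bidirectional
"dual dyad" motif motivates the strict AND rule). Convergence counts are
column sums of the resulting incidence matrix.

Proportion convergence for a cortical pair counts the subcortical targets
onto which *both* nodes converge, normalized by the grand total so the
proportions sum to one. A literal Kronecker-delta reading of the pair
indicator would also count joint absence ($\delta(0,0) = 1$) as
convergence, which contradicts the quantity's meaning (how often two nodes
project *simultaneously*); the package counts only joint presence.

Distances between bilateral ROIs average the left- and right-hemisphere
centroid distances; for a medial ROI (single centroid, e.g. cerebellar
vermis) the centroid is paired with each of the other ROI's centroids and
the distances averaged. Coordinates are used exactly as tabulated (MNI mm,
no axis flips).

Pairs are functionally similar (FS) when both nodes carry the same
resting-state-network label, functionally diverse (FD) otherwise; the
classification is exhaustive and symmetric. Distances are binned into
8-mm bins anchored at zero. The packaged convergence table's own maximum
pair distance is 150.05 mm (19 bins); the published analysis used a grid
spanning the full cortical sheet — 21 bins, i.e. 168 mm, which is the
default `max_distance` of `run_table1_analysis()` (the extra bins carry
zero weight and enter the paired test as zero differences). The paired
bin-wise t-test of FD minus FS summed weights has dof = bins − 1; a
constant non-zero difference is reported as an infinite-t sentinel.

Two normal-fit methods are provided for the per-class distance
distributions:

* `fit = "moments"` (function default): O-weighted mean and standard
  deviation of the pair-level distances — the estimator-consistent choice,
  recovering $(\mu, \sigma)$ of simulated Gaussian pair distances.
* `fit = "lsq"`: amplitude-free Gaussian least squares to the binned
  histogram, evaluated at the bin labels $8, 16, \dots$ mm (each 8-mm bin
  labelled by its upper edge, the common bar-plot abscissa). This is the
  method `run_table1_analysis()` uses, because it reproduces the published
  FD parameters to printed precision (60.08/28.18 vs 60.10/28.19); the FS
  parameters agree to 0.4 mm in the mean (33.58 vs 33.18) and about 2 mm
  in the SD — a residual discrepancy against an unstated fitting procedure
  that we report rather than hide. The moment estimates (44.25 FS /
  62.79 FD) differ substantially from both, which is expected: moments of
  a skewed, truncated-at-zero weight distribution do not coincide with the
  best-fitting Gaussian of its histogram.

Network-level convergence splits the eight cortical networks into primary
(VIS, SOM, CER) and association (DAN, VAN, LIM, CON, DMN) classes and
reports, per subcortical network, the percentage of its bidirectional
connections received from each class.

## Targeted attack and local efficiency

The efficiency of a node's neighbourhood is the mean inverse shortest-path
length among its neighbours with the node removed; paths are restricted to
the induced neighbourhood subgraph (the Latora–Marchiori convention;
`paths_within = FALSE` routes paths through the remaining full graph
instead, since the defining formula is ambiguous on this point).
Unreachable pairs contribute $1/\infty = 0$; fewer than two neighbours
give 0. The attack universe defaults to the *converging organization*:
subcortical nodes plus every cortical node with at least one bidirectional
subcortical edge, and all symmetrized edges among them — a purely
bipartite graph would make every subcortical neighbourhood edgeless
(efficiency 0), so the cortico-cortical and subcortico-subcortical edges
are essential to the analysis. Null distributions come from random node
sets of the same size (without replacement within a draw), either from all
nodes or, in the restricted condition, from the cortical members only,
compared with a one-sample t-test against the targeted value. Because the
neighbourhood efficiency of a node does not depend on the rest of the
attacked set, the per-node values are precomputed once, which makes 10,000
simulations cheap.

## The synthetic-data generator

`simulation_spec()`/`simulate_panel()` emulate the statistical structure
the pipeline assumes, not fMRI physics: per subject and session an AR(1)
process whose innovations have unit variance and block correlation
(`rho_within` inside planted communities, `rho_between` across; the
implied covariance is checked for positive definiteness at construction),
additive white measurement noise (`noise_sd`), a per-session additive mean
offset (`session_offset_sd`) that exists purely so the pipeline's
mean-centering step has something to remove, and planted convergence.
Defaults (20 subjects, 2 sessions of 1100 volumes at TR 0.72 s,
`rho_within` 0.6, `rho_between` 0.1, AR 0.3) are a deliberately scaled-down
analogue of a ~90-subject two-session resting-state study: large enough
for stable group inference, small enough that every stage runs in seconds
on one CPU. Each (subject, session) draws from a disjoint fixed-offset
sub-stream of the seeded generator, so panels are pure functions of the
spec and invariant to generation order.

Convergence is planted as a *direct additive coupling*: the target ROI's
observed series receives each source series scaled by `strength`. An
earlier design used a shared latent source added to target and sources
alike, but marginalizing a shared factor connects the target to everything
correlated with its sources, so the planted edge list was not the model's
conditional-dependence graph and partial correlation (correctly) found
"extra" edges. With direct coupling applied to the noise-bearing source
series, the planted adjacency is exactly the conditional-dependence
structure the node-wise regression estimates.

One genuine subtlety remains and is worth knowing about: if a coupled
target also belongs to a correlated community, conditioning on the target
(a collider) induces real negative partial correlations between its
sources and the target's community siblings. These are correct detections
of the generative model, not false positives of the method. The package's
detector-calibration test therefore uses a design whose planted graph is
the *complete* dependence graph — targets as baseline-independent
singleton communities — and verifies sensitivity ≥ 0.9 with false
discovery ≤ 0.1 at the convergence threshold (α = 0.01); the
community-embedded design is used to verify partition recovery (adjusted
Rand index ≥ 0.9 via the γ-sweep) and convergence sensitivity.

What passing these tests shows — and does not show: the pipeline recovers
planted linear-Gaussian structure of realistic dimensions. Real fMRI adds
hemodynamic convolution, low-frequency drift, motion artefacts,
non-stationarity and spatially structured noise, none of which the
generator models; results on real data depend additionally on
preprocessing choices the package deliberately leaves out of scope.

## Problem sizes used by the test-suite

Oracle-equivalence tests run on graphs of ≤ 15 nodes against brute-force
enumeration (tolerance 1e-8 for regression coefficients, 1e-10 for
modularity, exact for integer metrics). Recovery tests use the
20-subject, 2 × 1100-volume, 30-ROI panel above with 100 consensus
initializations per γ; null-model tests use 200 rewirings; surrogate
calibration uses 50 single-subject AR(1) panels with 20 surrogates each.
These sizes were chosen so the full suite completes in well under a
minute while keeping every Monte-Carlo margin comfortable.

## Known limitations

* Louvain on signed weighted matrices optimizes the positive part only;
  a signed-modularity variant is not implemented.
* The consensus procedure assumes the thresholded agreement matrix
  eventually stabilizes; pathological cycling raises an error rather than
  returning a partial answer.
* Normal fits to binned distance distributions are descriptive summaries,
  not model-based density estimates; both available estimators are biased
  for heavily skewed weight distributions.
* The attack analysis treats edges as unweighted and node removal as
  all-or-none; cascading or partial failures are out of scope.
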