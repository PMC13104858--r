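---
title: "Incremental-cluster TFCE: model, algorithms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental-cluster TFCE: model, algorithms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictfce)
```

## The statistic being computed

Threshold-free cluster enhancement (TFCE) transforms a map of test
statistics so that each variable's value reflects both its own height and
the sizes of the supra-threshold clusters it belongs to, integrated over all
thresholds:

$$\mathrm{TFCE}(x) = \int_0^{h_{\max}} c(x, h)^{E}\, h^{H}\, dh,$$

where $c(x, h)$ is the size of the cluster containing variable $x$ among
variables at or above threshold $h$, $E > 0$ weights cluster extent and
$H \ge 0$ weights threshold height. The variables are either

* **FC edges**: the $N(N-1)/2$ off-diagonal entries of a symmetric
  ROI-by-ROI statistic matrix. Two edges are neighbours iff they share an
  endpoint ROI (network-based-statistic adjacency), so clusters are
  connected subgraphs of the ROI graph and $c$ counts **edges**; or
* **voxels**: elements of a 3D statistic volume under 6-, 18- or
  26-connectivity, where $c$ counts **voxels** and an isolated
  supra-threshold voxel is a singleton cluster of size 1.

A note on symbols: the extent exponent and the edge count of a complete FC
graph are both conventionally written $E$; in this package the exponent is
always the argument `E` and the edge count is always called `edge_count` /
`n_edges`, never abbreviated.

In practice the integral is discretized with a step `dh`, summing
$c(x, k\,dh)^E (k\,dh)^H\, dh$ over $k = 1, \dots, n_{th}$ with
$n_{th} = \lceil t_{\max}/dh \rceil$ and $t_{\max}$ the map's largest
positive statistic. The package provides three engines computing this
quantity, all exposed through `tfce_fc()` / `tfce_voxel()`:

* **reference** — recomputes connected components from scratch at every
  threshold with a fresh union-find. Cost grows as $O(N^2 n_{th})$ for FC
  data. It exists to be the slow, obviously-correct oracle and shares
  nothing with the incremental engine beyond the bin convention.
* **incremental** — the headline algorithm. Edges are bucketed into
  threshold bins once, then processed from the highest bin downward: each
  edge either lands inside an existing cluster in $O(1)$ or merges two
  clusters, relabeling the smaller one. Starting from $N$ singleton
  clusters, at most $N-1$ merges can ever occur, and union-by-size bounds
  total relabeling by $O(N \log N)$. After each bin the cluster edge count
  of every node is recorded in a matrix $S$ ($n_{th} \times N$); the
  cumulative integral $F[k, v] = \sum_{j \le k} S[j, v]^E (j\,dh)^H dh$ is
  then accumulated ascending, and each edge reads its TFCE value in $O(1)$
  at row `bin(edge)` and either endpoint column (both endpoints share a
  cluster at every threshold the edge survives, so the two reads agree
  exactly). Total cost $O(N^2 + n_{th} N)$: runtime is decoupled from the
  discretization precision.
* **exact** — no discretization. Between two consecutive values of the
  sorted statistics every cluster size is constant, so the integral is a sum
  of closed forms $c^E (b^{H+1} - a^{H+1})/(H+1)$ over the intervals between
  sorted heights (which is why $H = -1$ is unsupported). The implementation
  processes heights descending with lazily flushed running clusters: a merge
  freezes both constituents at the merge height and creates a fresh cluster
  with score zero holding parent pointers, and a variable's final value is
  recovered by subtracting its recorded entry score and walking up the
  parent chain. With one interval per distinct statistic this costs
  $O(N^3)$ for FC data — the most precise and the slowest engine.

### Voxel data as a graph

`voxel_to_graph()` maps a masked volume onto the same machinery: one node
per in-mask voxel, activated at its own statistic, and one edge per adjacent
in-mask pair weighted by the *minimum* of its endpoint statistics. At any
threshold, an edge survives exactly when both endpoints do, so the
connected components of the graph restricted to surviving nodes and edges
coincide voxel-for-voxel with classic 3D connected-component labeling of
the thresholded volume — the property the test suite verifies exhaustively
on random volumes at all three connectivities. Within a threshold bin the
incremental engine activates nodes before edges, so singleton clusters
always exist before edges try to join them. Out-of-mask voxels are absent
from the graph entirely, not zero-valued nodes. Adjacency is array-index
based; any NIfTI affine is carried through I/O untouched.

## Numerical conventions

These choices make results deterministic and reproducible across engines:

* **Non-strict thresholds.** A statistic exactly equal to a threshold
  belongs to the cluster at that threshold, so an edge's bin is
  `floor(stat/dh)` with exact floor semantics and no floating tolerance;
  users with statistics on bin boundaries get documented deterministic
  behaviour. The reference engine decides activity from the same bins, so
  engine differences are pure summation order (measured: 0 on the test
  grid).
* **Right-endpoint integration** from $h_1 = dh$: the $h = 0$ term
  contributes nothing for $H > 0$, and the single-edge discretized sum
  converges to $t^{H+1}/(H+1)$ from above as `dh` shrinks.
* **`nth` uses `ceiling`**, so $t_{\max}$ never loses its topmost bin, and
  it is recomputed per statistic map — including separately for every
  permutation, since each permuted map has its own $t_{\max}$.
* **Positive tail only.** Statistics $\le 0$ (or below `dh`) get TFCE 0.
  Negative-tail and two-sided inference run the negated map (CLI `--negate`,
  `permutation_test(tails = "both")` with Bonferroni doubling, off by
  default: the choice of tails is made explicit rather than silently
  two-sided).
* **Tied statistics** in the exact engine collapse into one height; all
  edges at a tied height enter before any interval below it is flushed, and
  the zero-length interval between ties contributes nothing.
* **Memory.** The accumulator stores $S$ as a dense $n_{th} \times N$
  integer matrix plus one running row of $F$ (the full $F$ matrix is only
  materialized by `ic_tfce_state()` for inspection). Any scheme reproducing
  $F$ bit-for-bit needs the information in $S$ — its change points are
  $O(n_{th} N)$ in the worst case — so no streaming variant can beat this
  bound while preserving exact results; at `N = 1000`, `dh = 0.001`,
  `tmax = 10` the matrix is ~40 MB. A `max_cells` guard (default $10^8$)
  errors with advice (increase `dh`, raise the budget, or switch to the
  exact engine) rather than silently allocating more.
* **Exact-engine accuracy.** Recovering an edge's value by subtracting
  scores bounds its *absolute* error by machine epsilon times the cluster
  score scale. Equivalence tests therefore assert $10^{-9}$ relative
  agreement with a small-value floor at $10^{-6}$ of the map maximum;
  entries a million-fold below the map scale cannot carry meaningful
  relative precision under any subtraction-based scheme.

## Permutation inference

`permutation_test()` implements max-statistic familywise error control:
the observed map's TFCE values are compared against the distribution of the
per-permutation *global maximum* TFCE under random relabelings (group-label
shuffles for two-sample designs, sign flips for one-sample), with

$$p(e) = \frac{1 + \#\{\text{perm}: \max \mathrm{TFCE}_{\text{perm}} \ge \mathrm{TFCE}_{\text{obs}}(e)\}}{n_{\text{perm}} + 1},$$

never zero by construction. Edgewise statistics are pooled-variance
two-sample t values (group 2 minus group 1) or one-sample t against zero;
zero-variance edges get statistic 0 with a warning. When `n_perm` exceeds
the number of distinct relabelings the test warns and keeps sampling with
replacement. A fixed seed fixes the entire permutation sequence, so the
three engines produce identical p-values under the same seed — the
equivalence proposition carried through inference.

`estimate_power()` repeats generation and testing, reporting per-edge
rejection frequencies. Within each repetition the same subject draw and the
same permutation sequence are reused across all requested `dh` values, so
between-`dh` power differences are paired comparisons free of data noise.
With 100 repetitions the binomial standard error of any power estimate is
at most $\sqrt{0.25/100} = 0.05$. Given a node-to-network labeling, edges
are grouped by their unordered network pair and `top_networks()` ranks
pairs by mean power (descending) — "top-ranked network" here means highest
mean rejection frequency over the pair's edges, one of several defensible
readings of network-level power.

The master seed spawns one independent stream per repetition (dataset) and
per test (permutations), so any repetition can be reproduced in isolation.

## What the generators emulate

`synth_stat_matrix()` emulates a group-level edgewise t-statistic matrix:
standard-normal noise, a zero-padded 2D Gaussian filter to induce the
spatial correlation structure real FC statistics exhibit, symmetrization by
averaging with the transpose, and (default) rescaling of the off-diagonals
to unit standard deviation. Two knobs are deliberate package choices the
underlying procedure leaves open: the filter width defaults to
$\sigma = N/40$ — proportional to $N$, so the correlation length stays a
fixed fraction of the parcellation across sizes, and wide enough to be
clearly visible at $N = 200$ — and the unit-SD rescaling restores the
t-like marginal scale the filter shrinks (smoothing divides the variance by
roughly $4\pi\sigma^2$), giving a non-degenerate threshold grid
($t_{\max} \approx 3$–4 at $N = 200$). Both are parameters, not constants.
Symmetrizing by averaging halves the variance of the independent
off-diagonal pair; the rescaling absorbs this.

`synth_group_dataset()` plants a block effect: per-subject edge values are
iid Gaussian, with `effect_size` (in noise-SD units) added at the effect
edges of one group. This models an idealized group difference — it has no
subject-level covariance structure, no site effects, and no spatial
correlation in the noise, so passing calibration and power tests here
demonstrates correctness of the inference machinery, not performance on
real fMRI. `synth_voxel_image()` similarly places smooth Gaussian blobs on
optional white noise.

## Validation design and problem sizes

The suite is organized around independent oracles: per-threshold component
labeling through igraph (`clusters_at_threshold()`,
`voxel_clusters_reference()`) cross-checks the C++ engines, which never
call igraph; explicit interval enumeration cross-checks the exact engine's
running-score mechanism; hand-derived triangle and 1D-strip values pin the
conventions. The headline equivalence claim is exercised on a grid of 108
synthetic matrices ($N \in \{10, 30, 80\}$, $dh \in \{0.01, 0.1, 0.25\}$,
$(E, H) \in \{(0.4, 3), (0.5, 2), (1, 1)\}$, four seeds) plus one
$N = 200$ matrix at the FC defaults, where the measured incremental-vs-
reference difference is exactly zero. Voxel cluster equivalence runs on
random $12^3$ volumes at 20 thresholds for each connectivity. Inference
calibration uses 200 simulated null datasets ($N = 30$, 10 + 10 subjects,
200 permutations each) and checks the familywise error at
$\alpha = 0.05$ against its binomial band $[0.02, 0.09]$; power lawfulness
uses 50–60 repetitions of 100 permutations at $N = 20$. These sizes were
chosen to estimate each property to useful precision while keeping the
whole suite in the tens of seconds; all of them are package choices
recorded here, and scale linearly if stressed further.

`scripts/acceptance.R` recomputes the headline measurement end to end —
generate a 200-ROI synthetic matrix, run both discretized engines at
`dh = 0.1`, `E = 0.4`, `H = 3`, report the maximum absolute per-edge
difference — from a caller-supplied seed.

## Known limitations

* Node-sharing (NBS) edge adjacency only; anatomical-proximity (SPC) edge
  adjacency is out of scope.
* Group designs are one- and two-sample t; no GLM contrasts, no exchange-
  block structure, no FDR alternatives to max-statistic FWER control.
* The benchmark harness reports wall-clock ratios on whatever hardware it
  runs; timings are informational and never part of correctness claims.
* Voxel adjacency is isotropic in index space; anisotropic voxel sizes are
  not weighted.
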