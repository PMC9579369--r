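---
title: "Full-scale network analysis with persistent homology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-scale network analysis with persistent homology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phnet)
```

## The model

Functional connectivity analysis conventionally binarizes a correlation
matrix at one threshold and studies the resulting graph. The threshold is a
free parameter with no accepted selection rule, and the graph topology is
sensitive to it. `phnet` instead treats the weighted network as a finite
metric space and studies the *entire family* of graphs/complexes obtained as
the threshold sweeps the full range of distances.

Concretely, for a recording with channels $x_1,\dots,x_n$:

* the distance between nodes is $d_{ij} = \min(1/|r_{ij}|,\ \mathrm{cap})$,
  the reciprocal of the absolute Pearson correlation;
* ISOMAP converts the $n \times n$ distance matrix into a point cloud $X$
  whose Euclidean geometry approximates the network's intrinsic geometry;
* the Vietoris–Rips complex $\mathcal{R}(X,\varepsilon)$ contains the
  simplex $[x_{i_0},\dots,x_{i_k}]$ iff all pairwise distances among its
  vertices are $\le \varepsilon$; sweeping
  $\varepsilon \in [0, \varepsilon_{\max}]$ with
  $\varepsilon_{\max} = \max_{ij} d_{ij}$ gives a nested filtration;
* persistent homology over the two-element field records each component
  (dimension 0), loop (1) and void (2) as an interval
  $[\varepsilon_{\mathrm{birth}}, \varepsilon_{\mathrm{death}})$;
* diagrams are compared with the bottleneck distance $W_\infty$ (largest
  single matched discrepancy, sup-norm ground metric) and the
  $p$-Wasserstein distance $W_p$ (aggregate discrepancy).

The modelling assumptions worth stating are: correlation magnitude is an
adequate coupling measure (anti-correlation counts as coupling);
the recording is stationary over the analysed window; and topology that is
robust across thresholds is the scientifically meaningful part of the
network. The method does not model directionality or lag.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| bands | θ 4–7, α 7–14, β₁ 14–20, β₂ 20–30, γ 30–40 Hz + full | Hz | the canonical EEG decomposition used throughout this line of work |
| `cap` | 1000 | distance | keeps $1/|r|$ finite for $r \to 0$; must exceed 1, the distance at perfect correlation |
| `isomap_k` | 7 (module), 12 (pipeline) | neighbours | see below |
| `target_dim` | auto | — | keep components with eigenvalue $> 10^{-8}\lambda_{\max}$; on 60-node synthetic cohorts this lands at 32–36 dimensions, i.e. a data-driven dimension well below $n$ |
| `max_dim` | 2 | — | triangles suffice to measure components and loops, the dimensions where reliable group structure appears; use 3 when voids are of interest |
| `eps_max` | auto | distance | maximum inter-node distance: the complex reaches full connectivity, so nothing is thresholded away |
| `fs` | 20 | steps | the customary number of filtering steps; coarse enough to suppress noise bars, fine enough to keep persistent ones |
| `e` | 0.01 | distance | bottleneck accuracy for the approximate column; `e = 0` requests the exact optimum |
| `p` | 1 | — | first-order Wasserstein: total feature displacement |
| `min_length` | $0.1\,\varepsilon_{\max}$ | distance | feature/noise split for reporting; does not affect distances |

**Neighbourhood size.** The embedding module defaults to $k = 7$, a common
small-neighbourhood choice. The pipeline default is $k = 12$ for a
structural reason: in a modular network whose strongly-coupled blocks have
$m$ channels, every node's $m-1$ nearest neighbours lie inside its own
block, so any $k < m$ disconnects the k-NN graph into the blocks. With the
synthetic cohorts' 10-channel blocks, $k = 12$ guarantees inter-block
bridges. When the graph is disconnected anyway, `isomap_embed()` refuses
and reports both the component count and the smallest connecting $k$.

**Homology at the top simplex dimension.** A Rips $d$-skeleton contains no
$(d{+}1)$-simplices, so no dimension-$d$ class can ever die: every such
class is an essential artifact of truncation, not a data feature.
`persistent_homology()` therefore reports dimensions $p < d$ by default
(`drop_top = TRUE`). This convention is why a filtration built with
`max_dim = 3` shows dimension-3 feature count 0, and why measuring the
sphere's void requires `max_dim = 3`. The square illustrates it:

```{r square}
f <- rips_filtration(generate_fixture("square"), max_dim = 2, eps_max = 2)
persistent_homology(f)
```

The 2-skeleton of the full complex on 4 vertices carries a spurious
2-cycle; with `drop_top` it is not reported, and the diagram contains
exactly the square's components and its loop $[1, \sqrt 2)$.

## What the synthetic generator emulates — and what it does not

`cohort_spec()` draws channels as a stationary Gaussian process with an
exact block correlation structure: correlation `within_block_r` inside each
block, `between_block_r` across blocks, via a Cholesky transform, seeded
and reproducible. The defaults (60 channels, six blocks of ten,
within 0.6, between 0.2, 4000 samples) emulate the *geometry* of a
task-EEG connectivity matrix: modular organisation with reciprocal
distances spanning roughly 1.5–7, so that the data-driven
$\varepsilon_{\max}$ falls in the range where full-scale filtering of such
networks actually operates. An optional oscillator mode adds a shared
sinusoidal carrier per block so the band filters have narrow-band content
to act on.

The generator deliberately does **not** model volume conduction, 1/f
spectra, non-stationarity, artifacts, or electrode geometry. Passing tests
therefore demonstrate that the pipeline's mathematics is correct and that
it separates known connectivity structure; they do not certify performance
on clinical recordings, where preprocessing quality and non-stationarity
dominate.

Geometric fixtures (circle, Fibonacci-lattice sphere, unit square,
collinear points) provide point clouds whose homology is known a priori;
they are the oracles for the Rips/persistence stack.

## Numerical choices

* **Exact vs. grid filtration values.** By default a simplex enters at its
  true maximum pairwise distance. With `fs` set, values are snapped
  *upward* to the grid $\{i\,\varepsilon_{\max}/Fs\}$ (a simplex never
  appears before it exists); a $10^{-9}$ relative guard keeps values
  already on the grid in place. Snapped minus exact is always in
  $[0, \varepsilon_{\max}/Fs)$, so the grid converges to the exact
  filtration as $Fs \to \infty$.
* **Tie order.** Simplices are sorted by (value, dimension, lexicographic
  vertex tuple) — deterministic, and faces always precede cofaces.
* **Coefficients.** GF(2), the standard choice for persistence; zero-length
  intervals are discarded (invisible in barcodes and feature counts).
* **Two independent algorithms.** The production path is boundary-matrix
  column reduction in filtration order (C++). The oracle recomputes
  intervals from persistent Betti numbers via GF(2) ranks of boundary
  submatrices and inclusion–exclusion — no pairing, no reduction. Their
  exact multiset agreement on fixtures and random clouds is asserted in the
  test suite.
* **ISOMAP.** Geodesics are exact Dijkstra distances on the symmetric k-NN
  graph (no landmark approximation; $n$ is small). Classical MDS keeps
  only positive-eigenvalue components; negative eigenvalue mass (the
  non-Euclidean part of the geodesic geometry) is reported in the
  embedding report rather than silently dropped. With a complete neighbour
  graph the procedure reduces to classical MDS of the input — an oracle
  equivalence used in the tests, which also cross-check against an
  independent ISOMAP implementation.
* **Bottleneck distance.** Binary search over the sorted candidate costs
  (all point-to-point costs and diagonal projections), with a
  bipartite-matching feasibility check (augmenting paths on the
  diagonal-augmented graph) at each probe; a $10^{-12}$ slack absorbs
  floating-point ties. With `e = 0` the search runs to the exact optimum;
  with `e > 0` it stops when the bracket is narrower than `e`, so the
  error is at most `e`. The "exact vs. approximate" pairing of results
  mirrors the two conventional reporting modes (`e = 0` and `e = 0.01`).
* **Wasserstein distance.** Solved exactly as a square assignment problem
  on the $(n{+}m)\times(n{+}m)$ diagonal-augmented cost matrix with a
  shortest-augmenting-path solver, verified against exhaustive permutation
  enumeration in the tests.
* **Essential classes.** Distances exclude them by default
  ($\infty-\infty$ matching is ill-defined); `essential = "truncate"`
  clips them to $\varepsilon_{\max}$ when cross-run comparability of the
  essential structure matters. Comparing diagrams computed to different
  $\varepsilon_{\max}$ triggers a warning, once per band in group tables.
* **Stability bound.** The quantitative stability property asserted in the
  tests is: if every point moves by at most $\delta$ (Euclidean
  displacement per point; equivalently the sup over points of the
  displacement norms), every entry of the distance matrix changes by at
  most $2\delta$, and the bottleneck distance between the Rips diagrams is
  at most $2\delta$ in every dimension. Both clouds are filtered to a
  common $\varepsilon_{\max}$ so their finite structures align.
* **Band filter.** Two forward–backward passes of an order-2 Butterworth
  band-pass (8th-order steady-state magnitude, exactly zero phase). A
  single higher-order transfer-function filter is numerically fragile for
  the narrow 4–7 Hz band at typical sampling rates, which is why a cascade
  is used. Odd-symmetric reflection padding suppresses (but cannot
  eliminate) edge transients; filter-quality contracts are steady-state
  properties and are asserted on the record interior.
* **Indexing.** Node indices are 1-based everywhere, including exports;
  file headers say so.

## Open design points, resolved

* *Cohort aggregation.* Group-level analysis uses one correlation matrix
  per cohort (the recording passed per cohort is the group-level record);
  per-subject diagrams can be produced by running the pipeline per subject
  and comparing diagram lists — the aggregation scheme is the user's
  explicit choice, not hidden.
* *Sign of correlations in density thresholding.* $|r|$ is used, for
  consistency with the reciprocal-magnitude distance.
* *Whether filtering precedes epoching.* The band module filters whatever
  record it is given and takes no position.
* *Grid semantics.* Both exact-value and `fs`-grid filtrations are
  available, because downstream software conventions differ on whether the
  step parameter quantizes the filtration or only the rendering.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
60-channel, 4000-sample synthetic cohorts for the end-to-end runs; random
clouds of up to 8 points (where the rank oracle is exact and fast) for the
50-cloud reduction-vs-oracle equivalence; diagrams of up to 30 points for
the metric contracts; 20-point circles and 40-point spheres for the
known-homology checks. These sizes exercise every code path, including the
full $\binom{60}{2}$-edge filtration with tens of thousands of simplices.

## Known limitations

* Pearson correlation is undirected and lag-free; coherence, phase-locking
  or causal measures are out of scope.
* Cap-valued distances (near-zero correlations) compress all very weak
  couplings to one scale; results above the cap are not interpretable.
* The bottleneck/Wasserstein implementation targets diagrams of up to a
  few hundred points (cubic assignment solver); it is not tuned for
  very large diagrams.
* No statistical inference is attached to the distances: the package
  reports geometry, not p-values. Permutation nulls are a natural
  extension but are not implemented.
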