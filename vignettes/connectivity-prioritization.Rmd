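---
title: "Prioritizing landscape genetic connectivity with circuit theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing landscape genetic connectivity with circuit theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connscape)
```

## The problem

Functional connectivity — gene flow among populations mediated by the
landscape — is rarely made actionable in spatial conservation planning.
`connscape` implements a two-step prioritization that combines two kinds of
model a landscape geneticist typically already has:

1. a **resistance surface**: a raster whose cell values quantify impedance
   to gene flow (here following the convention of values from 1, least
   resistance, upward, on a 1200 m grid), and
2. a **genetic network**: populations (e.g. hierarchically clustered lek
   sites) as nodes with projected coordinates, and weighted edges carrying
   genetic covariance and optionally an externally computed betweenness.

The network tells us *which* population pairs exchange genes and how much
those connections matter to range-wide connectivity; the circuit analysis of
the resistance surface tells us *where* on the landscape that exchange is
expected to flow. The product is a set of spatial action maps: cumulative
connectivity, percentile-thresholded priority landscapes, per-edge
delineated pathways, overlay statistics against conservation polygons, and
impedance (cultivation/woodland) exceedance maps.

## The circuit model

The raster is converted to an electrical network: each non-nodata cell is a
vertex, adjacent cells are joined under queen's-case (8-neighbour)
adjacency, and the link between two cells carries resistance equal to the
arithmetic mean of their cell resistances, multiplied by $\sqrt{2}$ for
diagonal neighbours to account for the longer step. This is the standard
raster circuit convention; rook-4 adjacency is available for sensitivity
checks.

For each network edge $(s, t)$ we inject a unit current at $s$ and ground
$t$, solving the conductance-weighted graph Laplacian system
$L\,v = e_s - e_t$. Then:

* the **effective resistance** $R_{\mathrm{eff}}(s,t) = v_s - v_t$ is the
  two-terminal resistance of the whole landscape between the pair
  (symmetric in $s$ and $t$, and monotone: raising any cell's resistance
  can never lower it);
* the **current map** assigns each cell half the sum of the absolute branch
  currents incident to it, with the two terminal cells carrying the full
  injected current (1). Current concentrates where gene flow has few
  alternative routes, so high-current cells are pinch points.

Per-cell current conventions differ subtly between implementations; the
half-sum-of-incident-branches rule used here makes a cell on a single
serial path carry exactly the through-current, and is validated cell-by-cell
against a dense Laplacian-pseudoinverse oracle in the test suite.

Summing current maps over all network edges gives the **cumulative
connectivity map** — the object everything downstream consumes. Pairs are
summed unweighted (no scaling by genetic covariance), so the cumulative map
counts connections, not their genetic strength.

### Numerical choices

* Solver: sparse Cholesky factorization of the Laplacian grounded at one
  reference vertex per component (`Matrix`), factorized once and reused
  across all pairs of a network. Single pair solves verify a relative
  residual of at most 1e-8 and error out beyond it.
* Disconnected terminal pairs yield a flagged infinite resistance with an
  all-zero current map and a warning — real landscapes contain isolated
  fragments and should not abort a 10^4-pair run.
* Node coordinates snap to the containing cell centre; points exactly on a
  cell boundary resolve to the lower row, then lower column index. A node
  landing on a nodata cell is rescued to a valid neighbour within one cell,
  else the solve errors naming the node.
* Effective resistances among $k$ terminals are obtained with $k$ grounded
  solves (not $k(k-1)/2$) using linearity.

## Prioritization and delineation

The cumulative map is thresholded at the 50th to 95th percentile in steps
of 5, plus the 99th. Percentiles are linear-interpolation quantiles (R type
7) over **all** non-nodata cells, zeros included — whole-raster percentile
semantics; `include_zero = FALSE` restricts the base to cells carrying
current. Cells equal to the threshold are kept (a $\geq$ rule: the
conservative, larger footprint), with a value-scaled tolerance of
$10^{-9}\times$ the value range so that interpolation round-off never
excludes a tied cell; in the limit of a vanishing level every cell passes.

Edges are prioritized on the network side: the spanning tree **maximizing**
total genetic covariance is extracted (such trees are often labelled
"minimum spanning trees" when networks are expressed in genetic distance;
both senses are supported, maximum-covariance being the default since the
weights here are covariances), and its edges are ranked by shortest-path
edge betweenness, descending. Betweenness defaults to reciprocal-weight
edge lengths (1/weight), so high-covariance edges attract shortest paths;
unit lengths are available. Externally supplied betweenness attributes are
preferred when present, because published network models often carry their
own betweenness whose exact convention (full network vs tree-restricted,
normalization) may be unknown — the ranking preserves whichever is loaded.
All ties, in tree construction and in ranking, break on ascending edge id
for reproducibility.

Each top-ranked edge's pathway is delineated by thresholding *that edge's
own current map* at its 99th, 99.5th and 99.75th percentiles, giving nested
masks: buffers around the pair when the nodes are proximal, stepping-stone
bands when distal.

## Overlay statistics

Polygon sets (priority areas for conservation, PACs; management zones, MZs)
are rasterized by cell-centre containment (a cell belongs to a zone when
its centre falls inside or on the boundary of any polygon). Reported
statistics:

* proportion of cumulative connectivity within PACs — **value-weighted**
  (sum of cell values), since "proportion of cumulative gene flow" is a
  value sum; the area-weighted proportion is returned alongside;
* the decile partition: cells binned by 10% quantiles of cumulative value,
  each bin's connectivity split inside/outside PACs (rows conserve mass to
  1e-9);
* the threshold-area table: per level, in/out areas, their ratio, and the
  ratio normalized to the most inclusive (50th) level — an index of how
  strongly high-connectivity landscapes concentrate inside PACs;
* per-pathway percentage overlap with PACs.

The **random-placement baseline** asks how much connectivity equally sized
random polygons would capture. The procedure here translates each observed
polygon (optionally rotating by a random right angle about its centroid) to
a uniform-random position fully inside the grid, rasterizes, and recomputes
the value-weighted proportion, over `n_reps` replicates from one seed. This
is an interpretation of an "equal-area bootstrap spatial sample": it
preserves each polygon's area and shape exactly, which is the property the
comparison needs. On a uniform map the observed/expected ratio is 1 by
construction (verified to Monte-Carlo tolerance in the tests).

## Impedance screening

Land-cover layers are screened with a circular moving window of radius
6.44 km (per-cell mean over cells whose centres fall within the radius).
Windows truncate at raster edges and nodata — the mean is taken over
available cells — which avoids biasing range-edge fractions toward zero.
Fractions are then resampled to the 1200 m analysis grid (block mean for
fractions, nearest for categorical layers; same-CRS integer aggregation
factors only, which is all the analysis needs).

Exceedance rules are per management zone with **strict** inequality
("greater than"): by default cultivation > 0.25 in MZs I, II, IV and V, and
woodland canopy > 0.10 in MZs I, II and IV. The source models circulate two
variants of the MZ V cultivation threshold (0.25 and 0.05); both ship
(`impedance_rules("default")` and `impedance_rules("mzV5")`) and neither is
chosen silently. Exceedance intersected with the top-5% (95th percentile)
connectivity mask, split inside/outside PACs, yields the action-map summary
(areas in km² with ha twins, ha = 100 km²) and a 0/1/2-classified action
raster.

## The synthetic scene

The deposited empirical surfaces behind the original analysis are
range-wide downloads; the package instead ships a generator producing all
four input classes with the statistical structure the analysis assumes:

* **resistance**: Gaussian-smoothed white noise affinely rescaled to
  (1, 161) — convolution is simpler and dependency-lighter than spectral
  synthesis and gives the same qualitative autocorrelation — with optional
  planted unit-resistance corridors drawn as 8-connected raster lines;
* **nodes**: sampled without replacement with weight proportional to
  reciprocal resistance, because leks concentrate in permeable habitat and
  this couples node placement to the landscape the way the empirical
  models assume;
* **network**: edges by a Gabriel/complete/radius rule, weights
  $\exp(-\lambda R_{\mathrm{eff}})$ plus Gaussian noise floored at 1e-6 —
  weights decay with *effective resistance*, not Euclidean distance, so
  network and landscape structure are mutually consistent and recovery
  tests are meaningful; bridging edges are added if the rule leaves
  components;
* **polygons**: PACs as buffered circles around k-means node clusters with
  the buffer radius bisected until coverage is within about 1% of the
  target (default 0.30, echoing conservation designs covering roughly a
  quarter to a third of a range); MZs as a vertical-band partition;
* **land cover**: thresholded smoothed fields (binary patches for
  cultivation, patch-masked fractions for canopy).

Every generator is driven by a single integer seed and is bit-reproducible.
The default study scene is 50 × 50 cells (1200 m) with 15 nodes — sizes at
which the full pipeline, including 200 bootstrap replicates, runs in
seconds while exercising every code path; the scaling to larger grids is
in the sparse solver, not the analysis logic.

What the generator does **not** emulate: anisotropy and terrain-driven
resistance structure, the empirical models' specific covariate effects,
multi-scale lek clustering, genotype-level noise, and realistic polygon
shapes. Passing tests therefore demonstrate algorithmic correctness and
end-to-end recovery of planted structure, not that empirical conclusions
transfer to any particular real landscape.

### Micro-fixtures

`fixture_suite()` bundles analytically solvable landscapes: a 1×3 chain
(series law: endpoint resistance $(2+4)/2 + (4+6)/2 = 8$), a uniform 2×2
queen-8 grid (side-pair resistance 0.5428932..., frozen from the dense
pseudoinverse oracle), a two-component grid (infinite resistance), and the
corridor scene. The corridor fixture's corridor is deliberately a 25-cell
*interior* segment — 1% of the 2500-cell grid — so that the strictest
delineation level (the 99th percentile, which keeps exactly 25 cells) can
in principle contain it; an edge-to-edge corridor would be arithmetically
impossible to cover at that level regardless of solver quality.

## Workflow

The `analysis/` scripts run the stages in order over a generated scene
(`01_simulate` → `05_impedance`), writing tables under `results/`;
`run_pipeline()` performs the same end to end in one call. For large edge
sets, current maps are streamed into the accumulator rather than retained
(`keep_maps = FALSE`); only the ranked tree edges are re-solved for
pathway delineation, which is all delineation needs.

```{r example, eval = FALSE}
scene <- synthetic_scene(n_rows = 50, n_cols = 50, n_nodes = 15, seed = 1)
res <- run_pipeline(scene, pipeline_config(n_bootstrap = 200, seed = 1))
res$connectivity_within$proportion   # share of connectivity inside PACs
res$bootstrap$ratio                  # observed vs random-placement baseline
```

## Known limitations

* Terminals are single cells; analyses that treat population polygons as
  multi-cell source regions are out of scope.
* Rasterization supports simple rings without holes; resampling supports
  aligned integer factors (no general warping or reprojection).
* Raster IO is the plain-text ESRI ASCII grid (CRS carried as a label
  only); polygons travel as GeoJSON.
* No smoothing or gap-bridging of threshold masks — delineated pathways can
  be discontinuous by design, reflecting stepping-stone connectivity.
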