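---
title: "Methods: proximity of gene lists in pathway space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity of gene lists in pathway space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathspace)
```

## The model

`pathspace` treats a curated gene-interaction network as a fixed geometric
object: an undirected, unweighted, simple graph whose vertices are gene
symbols, equipped with a precomputed 2D layout. Two distinct geometries
coexist on this object and the package keeps them strictly separate:

* **graph geometry** — hop counts (shortest-path edge counts). All
  statistics live here.
* **layout geometry** — Euclidean positions in the unit square. All
  visualization lives here.

The statistical question is: *are two gene lists closer in graph geometry
than random lists of the same sizes?* For lists $L_1$ (size $m$) and $L_2$
(size $k$) on distance matrix $d$,

$$ T(L_1 \to L_2) \;=\; \frac{1}{m}\sum_{g \in L_1}\;\min_{h \in L_2} d(g, h), $$

the average hop distance from each $L_1$ gene to its first nearest
neighbor in $L_2$. Genes in both lists contribute 0 (each is its own
nearest neighbor); a gene whose minimum is infinite (other component) is
excluded from the average, and only if *every* term is infinite is the
statistic undefined (an error). The null distribution is built by drawing,
independently per replicate, two uniform without-replacement vertex
samples of sizes $m$ and $k$ and recomputing $T$; the p-value is
left-tailed (small distance = proximity) with the add-one correction
$p = (1 + \#\{T_{null} \le T_{obs}\})/(n_{perm}+1)$, and the z-score
$(T_{obs} - \bar T_{null})/\mathrm{sd}(T_{null})$ standardizes across
list-size pairs, since larger lists sit closer by chance.

### Direction convention

$T$ is directed: mean-of-minima from `from` into `to` is not the same as
the reverse (a concrete counterexample ships in the tests: on the packaged
toy space $T(L_1\to L_2)=1.25$ while $T(L_2\to L_1)=1$). The package's
default is the directed `from_to` variant; a `symmetric` option averages
the two directed values. The choice of default was pinned by the toy
space: the directed variant reproduces the worked value 1.25 exactly,
which is the package's reference behavior, so `from_to` is the default.

### Assumptions

* The graph is meaningful as an unweighted object; edge confidence or
  sign is not modeled.
* The null of "random gene lists" is uniform over vertices, **not**
  degree-matched. Lists concentrated on hubs will look proximal partly
  because hubs are close to everything; a degree-preserving null is a
  deliberate extension point, not the default.
* Gene symbols are matched case-sensitively with no alias resolution; the
  caller is responsible for using the graph's own vocabulary
  (`validate_membership` / `intersect_with_graph` make this explicit).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `nperm` | 10000 | replicates | resolves p-values to 1e-4; the calibration tests use 199 (resolution 5e-3) to keep simulations fast |
| `seed` | caller-supplied | — | one integer drives the entire null loop; results carry it for exact replay |
| `direction` | `from_to` | — | pinned by the toy space (above) |
| `projection_radius` | 0.05 | fraction of unit-square diagonal | kernel support; small enough that separate modules stay visually distinct on a few-hundred-vertex layout |
| `silhouette_radius` | 0.03 | fraction of diagonal | mask radius around the vertex cloud; smaller than the projection radius so the landscape keeps the graph's outline |
| `grid_resolution` | 400 | pixels/side | crisp rasters at publication size; property tests run at 48–200 |
| `kernel` | `linear` | — | triangular `max(0, 1-u)`; compact support makes the zero-beyond-radius contract exact. `gaussian` (truncated at `u=3`) is smoother but never exactly zero inside its support |
| `aggregation` | `max` | — | per-pixel maximum keeps overlapping disks from saturating; `sum` (capped during normalization) accentuates dense clusters |

Radii are scale-free because every layout is normalized on load by an
aspect-preserving affine map into the unit square — the same network in
different coordinate units produces the same landscape.

## Projection and silhouette

For pixel center $p$ and vertex $v$ with signal $s_v$, the raster value is
$\mathrm{agg}_v \; s_v \, K(\lVert p - xy(v)\rVert / (r\sqrt2))$, then the
grid is rescaled by its maximum into $[0,1]$ (so scaling all signals by a
positive constant changes nothing). The silhouette mask keeps a pixel iff
it lies within the silhouette radius of *any* vertex, signal or not;
masked pixels are `NA`. Pixel convention: row-major, origin at the lower
left, pixel $(i,j)$ centered at $((j-\tfrac12)/R, (i-\tfrac12)/R)$ — fixed
so raster tests can be exact.

Signal decays with **Euclidean layout distance**, not graph distance. For
a layout that places interacting genes together the two broadly agree;
where they disagree (long-range edges the layout could not shorten) the
landscape follows the picture, which is what a density overlay is for.
Graph-geodesic decay would be a different, complementary renderer. None of
the statistics depend on this choice, or on any projection parameter.

## Numerical choices

* Distances come from breadth-first search over the full graph
  (`igraph::distances`, unweighted) and are held dense; the graphs the
  package builds or ships are desk-scale, and even the ~13,000-vertex
  reference networks this method targets fit a dense double matrix in a
  few gigabytes. `Inf` marks cross-component pairs and round-trips
  through the TSV interchange format.
* The add-one p-value estimator never returns 0, so downstream
  `-log10(p)` transforms are safe; the smallest attainable value is
  $1/(n_{perm}+1)$.
* A degenerate null (zero standard deviation, e.g. full-vertex-set lists)
  reports `z_score = NA`; the p-value formula still applies.
* The plotted rejection region ends at the type-7 empirical
  $\alpha$-quantile of the null sample — R's default interpolation, fixed
  explicitly so the drawn threshold is reproducible elsewhere.
* Hub ranking breaks degree ties lexicographically by gene symbol, making
  `top_hubs` deterministic across platforms.
* Generators restore the caller's RNG state: `random_space`,
  `sample_lists` and `null_distribution` are pure functions of their
  arguments, seed included.

## What the synthetic generator emulates — and what it does not

`random_space` grows a preferential-attachment graph (scale-free-like
degree tail, guaranteed connected) and lays it out force-directed; tests
and simulations use 150–200 vertices with 2 edges per new vertex, sizes at
which the degree tail and hub structure of curated interaction networks
are already visible while a full distance matrix stays instant.
`sample_lists` draws either uniform lists (the null's own model) or
"neighborhood" lists — a BFS ball around a center, truncated to size with
random tie-breaking — which plant the proximity that power simulations
must detect.

What it does **not** emulate: pathway annotation structure (modules here
are purely topological), literature-curation bias, edge weights/signs, or
the exact degree distribution of any real database. Consequently, the
passing calibration and power tests show that the statistic and its null
are internally correct and sensitive to planted topology — not that any
particular biological pair of lists will or will not reject on a real
network. Simulation sizes in the suite (a 200-vertex space, 500
calibration repetitions at 199 permutations, 100 power repetitions at 99)
were chosen as the smallest runs whose binomial error bands are decisive.

## Limitations

* One pair of lists per test; all-pairs comparisons across many lists are
  loopable by the caller but receive no multiplicity correction here.
* The uniform null ignores degree: interpret proximity of hub-heavy lists
  with care (see Assumptions).
* Landscapes are qualitative by design — the raster normalization
  discards absolute signal scale, and no claim is made that pixel values
  match any other implementation of density projection.
* Very sparse or fragmented graphs erode the statistic's sample size
  through the infinite-term exclusion; the message reporting excluded
  genes should be heeded.
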