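# collagraph

Graph-theoretic quantification of 3D cell-mediated collagen remodeling.

Mesenchymal stem cells embedded in a type I collagen hydrogel pull on and
re-align the fibrillar matrix around them. Two-channel 3D confocal stacks
capture this process: a fluorescence channel shows the cell nuclei and a
second-harmonic-generation (SHG) channel shows the collagen. `collagraph`
turns such stacks into quantitative per-sample metrics of remodeling, for
tissue engineers and cell biologists who need to compare collagen
organization across conditions and time points.

## The model

1. **Cell-graph.** Nuclei are segmented by Otsu thresholding (the threshold
   minimising the intra-class variance `σ²_w(t) = p₁σ₁² + p₂σ₂²`) and
   connected-component labeling; each nucleus centre of mass becomes a graph
   vertex, and an edge joins vertices `u`, `v` whenever their Euclidean
   distance `d(u,v) ≤ 55 µm` (about two rounded cell diameters; the
   threshold is configurable and a 10–180 µm sweep is provided).
2. **Voronoi compartments.** The voxel grid is partitioned by nearest-seed
   assignment in physical (µm) space, seeded either at the nodes or at the
   edge midpoints, so each collagen voxel belongs to exactly one cell or one
   cell–cell link.
3. **Collagen Alignment Index (CAI).** In each edge compartment the per-voxel
   intensity gradient `∇I` is compared with the edge vector `e`;
   `θ = arccos(∇I·e / |∇I||e|) ∈ [0°, 180°]` is accumulated into a histogram
   weighted by `|∇I|` and normalized to a pdf. The CAI is the pdf mass in
   `[60°, 120°]`: gradients perpendicular to the edge (`θ = 90°`) mark
   perfect alignment, so CAI → 1 means a fully remodeled link, while
   uniformly random 3D gradients give CAI ≈ 0.5.
4. **Cell/Global Dissatisfaction Level (CDL/GDL).** Per node, all gradients
   of the node's compartment are summed into a net pull `F`; `F` is written
   as a linear combination of the incident edge vectors, `E·w = F`, using
   the minimum-norm solution `w = Eᵀ(EEᵀ)⁻¹F` when the node has more than
   three edges and deterministic hypothetical edges (cross products) when it
   has fewer. The CDL of an edge is the norm of the vector sum of its two
   endpoints' projected forces — zero when the cells pull against each other
   in balance — and the GDL is the CDL sum normalized to image size.
5. **Phase statistics.** Per-sample angle pdfs, clipped to `[60°, 120°]`, are
   compared with a weighted two-sample Kolmogorov–Smirnov test, and staged
   into remodeling phases (I/II/III) by SVD projection plus k-means.

A seed-deterministic synthetic generator (planted nuclei, oriented stripe
collagen fields, controllable gradient-angle distributions and planted net
pulls) makes every stage testable without microscopy data.

## Worked example

```r
library(collagraph)

# a synthetic sample: 48^3 voxels, 8 nuclei, 70% of collagen blocks aligned
spec <- synthetic_spec(shape = c(48, 48, 48), n_nuclei = 8,
                       fiber_mode = "mixture", mixture_fraction = 0.7, seed = 7)
gen      <- generate_nuclei_channel(spec)
graph    <- build_cell_graph(gen$truth, link_threshold_um = 55)
collagen <- generate_collagen_channel(spec, graph)

res <- run_pipeline(gen$stack, collagen, run_config())
res
#> <pipeline_result>
#>   nuclei: 8, edges: 28
#>   CAI: 0.6738
#>   GDL: 0.346954

glance(res$graph)
#> # A tibble: 1 × 5
#>   n_nodes n_edges mean_degree n_isolated link_threshold_um
#>     <int>   <int>       <dbl>      <int>             <dbl>
#> 1       8      28           7          0                55

head(res$edge_cai, 3)
#> # A tibble: 3 × 4
#>       u     v   cai n_voxels
#>   <int> <int> <dbl>    <int>
#> 1     1     2 0.720     1957
#> 2     1     3 0.825     7776
#> 3     1     4 0.473     6407

glance(res$angle_dist)
#> # A tibble: 1 × 4
#>   n_values total_weight peak_deg usable
#>      <dbl>        <dbl>    <dbl> <lgl>
#> 1   110592    48784925.     89.5 TRUE
```

The sample CAI of 0.67 sits between the fully random baseline (≈ 0.5) and
perfect alignment (1), consistent with the planted 70% aligned fraction; the
pooled angle histogram peaks at ≈ 90°, and 22 of 28 edges exceed the 0.6
highlight threshold (`res$report$n_highlighted`). The GDL of 0.35 is the sum
of per-edge dissatisfaction weights divided by the voxel count; it shrinks
toward 0 as the planted pulls cancel. `autoplot(res$angle_dist)` draws the
histogram with the CAI window shaded, and `autoplot(res$graph)` the weighted
graph projection.

A command-line front end with the same stages (`synth`, `segment`, `graph`,
`cai`, `cdl`, `phases`, `sweep-threshold`, `run`) lives at
`inst/cli/collagraph.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","collagraph.R",package="collagraph"))')" \
  run --nuclei nuclei.tif --collagen shg.tif --spacing 2,1,1 --out results/
```

## Package layout

- `R/` — segmentation, cell-graph, Voronoi partition, alignment (CAI),
  dissatisfaction (CDL/GDL), phase statistics, synthetic generator,
  pipeline, I/O (TIFF/GraphML/CSV/JSON/YAML).
- `tests/testthat/` — unit, property and acceptance tests; all fixtures are
  generated in code.
- `vignettes/collagen-remodeling.Rmd` — the methods vignette: model,
  parameter choices, numerical conventions, limitations.
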