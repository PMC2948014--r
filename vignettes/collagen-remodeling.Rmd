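---
title: "Quantifying 3D cell-mediated collagen remodeling with cell-graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D cell-mediated collagen remodeling with cell-graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collagraph)
```

## The problem and the model

Cells seeded in a type I collagen hydrogel compact and re-align the fibrous
matrix around them, and they do so cooperatively: the alignment between a
*pair* of cells is the signature of interest, not bulk fiber anisotropy.
`collagraph` models a two-channel 3D stack (nuclei fluorescence + SHG
collagen) as a **cell-graph**: one vertex per segmented nucleus, an edge
between every pair of nuclei closer than a link threshold. Collagen
organization is then read out of the SHG channel through per-voxel intensity
gradients — at the magnification where single fibrils cannot be segmented,
the gradient direction is the available surrogate for local fiber
organization — and every gradient is attributed to exactly one graph element
through a discrete Voronoi partition of the voxel grid.

Two metrics summarise a sample:

- **CAI** (Collagen Alignment Index): each edge owns the voxels nearest to
  its midpoint; the angle θ between each voxel gradient and the edge vector,
  weighted by gradient magnitude, forms a pdf over [0°, 180°], and the CAI
  is the pdf mass with bin centres in [60°, 120°]. θ = 90° (gradient
  perpendicular to the edge) marks perfect alignment, so a delta at 90°
  gives CAI = 1; gradient directions uniform on the 3D sphere give exactly
  1/2 (the integral of sin θ/2 over the window), and directions uniform in a
  plane containing the edge give 1/3. These closed forms anchor the test
  suite.
- **CDL/GDL** (Cell/Global Dissatisfaction Level): each node's compartment
  gradients are vector-summed into a net pull **F**, which is decomposed
  over the incident edge vectors, **E w = F**. Each edge then carries the
  norm of the vector sum of its two endpoints' projected forces; balanced,
  opposing pulls cancel to zero. The GDL is the sum of edge weights divided
  by the voxel count, and decreases as the tissue approaches mechanical
  homeostasis.

One textual ambiguity is resolved operationally: the angle is *defined* as
θ(gradient, edge) with CAI mass in [60, 120], regardless of how one
verbalises the corresponding fiber orientation; and the net pull is the
*vector* sum of compartment gradients (required for the projection step to
be meaningful), with the scalar magnitude sum retained only as the
`magnitude_sum` diagnostic on `net_force` objects.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `link_threshold_um` | 55 | µm | ≈ two rounded cell diameters; a sweep over 10–180 µm is provided (`sweep_link_threshold()`) because graph topology—and hence both metrics—depends on it |
| `cai_lo_deg`, `cai_hi_deg` | 60, 120 | deg | symmetric window around 90°; wide enough to be robust to a few degrees of gradient-direction noise |
| `bins` | 180 | — | 1° bins; fine enough that the window is bin-aligned, membership by bin centre |
| `highlight_cai` | 0.6 | — | threshold for drawing strongly remodeled edges |
| `connectivity` | 26 | — | nuclei blobs are compact; corner adjacency merges diagonal stair-steps |
| `min_size` | 27 | voxels | a 3×3×3 block; rejects shot noise (no filter is prescribed by the protocol, so it is exposed in `run_config()`) |
| `k_clusters`, `svd_dims` | 3, 2 | — | three remodeling phases; 2 singular directions retain the dominant pdf contrasts (the dimensionality is a free choice and configurable) |

## Numerical conventions

- **Axes and coordinates.** Voxel arrays are (depth, row, col); the physical
  centre of a voxel is its 0-based index times the spacing (µm). Anisotropic
  z-spacing enters centroid conversion, Voronoi distances and gradient
  denominators — but *not* connectivity, which is evaluated on the grid.
- **Otsu.** Exhaustive search over the empirical histogram (256 uniform bins
  when there are more distinct values than that); foreground is strictly
  above the threshold; ties broken toward the lowest threshold.
- **Voronoi.** Discrete nearest-seed assignment over voxel centres in µm;
  equidistant voxels go to the lowest seed label. The implementation must
  (and is tested to) equal a brute-force all-seed scan.
- **Gradients.** Central differences in the interior, one-sided at boundary
  planes; a `drop_boundary` flag zeroes the one-voxel shell instead.
  Smoothed (Sobel-style) operators are deliberately not the default because
  smoothing changes the magnitudes that act as histogram weights.
- **Angle binning.** 180 uniform bins over [0, 180], half-open with a closed
  last bin. 90° lies on a bin edge and accumulates into the [90, 91) bin,
  so the histogram peak of an exactly perpendicular fixture is reported at
  the 90.5° bin centre. Zero-magnitude gradients are skipped (undefined
  angle, zero weight regardless).
- **Edge-basis completion.** Degree-2 nodes gain the cross product of their
  two edges; degree-1 nodes gain a deterministic perpendicular (cross with
  the canonical axis least aligned with the edge) and then the cross product
  of the pair. Hypothetical columns are rescaled to the mean real-edge norm
  to keep `EEᵀ` well-conditioned, and their solved weights are discarded —
  they belong to no real edge — so part of a low-degree node's pull is
  deliberately unattributed. Parallel degree-2 edges (a numerically null
  cross product) fall back to the degree-1 construction.
- **Minimum-norm solution.** `w = Eᵀ(EEᵀ)⁻¹F` for k > 3 columns, plain
  solve for k = 3, SVD pseudoinverse (with a warning) when numerically rank
  deficient. Reconstruction `E w = F` is enforced to 1e-6 relative.
- **GDL normalization.** "Image size" is taken as total voxel count;
  `physical = TRUE` divides by µm³ volume instead. Degree-0 nodes own no
  edges and are skipped.
- **Weighted KS test.** The clipped-window comparison uses weighted ECDFs
  (step heights ∝ weights) and effective sample sizes `(Σw)²/Σw²` in the
  asymptotic two-sample Kolmogorov p-value. With unit weights this reduces
  exactly to the textbook test — verified against `stats::ks.test`
  (asymptotic), which serves as the oracle, to 1e-12 in D. Whether the
  original analysis honoured weights is unknowable from the text; the
  weighted form is the exact superset.
- **Phase naming.** With time and CAI metadata, the cluster holding the
  earliest time point is phase I and the cluster holding the maximum-CAI
  sample is phase III; without metadata clusters are numbered by first
  appearance. Under a fixed seed, k-means uses ≥ 10 restarts and is fully
  reproducible.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` fixtures contain Gaussian-profile ellipsoidal nuclei at
planted centroids over a constant background (optional additive noise) and
a collagen channel of sinusoidal stripe fields. Stripe normals are chosen
per edge compartment: perpendicular or parallel to the local edge, uniform
random per wavelength-sized block, or a mixture with fraction *f* of
perpendicular blocks. The analytic gradient of a stripe is ± its normal, so
the planted angle distribution is known: measured CAI grows linearly from
≈ 0.5 at *f* = 0 to ≈ 1 at *f* = 1 on single-edge fixtures.

Choices worth recording:

- **Stripe wavelength 12 voxels.** The central-difference response scales
  each gradient component by `sin(k_i h)/(k_i h)`; at 6-voxel wavelength an
  oblique stripe normal can be distorted by ~3°, at 12 voxels the error
  stays below ~1°, so measured angles track the planted ones.
- **One stripe phase per compartment in coherent modes.** Independent phases
  per block would create intra-compartment discontinuities whose large
  finite-difference magnitudes dominate the magnitude-weighted histogram.
  Compartment-boundary discontinuities remain, which is why multi-edge
  perpendicular fixtures measure CAI slightly below 1; exact CAI = 1 claims
  are made on single-edge fixtures, where the field is globally smooth.
- **Timecourses.** `generate_timecourse()` keeps nuclei and stripe
  orientation draws fixed across time points (mixture membership is decided
  by thresholding one fixed uniform draw per block, so aligned block sets
  are nested in *f*) and varies only the planted profiles: *f* drives CAI,
  and a linear intensity ramp scaled by `ramp_max × (1 − cancellation)`
  plants a non-cancelling net pull that drives GDL. `ramp_max = 150`
  intensity/µm makes the ramp-induced net force dominate the stripe-residual
  force on 40³ fixtures, so monotone planted profiles yield monotone
  measured metrics.

The generator does **not** emulate: optical point-spread and SHG speckle,
fibril-scale texture, intensity attenuation with depth, nucleus shape
irregularity, or touching nuclei (no watershed splitting is implemented —
overlapping blobs merge, and the generator warns when planted centres are
closer than four radii). Passing tests therefore demonstrate correctness of
the computational pipeline on controlled fields, not robustness to every
microscopy artifact.

## Problem sizes used by the test suite

Oracle-equivalence suites run at: 1000 random histograms (Otsu vs exhaustive
search), 200 points (cell-graph vs all-pairs), 20³ grids with 10 seeds
(Voronoi vs brute force), 9³ stacks (gradients vs loop), 1000 random 3×5
systems (minimum-norm vs pseudoinverse/nullspace perturbation and a KKT
solve). Closed-form CAI limits use 10⁶ Monte Carlo directions at tolerance
0.01. End-to-end fixtures use 24³–48³ grids with 2–8 nuclei and 3–4 time
points — sizes at which every stage's output is still checkable against a
hand-computed or brute-force reference.

## Known limitations

- Touching nuclei are merged (no watershed); centroid counts can undershoot
  on dense fields.
- The CAI of multi-edge synthetic fixtures is depressed by compartment
  boundary gradients; on real, continuous SHG fields no such discontinuity
  exists.
- The asymptotic KS p-value is approximate for small effective sample
  sizes, as in any asymptotic two-sample test.
- Phase labels beyond the I/III anchoring convention are nominal cluster
  ids; reproducing any particular published phase table requires the
  original image data.
- "Forces" are intensity-gradient surrogates, not physical units; no spring
  or continuum mechanics is implied.
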