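---
title: "Methods: quantitative mapping of the intrinsic cardiac nervous system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative mapping of the intrinsic cardiac nervous system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(icnsmap)
```

## Scope

The intrinsic cardiac nervous system (ICNS) is the population of neurons
residing on and in the heart, concentrated on the atrial base where the
great vessels enter. `icnsmap` implements the quantitative side of
whole-heart ICNS mapping: given per-subject annotation files containing
single-neuron markers (3D somata positions with soma-size attributes) and
anatomical contour traces (per-section polylines of atria, vessels and
sulci), it

1. filters somata by the 13 µm × 23 µm short/long-axis inclusion criterion,
2. clusters the neuron point cloud with partitioning around medoids (PAM)
   and selects the number of clusters against a randomized null,
3. projects the cloud onto a PCA flatmap and estimates packing density,
4. assigns neurons to anatomical regions of interest (ROIs) by contour
   proximity, and
5. registers each subject onto a common quad-element surface scaffold by
   least-squares fitting, embeds neurons as material coordinates, and
   quantifies cross-subject overlap on the generic scaffold.

A synthetic-heart generator reproduces the study conditions (sex-specific
neuron totals, ROI-anchored clusters, per-subject deformation, 5 µm
sectioning) so every stage is testable without imaging data.

## Data model and file dialect

Markers and contours live in a `subject_map()`. Coordinates are in µm;
section indices are 0-based, with `z = section × thickness` at the section
mid-plane and a default thickness of 5 µm. Files use a minimal XML dialect
(`<subjectmap>` / `<marker>` / `<contour>` / `<point>`; schema in the
`read_subject()` help and in `R/io_xml.R`). The reader ignores unknown
elements and attributes so richer tissue-mapper exports remain readable,
preserves unknown structure names verbatim with a warning flag, and accepts
contour z either in µm or as section indices (`contour_z = "section"`),
because deposited files are ambiguous on this point.

Markers lacking soma axes pass `apply_inclusion_filter()` with a
`size_unchecked` flag rather than being dropped: annotation files typically
record only somata already accepted at mapping time, so silently deleting
them would discard valid neurons. The filter is boundary-inclusive ("at
least 13 µm × 23 µm").

Serial-section double counting is emulated by `expand_marker_sections()`
(each soma appears on the 3–5 adjacent sections it spans) and undone by
`dedup_four_section()`, which keeps one record per soma using counting
sections every fourth section and falls back to the group's middle section
when a soma misses its counting section.

## Clustering and the number of clusters

`pam_medoids()` is classic Kaufman–Rousseeuw PAM on plain 3D Euclidean
distances: a greedy BUILD phase (first medoid minimizes total distance,
each later one maximizes cost reduction) followed by a SWAP phase that
evaluates every (medoid, non-medoid) exchange and applies the single best
strictly improving swap until none remains. The swap deltas are accumulated
in O(n²) per round, which is algebraically identical to evaluating each
swap naively; results are deterministic for a given input order, clusters
are numbered 1..k, and nearest-medoid ties resolve to the lower medoid
index.

PAM, like every swap-based local search (including the reference
`cluster::pam`), can terminate in a swap-local optimum on unstructured
data; on clusterable data it reliably attains the exhaustive optimum. The
test suite verifies exact agreement with a brute-force search over all
C(n, k) medoid sets on clustered instances and validity plus
reference-parity of attainment on uniform ones.

`silhouette_widths()` implements the standard widths
\(s(i) = (b - a)/\max(a, b)\) with singleton clusters scored 0.
`select_k()` reproduces the randomized-null selection: the data are
clustered for every k on a grid (default 2..20), ten coordinate-randomized
replicates of the data are clustered the same way, and the chosen k
maximizes the gap between the real and mean-null silhouette among the
candidates whose real silhouette is within ε = 0.01 of the best. The ε
band replaces the human visual inspection of near-equal silhouette curves
with a fixed, documented tolerance. The default null permutes each
coordinate axis independently across points — this preserves the marginal
spatial footprint of the organ and is therefore stricter than resampling
uniformly in the bounding box, which is also available
(`null_method = "uniform"`).

A known limitation, visible in the acceptance measurements: when a few
percent of neurons are diffuse background, the silhouette can prefer
granting those stray points their own medoid, overcalling k by one. With a
planted k = 4, 400-neuron hearts and 5% background, recovery is roughly
85–95% across seed sets rather than 100%; the original procedure resolved
such cases by visual inspection, which no fixed ε fully reproduces.

## Flatmap and packing density

`pca_flatmap()` centres the cloud and projects it onto the two leading
principal axes. PCA's reflection ambiguity is fixed by making each axis's
largest-magnitude loading positive, so superior–inferior orientation is
reproducible across runs and subjects. `packing_density()` is a Gaussian
product-kernel intensity (neurons/µm², not a probability density): the
raster integrates to the neuron count. The default bandwidth is Scott's
rule per axis, `sd · n^{-1/6}`; both the smoothed raster and raw
counts-per-cell are returned, since either convention may be wanted for a
density colormap.

## ROI association

ROIs have no contours of their own; they are defined by proximity to the
structures that bound them (`roi_definition()`). Vessel roots and hila use
the union rule (within radius of any defining structure); sulci — junctions
between two structures — use the joint rule (within radius of every
defining structure). The default radius of 500 µm is roughly one
atrial-wall thickness at rat scale; since the original proximal/distal
calls were visual, the radius is configurable everywhere and reported in
outputs, and proximity is monotone in it. Distances are 3D Euclidean
point-to-segment distances to the contour polylines, not geodesics: the
contours are the only anatomy the data model carries. A cluster is
*associated* with an ROI when more than half its members are proximal;
overlapping ROIs mean a neuron (or cluster) may belong to several regions,
so per-ROI fractions need not sum to one.

## Scaffold registration and material coordinates

The scaffold is a structured grid of bilinear quadrilateral elements
(`make_generic_scaffold()`); a material coordinate is an (element, ξ)
address with ξ ∈ [0,1]². Bilinear quads are a deliberate simplification of
the bicubic-Hermite elements used by organ-scaffold toolchains: they keep
the material-coordinate semantics while making each fitting round a linear
least-squares problem. The generic geometry is the same parametric family
as the synthetic template heart, so synthetic subjects are in-model.

`project_points()` finds the globally nearest surface point per query:
clamped Gauss–Newton on ξ, multi-started at the four corners and centre of
every element, with ties going to the lower element id. Because a bilinear
patch lies in the convex hull of its corners, elements whose
bounding sphere is farther than the current best distance are skipped
exactly; a coarse ξ-grid seeds the bound. Non-converged points return the
best clamped candidate.

`fit_scaffold()` alternates correspondence (projection) with a linear
update of the node coordinates minimizing

\[ \sum_i w_i \lVert x_i - \textstyle\sum_j \phi_j(\xi_i)\, p_j \rVert^2
   + \lambda \sum_{(a,b)\in E} \lVert (p_a - p_b) - (g_a - g_b) \rVert^2 ,\]

where E are the grid edges and g the reference nodes. The membrane penalty
is anchored to the reference edge *vectors* rather than penalizing edge
lengths themselves: the raw form is minimized by collapsing the mesh and
biases any fit, while the anchored form vanishes at the reference shape and
at every translation of it. Fitting starts with three coarse rounds in
which the update is restricted to a single affine map of all nodes (12
parameters): global pose and scale are absorbed before nodes move freely,
which prevents the element parameterization sliding across sharp features
such as the hilum ridge. λ defaults to 0.05, putting the penalty near 1% of
the data term at convergence on synthetic defaults; data weights default
to 1 and are configurable per point. With λ = 0 the normal equations must
be full rank, and the error message says to raise λ when they are not.

`embed_markers()` stores each neuron's material coordinate and projection
distance against the fitted scaffold; `transfer_to_generic()` evaluates
the same material coordinates on the generic scaffold — the one-to-one
transfer between geometries. `overlap_map()` bins material coordinates on
a per-element subgrid, normalizes each subject's histogram to sum one, and
reports the histogram intersection Σ min(dₐ, d_b) as the global proportion
of neuronal overlap, along with a per-bin min/max ratio and the Jaccard
index of occupied bins.

Registration corrects geometric (normal) deformation; displacement
*tangential* to the surface moves material coordinates with it and is
invisible to any surface fit. Cross-subject agreement is therefore
assessed on mean homologous-cluster centroid distances, which average over
the tangential noise; individual clusters can sit farther apart than the
mean suggests.

## Synthetic hearts

The template (`make_template_heart()`) is a single-sheet height-field dome
of ~8000 µm extent with a ridge standing in for the pulmonary-vein hilum;
all analyses consume epicardial point clouds, so no chamber volumes are
modelled. Five (u,v) anchors mark the ROIs, and (u,v) rectangles mark the
structures that are traced into per-section contours by
`slice_contours()` (iso-z intersection of each structure patch).

Sex profiles encode the study conditions: male hearts average 2845 mapped
neurons (coefficient of variation 0.05, matching the reported 2676–2973
range) in 8–12 clusters; female hearts average 1581 neurons in 4–8 larger,
sparser clusters. Lower female packing density is produced by
`density_scale = 0.5`, which widens the effective cluster spread
(`cluster_spread / sqrt(density_scale)`, i.e. 250 → ~354 µm). Values the
source conditions do not pin down were chosen once as realistic defaults:
5% diffuse background neurons, 250 µm tangent-plane cluster spread, a
15 µm normal jitter, soma axes lognormal with medians (16, 28) µm and log
sds (0.095, 0.09) so ~97% of somata pass the inclusion criterion.
Cluster-size dispersion is a free parameter (gamma weights, shape 4).

Per-subject deformation (`deform_subject()`) composes an affine map
(isotropic scale 0.9–1.1, rotation up to ±5°) with a sinusoidal
displacement field of one spatial period across the organ and total
amplitude bounded by `warp_amplitude` (default 300 µm, zero gives the
identity), applied identically to surface and markers. Cluster centres are
kept at least four effective spreads apart so the planted k is
recoverable.

What the generator does *not* emulate: staining variability beyond a
dropout fraction, histological damage, non-smooth individual anatomy, and
annotation error in contour tracing. Passing tests on synthetic hearts
show the algorithms are correct and stable under the stated variability;
they do not certify performance on real annotation files beyond the format
contract.

## Problem sizes and numerical choices

Simulation sizes used by the test and acceptance suites are package
choices: 50-replicate cluster-number recovery runs use 4-cluster,
400-neuron hearts (the low end of realistic per-cluster counts);
registration checks use five 300-neuron subjects on an 8×8-element
scaffold with ~1200 contour points per fit; full-size (2845/1581) hearts
are used for count, density and overlap measurements, with the k grid on
full-size subjects searched on a seeded 600-marker subsample to bound the
O(n²) silhouette work. Gauss–Newton projection runs at most 20 iterations
per start with a 10⁻¹⁰ step tolerance; fitting stops when the RMS data
distance changes by under 0.5 µm (default `max_iters = 8`). All randomness
descends from one master seed through `derive_seed(master, stage)`, a
stage-name hash, so stages are individually reproducible and collisions
are avoided; fixed seeds make every generator output bit-reproducible.

## Command-line use

The package is primarily an R API (`run_pipeline()` over a
`run_config()`), with reports written as JSON/CSV. A thin wrapper for
shell use ships in `inst/scripts/icns.R`:

```sh
Rscript inst/scripts/icns.R synth --seed 1 --out subjects/
Rscript inst/scripts/icns.R run --seed 1 --out results/
```
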