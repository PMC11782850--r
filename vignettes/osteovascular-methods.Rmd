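---
title: "Quantifying osteovascular structure from contrast-enhanced micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying osteovascular structure from contrast-enhanced micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteovasc)
```

## The measurement problem

Blood vessels inside long-bone marrow supply the skeleton and couple
angiogenesis to bone formation. Contrast-enhanced micro-CT (CE-CT) with a
hafnium polyoxometalate stain renders the soft-tissue compartments of the
marrow visible next to bone: mineralized bone attenuates most, stained
vessels and the bright partial-volume halos at adipocyte boundaries sit at
intermediate gray levels, and unstained lipid (the adipocyte interior) is
darkest. From a reconstructed isotropic volume (2 µm voxels in the reference
protocol) this package quantifies:

* **Marrow morphometry** — marrow volume (Ma.V, mm³), adipocyte volume
  fraction (Ad.V/Ma.V, %), adipocyte density (Ad.D, #/mm³) and equivalent
  diameters (Ad.Di, µm), vessel volume fraction (Ves.V/Ma.V, %), vessel
  density (Ves.D, #/mm³).
* **Vessel caliber** — the local thickness (Ves.Th, µm) of the vessel mask by
  the inscribed-sphere (model-independent) definition, and its
  volume-weighted distribution in 4-µm bins from 2 µm with an open tail
  above 66 µm.
* **Network branching** — branches, junctions, triple points (three incident
  branches) and quadruple points (four) of the vessel skeleton.
* **Vessel–bone proximity** — the geodesic distance from vessel surface
  voxels to bone surfaces through non-bone space (Ves.S-BS), binned at 4 µm
  up to 52 µm with an open tail.
* **Osteovascular composition** — EMCN⁺, CD31⁺ and type-H (double-positive)
  area fractions from two-channel immunofluorescence sections.
* **Perfusion** — laser Doppler flowmetry trace reduction: duration-weighted
  means of repeated 30-s measurements and the OLS slope (PU/min) of the
  30-minute intra-operative trace, with one-sample stability tests.

No imaging data ship with the package. Every stage is validated on synthetic
phantoms with exact ground truth, generated by the package itself.

## The segmentation chain

The processing order follows the reference protocol exactly:

1. **VOI selection** (`select_voi`): a crop of `round(length_um/voxel)` slices
   starting at the growth-plate reference slice; 1600 µm by default.
2. **Bone removal** (`segment_bone`): automatic Otsu threshold on the full VOI
   histogram; bone is the high class, marrow is the complement. A constant
   volume is an error; a near-empty bone class raises a warning because the
   threshold is then splitting noise.
3. **Adipocytes** (`segment_adipocytes`): global threshold (dark class),
   opening (ball r = 1), closing (r = 3), white despeckle (< 650 voxels),
   black despeckle (cavities < 650 voxels), restricted to marrow.
4. **Edge suppression** (`suppress_adipocyte_edges`): adipocytes dilated by a
   ball of r = 5; the dilated region is re-leveled to the marrow background
   (median of marrow outside the region). The bright rims at adipocyte
   boundaries have vessel-like gray values and would otherwise be
   misclassified; re-leveling removes them from vessel candidacy
   deterministically.
5. **Vessels** (`segment_vessels`): global threshold (bright class), closing
   (r = 4), white despeckle (< 1050), closing (r = 6), white despeckle
   (< 5500), restricted to marrow and disjoint from the adipocyte mask.

All structuring elements are discretized Euclidean balls
\(\{x : \lVert x\rVert \le r\}\) realized exactly through the squared
Euclidean distance transform; closing and opening are exact duals under the
package's border conventions (dilation cannot paint outside the volume;
erosion responds only to observed background, so VOI cut faces do not erode).

**Bone-halo exclusion.** One addition to the printed chain was unavoidable:
the blurred marrow→bone intensity ramp sweeps through *every* intermediate
gray value, so a PSF-scale shell adjacent to every trabecular surface crosses
any global vessel threshold. `morpho_params(bone_dilate_r = 2)` excludes the
2-voxel dilation of the bone mask from vessel candidacy — the same
partial-volume logic the protocol applies at adipocyte rims, applied at the
bone interface. Without it, phantom vessel fractions inflate by an order of
magnitude; with it, recovery is unbiased to within the closing-chain effects
discussed below.

**Parameter scaling.** The despeckle volumes (650/1050/5500 voxels) are
absolute counts tuned to the reference data at 2 µm: 650 voxels corresponds
to a 21.5-µm sphere. For data (or phantoms) whose smallest genuine objects
are smaller, these must be scaled down; the validation phantoms use
`adip_despeckle_vox = 100`, below the smallest generated cell (~180 voxels).
The vessel despeckles assume the vasculature forms large connected networks —
isolated fragments below 5500 voxels are deliberately erased by the protocol.

## Local thickness

`local_thickness` implements the model-independent definition: the thickness
at a point is the diameter of the largest sphere that contains the point and
fits inside the structure. Sphere centers are sampled at voxel centers *and*
at face midpoints between voxels. At voxel centers the radius follows the
classic digital convention — Euclidean distance to the nearest background
voxel center minus half a voxel, which compensates the half-voxel that
center-sampled rasterization shaves off round objects. At face midpoints
the radius is the *exact* distance to the nearest background voxel cube
(the nearest point of an axis-aligned cube to a half-lattice point is the
coordinate-wise clamp, itself a half-lattice point); these centers make
structures of even voxel width, whose maximal sphere sits between voxel
centers, exact, and can never overestimate. Redundant centers are removed
by a dominance test (a ball contained in a neighbour's ball is dropped) and
the surviving balls are painted taking the maximum.

Consequences worth knowing: slabs of width *w* voxels measure exactly
*w*·voxel everywhere in their interior, for even and odd *w* alike;
center-sampled digitized cylinders of radius *r* voxels measure 2*r* to
within one voxel (the center-distance convention compensates almost exactly
for the half-voxel the rasterization shaves off the analytic cylinder).

## Skeleton census

`skeletonize` is a six-subiteration topology-preserving thinning: a voxel is
deletable when it is a *simple point* (one 26-connected foreground component
in its neighbourhood and one face-connected background component) and not a
curve endpoint. Candidates collected per direction are deleted sequentially
with the simplicity test re-checked at deletion time; endpoint status is
fixed at collection time, which prevents mid-pass line ends from being
protected into spurious spurs. `analyze_skeleton` then classifies skeleton
voxels with ≥ 3 neighbours as junction voxels, merges adjacent junction
voxels into junction nodes, and counts maximal degree-≤2 chains as branches;
triple and quadruple points are junction nodes of degree 3 and 4 (higher
degrees count as junctions only, mirroring the two named classes). No
end-branch pruning is applied by default; `prune_length_um` exposes it.

## Geodesic proximity

`geodesic_from_bone` runs a priority-queue (Dijkstra) wavefront over the
26-neighbourhood with quasi-Euclidean weights (1, √2, √3 × voxel size).
Seeds are the traversable voxels 6-adjacent to bone, so distance 0 means
touching bone; vessels and adipocytes are traversable by default
(`block_vessels` makes vessel interiors opaque while keeping their surface
reachable — the protocol does not specify this, so it is a flag). The
distribution samples the map at vessel *surface* voxels (6-adjacency
definition) in 4-µm bins; unreachable voxels are reported separately, and the
quasi-Euclidean metric overestimates true Euclidean distances by at most
about 8%, which is the price of an exact shortest-path semantics on the grid.

## The phantom generator

`generate_cect_phantom` builds the three tissue compartments with exact
bookkeeping, then renders:

* **Vessel trees** grow by a stochastic branching random walk (step 4 voxels,
  direction jitter, radius tapering child ≤ parent), with relationship-aware
  collision tests so no two tubes ever merge: a branch ignores its own recent
  nodes and its parent/siblings near the shared junction, and everything else
  must keep a 2-voxel clearance. Junctions spawn two children (triple point)
  or, with probability 0.2, three (quadruple point) at near-symmetric
  azimuths. Branch interiors are Laplacian-smoothed before rasterization so
  tubes are smooth at the voxel scale, terminal branches shorter than
  16 + 2·radius voxels are pruned (thinning erodes caps by about one radius),
  and a tree whose tube volume falls below a grid-scaled minimum is regrown
  elsewhere, because the protocol's despeckling presumes large connected
  networks. Enclosed background pockets pinched off at wide-angle junctions
  are filled (tube unions are genus-0). The exact centerline graph and its
  branch/junction census are recorded as ground truth.
* **Adipocytes** are dart-thrown spheres (diameter ~ N(32, 6²) µm, truncated
  to ±3 SD) with overlap-free placement; the *cell* is the dark lipid sphere,
  and the bright partial-volume halo is painted as a 2.5-voxel shell *around*
  it — an imaging artifact, not part of the cell — so ground-truth cell
  volumes are the dark voxels only. Infeasible packing errors out naming the
  achieved count.
* **Trabecular scaffold**: thresholded smoothed Gaussian noise
  (plate/rod-like texture), calibrated to the target bone fraction by an
  order statistic (exact, in place of iterative bisection), with a 3-voxel
  clearance around vessels and adipocytes that keeps the perivascular space
  open.
* **Rendering**: role intensities (defaults 18000 marrow, 5000 lipid,
  25000 halo, 28000 vessel, 58000 bone — spaced so the vessel mode sits
  clearly below the marrow/bone Otsu point), Gaussian PSF blur (σ = 1 voxel),
  additive Gaussian detector noise (SD = 10% of the marrow–vessel contrast),
  then a reconstruction-side Gaussian filter (σ = 0.6 voxel) emulating the
  smoothing that reconstruction software applies — detector noise precedes
  that filter in any real chain, so the voxel noise the segmentation sees is
  correlated, not white.

Identical spec + seed reproduces the phantom bit-identically. Ground-truth
volumes are counted before blurring; the blur, noise and operator chain are
exactly what the recovery tolerances measure.

**What the phantom does and does not show.** It reproduces the statistical
structure the analysis assumes — contrast ordering, PSF, noise, tubular
topology, spherical cells, plate/rod scaffold — but not streak or ring
artifacts, stain diffusion gradients, vessel wall irregularity, or marrow
heterogeneity. Passing the phantom suite therefore demonstrates that the
implementation measures what it claims on data obeying the protocol's
assumptions; it does not certify accuracy on pathological scans.

**Calibration notes.** Where neither the protocol nor physiology fixes a
generator value we chose once: three trees per VOI-scale grid, branching
probability 0.08 per step (internodal spacing ≈ 100 µm at the CT-resolved
scale), vessel radii 6–20 µm matching the published thickness-distribution
support (bins from 6 µm to an open tail above 66 µm), 30 adipocytes per
160³ grid (Ad.D within the published range). The morphological closing steps
inherently add a surface layer on thin curved tubes and fill junction
wedges; at these settings that bias is about +5 to +8% of vessel volume,
within the 10% validation tolerance, and users should expect the same
behaviour on real data — it is a property of the protocol, not of this
implementation.

## Immunofluorescence quantification

`emcn_mask` binarizes the EMCN channel with an adaptive threshold (local
arithmetic mean over a square window — clipped at borders, computed by an
integral image — plus an offset; default window is the nearest odd integer
to 1/8 of the ROI bounding box, offset 0), then refines with a disc opening
(r = 1) and closing (r = 2). `cd31_mask_from_roi` rasterizes manually traced
polygons (even-odd scanline fill at pixel centers; self-intersecting
polygons are rejected by a segment-intersection test). `type_h` is the exact
pixel intersection, reported relative to the ROI pixel count ("total area"
is read as ROI area; flagged in the documentation since the protocol is
ambiguous between ROI and tissue area). `average_sections` averages the two
sections per bone arithmetically.

## Perfusion reduction

Weekly perfusion per bone is the duration-weighted mean of its repeated
segments, the weights being the valid recorded duration (sample count ×
sampling interval) — with two nominally equal 30-s segments this reduces to
the arithmetic mean, and duration weighting is the only information
available when segments differ. The intra-operative stability check fits an
OLS slope on the raw samples (PU/min, with standard error). The one-sample
stability test offers a t test (error on zero variance) and a signed-rank
test whose p value is computed by exhaustive enumeration of all 2ⁿ sign
assignments for n ≤ 15 — midranks handle ties, zero slopes are dropped by
the standard convention, and an all-zero sample returns p = 1 — with the
normal approximation beyond. The mixed hierarchical models of the original
statistical analysis are deliberately out of scope; `group_summary` emits
tidy descriptive tables (mean, SD, n per cell, absent cells flagged missing)
from which percent differences are computed as 100·(a − b)/b.

## Numerical choices and degenerate inputs

* Connectivity: foreground 26, background 6 (the standard complementary
  pair); despeckle exposes the choice.
* Black despeckling fills only *enclosed* cavities; border-touching
  background is exempt.
* Despeckle survival is "< cut removed": a component of exactly the cut
  size survives.
* Histogram weights sum to 100 exactly; values below the first edge are
  counted in the first bin.
* `local_thickness` and `skeletonize` operate on the mask's bounding box
  plus one voxel; space outside the volume is background.
* Ties in Dijkstra cannot affect distances (the metric is deterministic);
  all RNG flows from the single spec seed, so every pipeline output is
  bit-stable under a fixed configuration (`run_pipeline` reports a config
  hash and reruns reproduce the JSON report byte for byte).
* Validation problem sizes: phantom recovery at 256³, census phantoms at
  96³, end-to-end determinism at 112³ — sizes at which the full suite runs
  comfortably on one CPU.

## Known limitations

* Ves.D and Ad.D count connected components of the final masks; for a
  largely connected vascular network the component count is a coarse
  statistic (the published densities for real data are similarly volatile),
  and no per-vessel instance definition exists.
* Exact voxel-level agreement with specific commercial or plugin
  implementations (CTAn kernels, BoneJ thinning order) is not promised;
  topological counts and metric definitions are the contract.
* The quasi-Euclidean geodesic overestimates Euclidean lengths by ≤ ~8%;
  distances are metric lengths in µm, not step counts.
* The adaptive-threshold window and offset for EMCN are unpublished in the
  protocol; defaults are stated above and exposed.
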