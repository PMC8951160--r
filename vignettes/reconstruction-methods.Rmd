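---
title: "Reconstructing volumetric point-cloud models from micro-CT slice stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing volumetric point-cloud models from micro-CT slice stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomocloud)
```

## The problem

A micro-CT scanner delivers an ordered stack of 2-D greyscale slice images
(typically TIFF, 1000–3500 slices, 30–60 µm slice thickness for the
archaeological scans this package targets). Two things stand between that
stack and a 3-D model one can measure:

1. **Volumetric faithfulness.** Simply gluing slices together produces
   correct in-plane (x, y) geometry but a completely distorted length,
   because slice index is not a physical coordinate. Every voxel must be
   placed at `z = k * dz`, where `k` is the 1-based slice position and `dz`
   the slice thickness in µm. All reconstructions in this package do exactly
   that, so the z-extent of a full-depth model is `(n_slices - 1) * dz` by
   construction.
2. **Selectivity.** Conservation work cares about internal voids — pores,
   cracks, openings, fractures — which occupy a narrow grey band darker
   than sound wood. Emitting every voxel (the *direct* mode) preserves
   everything but produces enormous clouds; restricting output to grey
   windows and edges (the *segmented* mode) keeps the boundaries of the
   object and of its internal features in a cloud that is orders of
   magnitude smaller.

## The two reconstruction modes

**Direct** (`direct_reconstruct`): one interior-labeled point per voxel
passing an optional foreground grey window, at
`((j-1) dx, (i-1) dy, k dz)`, with the grey value attached. With no window
every voxel is emitted.

**Segmented** (`segmented_reconstruct`), per slice:

* the *solid* is thresholded against air (user threshold, or Otsu on the
  pooled grey histogram of the whole stack — a per-slice threshold would
  split pure noise on slices that contain no object and fabricate a solid
  there) and reduced to its largest 8-connected component, which suppresses
  mounting-foam and speckle components;
* the boundary of the solid becomes `outer_surface` points;
* within the solid, the feature grey window selects the internal non-wood
  voxels; the configured edge detector applied to that binary mask yields
  `internal_feature` points;
* wood voxels 8-adjacent to feature voxels become `wood_boundary` points.

Each voxel is emitted at most once with label precedence
`internal_feature > wood_boundary > outer_surface`. Features are detected
per slice; no 3-D linking across slices is attempted — internal voids are
marked exactly where each slice sees them, which keeps the procedure a
single pass over the stack.

### Edge detection

The primary operator is the Roberts cross: `Gx = p(i,j) - p(i+1,j+1)`,
`Gy = p(i,j+1) - p(i+1,j)`, edge where `sqrt(Gx^2 + Gy^2)` exceeds a
threshold. It is cheap, does not smooth, and keeps small openings — the
properties that matter for crack detection. Prewitt, Sobel,
Laplacian-of-Gaussian, plain-Laplacian zero crossings, Canny and an
approximate Canny are provided for the side-by-side comparison
(`compare_edge_detectors`); the comparison reports counts and masks without
declaring a winner, because no numeric criterion for "keeps the most small
detail" exists.

Two policies are worth stating explicitly:

* **Edges on the mask, not the greys.** In segmented mode the detector runs
  on the binarized window mask (threshold 0.5 on a 0/1 image), making
  feature edges threshold-free. The raw-grey alternative is available via
  `on_mask = FALSE`. The mask reading is the faithful one: the grey window
  is applied first, boundaries of the selected regions second.
* **Border policy.** Positions lacking a complete kernel window are never
  edges; padding would invent edges at the field-of-view boundary.
* **Edge maps keep the operator's raw positives** — pixels on both sides of
  a 0/1 transition. Intersecting with the mask was rejected: a 2x2 cross
  operator only flags down/right-facing boundary pixels inside a mask,
  which would bias feature-ring centroids by about half a radius.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `dx`, `dy`, `dz` | none (required) | physical voxel spacing, µm; supplied from acquisition metadata, never silently inferred |
| feature window | none (required in segmented mode) | grey band of internal voids on the 0–255 scale, e.g. 110:130 in the published wooden-point scans |
| air threshold | stack-level Otsu | solid/air split; override when stacks have unusual histograms |
| edge threshold | Otsu on gradient magnitudes | used only when detecting on raw greys; logged when chosen automatically |
| `tilt_deg` | 0 | mounting inclination about the slice normal, counter-rotated about the cloud centroid |

A reported Hounsfield value such as −278 HU is metadata only: HU-to-grey
calibration is scanner-specific, so all computation stays on the 0–255
scale. 16-bit inputs are normalized by the fixed ratio `floor(v/257)` —
never per-stack min–max, which would make the same window select different
attenuation in different stacks.

## Morphometrics and deformation monitoring

`change_table` expresses length, width, thickness and volume of repeated
scans relative to a base scan (`index = 100 + percent`,
`percent = 100 (x - x_base)/x_base`, printed to 2 decimals). Volumes are
voxel counts times `dx dy dz`, computed on solid (direct-mode) masks —
never on segmented clouds, which are surfaces.

Dimensions default to extents along principal axes. Plain covariance PCA
cannot orient a near-isotropic scatter (a cube's covariance is a multiple
of the identity, so its eigenvectors are arbitrary); the implementation
therefore refines the PCA basis by minimizing the in-plane bounding-box
area about each axis with a deterministic golden-section search. For
well-conditioned elongated objects this changes nothing; for degenerate
ones it recovers the tight box. Extents along raw x/y/z axes remain
available (`method = "axis"`).

Deformation between scan years is measured as a cloud-to-cloud
nearest-neighbour distance field after point-to-point ICP alignment. This
approximates the viewer-side cloud-to-mesh (C2M) comparison; the
approximation converges to C2M as the reference cloud densifies, and the
gap is largest where the reference is sparsest. ICP uses exact kd-tree
nearest neighbours with lowest-index tie-breaks, centroid plus
principal-axes initialization (all det +1 sign candidates scored by initial
RMS), and the closed-form SVD update, so results are fully deterministic;
the correspondence RMS is non-increasing by construction and the trace is
returned.

## The synthetic phantom: what it does and does not establish

No scan data of the original artefact is publicly deposited, so the package
validates itself on a parametric phantom (`phantom_spec`,
`generate_phantom`): a tapered ellipsoid ("leaf-shaped" body, long axis
along the stack) at wood grey 200, air 20, with planar cracks (slabs
restricted to an outer shell of the body) and spherical pores at feature
grey 120, plus i.i.d. Gaussian noise (default sd 5) clipped to [0, 255].
The defaults — 96³ voxels at 20 µm, half-axes 600 x 380 x 850 µm, taper
0.35, one crack, four pores — give a ~2 mm object with the geometry the
pipeline must handle: a single dominant component, internal voids of a few
voxels' width, 10-sigma grey separation between classes. The body volume
has a closed polynomial form, which is the analytic ground truth for volume
tests.

`deform_phantom` emulates conservation-induced change: uniform linear
shrinkage (axes, crack geometry and pore radii scaled together; pore
centres are sampled in normalized body coordinates so the same seed yields
corresponding features) and a circular-arc bend of the long axis.

What a green phantom test does **not** establish: robustness to ring or
beam-hardening artefacts, partial-volume blur, intensity drift between
slices, multiple objects in the field of view, or grey classes that
overlap under noise. The phantom's class separation (80 grey levels at
noise sd 5) is deliberately clean; with overlapping classes the grey-window
stage, not the geometry, becomes the accuracy bottleneck.

Ground truth for the boundary-recovery test is defined with the same 2x2
cross-difference boundary operator the reconstruction applies, but computed
independently from the pre-noise feature mask; at zero noise the grey
window recovers the planted mask exactly, so the test exercises the window
plus edge chain rather than a shared code path.

## Numerical choices

* Slice order comes from a natural sort of file names (digit runs compared
  numerically, extension separately from stem, path components per level);
  z uses the sorted *position*, not the parsed number, so numbering gaps do
  not create physical gaps.
* Otsu's threshold maximizes between-class variance on a 256-bin histogram;
  when the maximizer is a plateau (an empty grey gap between classes) the
  plateau midpoint is taken.
* Zero-crossing detectors mark the smaller-magnitude pixel of a
  sign-changing neighbour pair whose slope exceeds the threshold; ties mark
  both pixels.
* OBJ export writes µm with 4 decimals by default; write-read-write is
  byte-idempotent, and label colours survive the round trip.
* Degenerate inputs: all-air stacks return an empty cloud with a warning;
  coplanar clouds fall back to axis extents with a warning; features
  reaching outside the phantom body are clipped with a warning.

## Known limitations

* Only uncompressed single-channel baseline TIFF and PGM are read/written;
  compressed TIFF, RGB imagery and DICOM are out of scope (RGB rejection is
  deliberate — silent channel mixing would corrupt grey windows).
* Surface meshing (Poisson, marching cubes) is delegated to external
  viewers; consequently "C2M" here is cloud-to-cloud.
* Per-slice segmentation cannot separate two internal features that merge
  in-plane, and the largest-component rule assumes a single object per
  scan.
* Crack-specific calipers (local width/depth of a named crack) are not
  provided; the distance field is the generic tool.
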