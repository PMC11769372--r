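---
title: "Multi-view lifting and confidence-driven fusion for 3D leaf instance segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view lifting and confidence-driven fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MVLeafSeg)
```

## The model

MVLeafSeg turns per-view 2D instance masks into one 3D instance
segmentation of a reconstructed plant point cloud. The pipeline assumes:

* a calibrated pinhole camera per view (COLMAP `PINHOLE`: `fx, fy, cx,
  cy`, no distortion — undistortion is upstream's job);
* per-view depth and normal maps consistent with the cloud (from the same
  multi-view-stereo run that produced the cloud), with normals in the
  world frame — converting camera-frame normals is the loader's
  responsibility;
* mask rasters where 0 is background and `k` is mask `k`, from any 2D
  segmenter.

**Lifting.** Every cloud point is projected into every view
(`projectPoints`). The pixel it lands on corresponds to a whole viewing
ray (the view-frustum ambiguity), so three rejections guard the label
transfer (`liftView`):

1. no hit — behind the camera, outside the raster, or no depth data;
2. depth gate — the relative error `e = (d(u,v) − Zc)/d(u,v)` must stay
   below `eThreshold`; this is what makes occluded points come out
   unlabeled rather than mislabeled;
3. backside — `cos φ ≥ 0` (surface seen edge-on or from behind): a 2D
   segmentation of such a surface carries no usable information, so the
   label is discarded at lift time, not merely down-weighted.

Surviving points get a confidence `s = λ·max(0, −cos φ) + (1−λ)·d_n`.

**Fusion.** `incrementalFuse` folds the views in capture order, because
adjacent turntable angles overlap the most, keeping group correspondences
unambiguous. Each merge (`mergePair`) classifies group pairs from the
row-normalized overlap tables `Qx`/`Qy` (`overlapTables`):

* *unmatched* (γ mass on unassigned ≥ `tauUnmatched`): the whole incoming
  group enters as a new group, confidences inherited;
* *matched* (mutual γ ≥ `tauMatch`): union under the state's label,
  confidences summed point-wise — mutual validation across viewpoints
  accumulates reliability mass, deliberately unnormalized and allowed to
  exceed 1;
* *conflict* (everything else that overlaps): the group with the higher
  mean confidence keeps the overlap; overlap confidences become
  `|s_x − s_y|`, non-overlap points keep their own label and score.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `eThreshold` | 0.005 | relative (unitless) | a 0.5 % depth tolerance balances dropping occluded/ambiguous points against starving the views; smaller is stricter |
| `lambda` | 0.9 | unitless, (0,1) | weight of view angle vs depth in the score; results are insensitive over a wide range because the mask shape filter already removes most oblique views of a leaf |
| `tauMatch` | 0.5 | overlap ratio | mutual majority overlap is the weakest claim under which two masks are safely one leaf |
| `tauUnmatched` | 0.8 | overlap ratio | a group mostly landing on unassigned points is genuinely new information |
| `sMin` | 40 | 8-bit HSV saturation | studio backgrounds are low-saturation white/gray; 40 separates them from foliage. The 0–255 scale is the convention of mainstream image libraries (on a 0–1 scale a threshold of 40 would be meaningless) |
| `iouMin` | 0.5 | IoU | above this two masks are duplicates (the coarser one is dropped); below it part–whole overlaps are resolved by giving shared pixels to the finer mask |
| `rMax` | 4 | area ratio | enclosing-circle/mask-area ratio: discs ≈ 1, squares ≈ π/2, stems ≫ 10, so 4 cleanly splits leaves from stems |

`distanceMode` ships in two variants because the printed form of the
confidence score rewards *larger* normalized depth, while its motivation
(imaging-distance quality) suggests rewarding proximity. `"literal"` (the
default) implements the printed form; `"proximity"` replaces the depth
term with `(1−λ)(1−d_n)`. The λ-insensitivity noted above makes the choice
immaterial in practice; both are tested.

Per-group statistical pre-filtering (`prefilterGroups`, k = 10 neighbours,
2 σ, minimum group size 5) removes spatially isolated mislifted points.
It is exported and tested but **off by default** in `runPipeline`: by
construction it also deletes a small tail of true boundary points (the
2 σ rule flags ~2 % of any compact group), trading recall for precision.
Enable it when masks are noisy and precision is the priority.

## The synthetic benchmark

`generateScene` builds what the pipeline's tests need and nothing more: a
young rosette-like plant of `nLeaves` planar elliptical patches staggered
in height (0.12 scene units apart) and azimuth around a stem axis, tilted
8–18° from horizontal, each uniformly sampled with `pointsPerLeaf` points.
`cameraRing` places 32 cameras at 11.25° azimuth steps and 30–45°
elevation, 4 units from the scene — the classic turntable capture.
`renderView` is a z-buffer point-splat renderer (splat radius 2 px,
640×480): the nearest point wins each pixel and writes its *exact* depth,
normal and instance id. Splatting, rather than mesh rasterization,
guarantees the rasters and cloud agree exactly, so on clean renders the
whole lift-and-fuse chain must reproduce ground truth perfectly — which
the acceptance suite asserts, along with exact zero depth error at every
rendered pixel.

`corruptMasks` then emulates segmenter failure modes directly in the
label raster — merge (under-segmentation), split (over-segmentation),
dropout (missed instance), boundary erosion/dilation — without touching
depth or normals, exactly like a 2D model erring on a correct scene.

What the generator deliberately does **not** emulate: reconstruction
noise fields (MVS holes appear here only as point dropout), weak-texture
artifacts, camera-pose error, non-planar leaf blades, stems and pots in
the cloud. Passing tests therefore demonstrate the correctness of the
geometry, gating, fusion logic and metrics — not robustness to
reconstruction pathologies of real field data.

The tilt range is not cosmetic: with camera elevations of 30–45°, tilts
below 30° keep every leaf front-facing in all views, so on clean data all
consecutive-view group pairs are *matched* and fusion provably converges
to the ground-truth partition. Steeper leaves would enter views edge-on,
where the (intended) backside and grazing rejections make per-view
coverage collapse.

## Numerical choices and degenerate inputs

* Pixels are 0-based with centers on integers; raster lookups round to
  nearest. Points behind the camera or off-raster return "no hit" rather
  than clamped coordinates.
* Depth maps encode no-data as NA (NaN on disk); the gate treats it as a
  distinct failure, never as zero error.
* Equal group means in a conflict: the state wins — deterministic and
  biased toward accumulated evidence. Conflict pairs are processed in
  descending overlap size, each point resolved at most once per merge.
* Equal-area duplicate masks: the lower mask id is the "finer" one.
* Degenerate 1–2 pixel masks report an infinite shape ratio (always
  filtered). The minimum enclosing circle is exact (move-to-front Welzl
  on boundary pixels, deterministic scrambled insertion order).
* RANSAC circle fitting (1000 iterations, inlier tolerance 0.5 % of the
  hypothesized radius, explicit seed) refuses all-collinear samples and
  refines the consensus with a PCA-plane + algebraic circle fit.
* `countAgreement` refuses zero ground-truth counts (MAPE undefined).

## Problem sizes

The test and acceptance runs use 8 leaves × 400 points, 32 views at
640×480 — small enough for interactive iteration, large enough that every
leaf is multiply covered and occlusions, grazing views and z-buffer
collisions all actually occur. The evaluation restricts to points visible
in ≥ 1 view; points never visible (e.g. permanently back-facing) cannot
carry information in a view-based method and are excluded from recall by
construction.

## Known limitations

* Incremental fusion never merges two groups that both already live in
  the state; if early views fragment a leaf (extremely sparse per-view
  coverage, e.g. a depth gate far below the renderer's quantization
  error of ~0.2–0.5 % of depth), the fragments persist. This is visible
  in the depth-gate sweep at 0.1 %: per-view labelings get *more*
  precise while the fused partition over-fragments. A global association
  pass would remove this failure mode and is out of scope here.
* Confidence masses are unnormalized; comparing them is meaningful only
  within one run.
* The shape filter's circle-ratio misclassifies genuinely elongated
  leaves (grasses); aspect-ratio or roundness descriptors would be
  needed there.
* The mask-overlap filter is quadratic in the number of masks per view.
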