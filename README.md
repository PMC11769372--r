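# MVLeafSeg

Zero-shot 3D leaf instance segmentation from multi-view images, in R.

## The problem

Organ-level plant phenotyping needs each leaf isolated as its own 3D
instance. Training-free 2D segmenters (SAM-family models) segment leaves
well in individual photographs, and multi-view stereo (COLMAP) turns a
turntable image sequence into a dense point cloud with per-view depth and
normal maps — but neither produces a 3D instance segmentation. MVLeafSeg
implements the bridge: it filters raw 2D masks down to leaf-only masks,
lifts each view's mask labels onto the cloud through the calibrated
cameras, scores every lifted point, and incrementally fuses the per-view
labelings into a single labeling of the original cloud.

It is aimed at phenotyping pipelines where the segmenter and the
reconstruction already exist as files: the package consumes a PLY cloud,
a COLMAP text model (`cameras.txt`/`images.txt`), per-view depth/normal
rasters and indexed mask PNGs, and produces a per-point instance labeling.
A synthetic turntable scene generator (leaf-like surface patches, camera
ring, z-buffer point-splat renderer, controlled mask corruption) stands in
for the camera + reconstruction + segmenter front end in all tests.

## The method

For a world point `p` and a view with intrinsics `K` and extrinsics
`[R|t]`, the pinhole projection

    [u v 1]' = (1/Zc) K [R|t] [Xw Yw Zw 1]'

gives the pixel it falls on. Because a pixel corresponds to a whole
viewing ray, a point only inherits the pixel's mask label if its depth
agrees with the imaged surface: the relative depth error
`e = (d(u,v) − Zc) / d(u,v)` must satisfy `|e| < 0.005` (0.5 %), and the
surface must face the camera (`cos φ = v·n/|v| < 0` for viewing ray `v`
and surface normal `n`). Each lifted point receives a confidence

    s = λ · max(0, −cos φ) + (1 − λ) · d_n,      λ = 0.9 by default,

blending view-angle quality with min–max-normalized depth `d_n`.

Per-view labelings are folded into a running state one view at a time.
For each pair of groups the normalized overlap ratios γ (tables Qx/Qy) are
computed; a group with ≥ 80 % of its mass on unassigned points enters as a
new group, a pair with mutual γ ≥ 0.5 is the same leaf (union, confidences
summed point-wise), and every other overlapping pair is a conflict:
the side with the higher mean confidence keeps the overlap, whose
per-point confidence becomes `|s_x − s_y|`.

Evaluation follows standard instance-segmentation practice: greedy
descending-IoU one-to-one matching, point-level precision/recall/F1,
mean IoU over ground-truth instances, AP at IoU 0.50/0.75, and
R²/MAPE/RMSE agreement for leaf counts.

Also included: the turntable preprocessing chain (voxel downsampling,
RANSAC 3D circle fit of the turntable for metric scale and plane
alignment, pass-through/RGB/statistical filters) and the three-stage mask
post-filter (mean HSV saturation > 40, overlap de-duplication keeping the
finer mask, minimum-enclosing-circle shape ratio ≤ 4 to drop stems).

## Worked example

```r
library(MVLeafSeg)

scene <- generateScene(nLeaves = 8, pointsPerLeaf = 400, seed = 42)
cam   <- CameraModel(600, width = 640, height = 480)
views <- renderViews(scene, cam, cameraRing(32))

res <- runPipeline(scene@cloud, views)          # lift 32 views, then fuse
vis <- Reduce("|", lapply(res$labelings, function(l) instanceLabels(l) >= 0L))
evaluateSegmentation(res$state, gtLabels(scene), subset = vis)
#> MetricsReport
#>   point-level : TP=3200 FP=0 FN=0  precision=1.0000 recall=1.0000 F1=1.0000
#>   object-level: mIoU=1.0000  AP50=1.0000  AP75=1.0000
```

On clean renders the lift-and-fuse chain reproduces the ground truth
exactly on every point visible in at least one view. With segmenter-like
mask corruption (10 % merge, 10 % split, 10 % dropout per mask, seed 7)
the fused F1 is 0.786 versus 0.616 for the average single view and 0.690
after fusing only two views — fusing more views monotonically recovers
what individual corrupted views lose.

A shell front end with the same defaults ships in
`inst/scripts/mvleafseg` (`simulate`, `filter-masks`, `lift`, `fuse`,
`preprocess`, `eval`), all driven by the exported functions.

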