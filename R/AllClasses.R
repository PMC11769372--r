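#' @import methods
#' @importFrom stats dist rnorm runif sd quantile
#' @importFrom utils head tail
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("integerOrNULL", c("integer", "NULL"))

## ---------------------------------------------------------------------------
## Camera geometry
## ---------------------------------------------------------------------------

#' Pinhole camera intrinsics
#'
#' The COLMAP \code{PINHOLE} dialect: separate focal lengths and a principal
#' point, no distortion (undistortion is assumed done upstream).  Pixels are
#' 0-based with centers on integer coordinates.
#'
#' @slot fx,fy focal lengths in pixels (> 0).
#' @slot cx,cy principal point in pixels, inside the raster.
#' @slot width,height raster size in pixels.
#' @export
setClass("CameraModel",
    representation(fx = "numeric", fy = "numeric",
                   cx = "numeric", cy = "numeric",
                   width = "integer", height = "integer"))

setValidity("CameraModel", function(object) {
    msg <- NULL
    if (object@fx <= 0 || object@fy <= 0)
        msg <- c(msg, "focal lengths must be positive")
    if (object@width < 1L || object@height < 1L)
        msg <- c(msg, "raster dimensions must be at least 1")
    if (object@cx < 0 || object@cx >= object@width ||
        object@cy < 0 || object@cy >= object@height)
        msg <- c(msg, "principal point must lie inside the raster")
    if (is.null(msg)) TRUE else msg
})

#' Construct a pinhole camera
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point; defaults to the raster center.
#' @param width,height raster size in pixels.
#' @return A [CameraModel-class] object.
#' @examples
#' CameraModel(600, 600, width = 640, height = 480)
#' @export
CameraModel <- function(fx, fy = fx, cx = (width - 1) / 2,
                        cy = (height - 1) / 2, width, height) {
    new("CameraModel", fx = as.numeric(fx), fy = as.numeric(fy),
        cx = as.numeric(cx), cy = as.numeric(cy),
        width = as.integer(width), height = as.integer(height))
}

setMethod("show", "CameraModel", function(object) {
    cat(sprintf("CameraModel (PINHOLE) %dx%d  fx=%.2f fy=%.2f cx=%.2f cy=%.2f\n",
                object@width, object@height, object@fx, object@fy,
                object@cx, object@cy))
})

#' Rigid camera pose (world to camera)
#'
#' Extrinsics \eqn{[R|t]} mapping world coordinates into the camera frame
#' \eqn{x_c = R p + t}.  The camera center in world coordinates is
#' \eqn{C = -R^\top t}.  Camera axes follow the COLMAP convention:
#' +x right, +y down, +z forward.
#'
#' @slot rotation 3x3 rotation matrix (world to camera).
#' @slot translation length-3 translation vector.
#' @export
setClass("Pose",
    representation(rotation = "matrix", translation = "numeric"))

setValidity("Pose", function(object) {
    R <- object@rotation
    msg <- NULL
    if (!all(dim(R) == c(3L, 3L)) || length(object@translation) != 3L)
        msg <- c(msg, "rotation must be 3x3 and translation length 3")
    else {
        if (max(abs(crossprod(R) - diag(3))) > 1e-9)
            msg <- c(msg, "rotation is not orthonormal within 1e-9")
        if (abs(det(R) - 1) > 1e-9)
            msg <- c(msg, "rotation determinant is not +1 within 1e-9")
    }
    if (any(!is.finite(R)) || any(!is.finite(object@translation)))
        msg <- c(msg, "pose entries must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Construct a camera pose
#'
#' @param rotation 3x3 world-to-camera rotation matrix.
#' @param translation length-3 translation vector.
#' @return A [Pose-class] object.
#' @examples
#' Pose(diag(3), c(0, 0, 0))
#' @export
Pose <- function(rotation, translation) {
    new("Pose", rotation = rotation, translation = as.numeric(translation))
}

setMethod("show", "Pose", function(object) {
    C <- cameraCenter(object)
    cat(sprintf("Pose: camera center (%.4f, %.4f, %.4f)\n", C[1], C[2], C[3]))
})

## ---------------------------------------------------------------------------
## Point cloud
## ---------------------------------------------------------------------------

#' World-space point cloud
#'
#' N points with optional 8-bit RGB, optional per-point unit normals and
#' optional ground-truth instance labels (0-based, -1 = unlabeled).  The row
#' order of \code{coords} defines the point indexing used by every
#' per-point vector in the package.
#'
#' @slot coords N x 3 numeric matrix of XYZ coordinates.
#' @slot rgb N x 3 integer matrix in [0, 255], or NULL.
#' @slot normals N x 3 numeric matrix of unit normals, or NULL.
#' @slot gtLabels integer vector of ground-truth instance ids, or NULL.
#' @export
setClass("PointCloud",
    representation(coords = "matrix", rgb = "matrixOrNULL",
                   normals = "matrixOrNULL", gtLabels = "integerOrNULL"))

setValidity("PointCloud", function(object) {
    n <- nrow(object@coords)
    msg <- NULL
    if (ncol(object@coords) != 3L)
        msg <- c(msg, "coords must have 3 columns")
    if (!is.null(object@rgb) &&
        (nrow(object@rgb) != n || ncol(object@rgb) != 3L))
        msg <- c(msg, "rgb must be N x 3")
    if (!is.null(object@normals) &&
        (nrow(object@normals) != n || ncol(object@normals) != 3L))
        msg <- c(msg, "normals must be N x 3")
    if (!is.null(object@gtLabels) && length(object@gtLabels) != n)
        msg <- c(msg, "gtLabels must have length N")
    if (is.null(msg)) TRUE else msg
})

#' Construct a point cloud
#'
#' @param coords N x 3 matrix of coordinates.
#' @param rgb optional N x 3 matrix of 8-bit colors.
#' @param normals optional N x 3 matrix of unit normals.
#' @param gtLabels optional integer vector of instance labels.
#' @return A [PointCloud-class] object.
#' @examples
#' PointCloud(matrix(rnorm(30), ncol = 3))
#' @export
PointCloud <- function(coords, rgb = NULL, normals = NULL, gtLabels = NULL) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (!is.null(rgb)) { rgb <- as.matrix(rgb); storage.mode(rgb) <- "integer" }
    if (!is.null(normals)) {
        normals <- as.matrix(normals); storage.mode(normals) <- "double"
    }
    if (!is.null(gtLabels)) gtLabels <- as.integer(gtLabels)
    new("PointCloud", coords = coords, rgb = rgb, normals = normals,
        gtLabels = gtLabels)
}

setMethod("show", "PointCloud", function(object) {
    cat(sprintf("PointCloud with %d points%s%s%s\n", nrow(object@coords),
                if (!is.null(object@rgb)) ", RGB" else "",
                if (!is.null(object@normals)) ", normals" else "",
                if (!is.null(object@gtLabels))
                    sprintf(", %d ground-truth instances",
                            length(unique(object@gtLabels[object@gtLabels >= 0L])))
                else ""))
})

## ---------------------------------------------------------------------------
## Views
## ---------------------------------------------------------------------------

#' One calibrated view of the scene
#'
#' Bundles a camera, its pose and the per-view rasters the lifting stage
#' consumes: a depth map in world units (NA = no data), a world-frame unit
#' normal map, and an instance-label raster (0 = background, k = mask k).
#' Rasters are stored as height x width matrices (row = pixel row v,
#' column = pixel column u, both 0-based in the API).
#'
#' @slot viewId integer view identifier.
#' @slot camera a [CameraModel-class].
#' @slot pose a [Pose-class].
#' @slot depth H x W numeric matrix of depths (world units, NA = no data).
#' @slot normal H x W x 3 numeric array of world-frame unit normals.
#' @slot labels H x W integer matrix of mask ids (0 = none).
#' @slot rgb optional H x W x 3 array in [0, 1].
#' @slot winner optional H x W integer matrix of the splatted point index
#'   that owns each pixel (renderer bookkeeping; NA off-surface).
#' @export
setClass("ViewBundle",
    representation(viewId = "integer", camera = "CameraModel", pose = "Pose",
                   depth = "matrix", normal = "array", labels = "matrix",
                   rgb = "arrayOrNULL", winner = "matrixOrNULL"))

setValidity("ViewBundle", function(object) {
    H <- object@camera@height; W <- object@camera@width
    msg <- NULL
    if (!all(dim(object@depth) == c(H, W)))
        msg <- c(msg, "depth raster does not match camera raster size")
    if (!all(dim(object@normal) == c(H, W, 3L)))
        msg <- c(msg, "normal raster must be H x W x 3")
    if (!all(dim(object@labels) == c(H, W)))
        msg <- c(msg, "label raster does not match camera raster size")
    d <- object@depth
    if (any(d[!is.na(d)] <= 0))
        msg <- c(msg, "valid depths must be positive")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ViewBundle", function(object) {
    cat(sprintf("ViewBundle %d: %dx%d, %d mask labels, %.1f%% pixels covered\n",
                object@viewId, object@camera@width, object@camera@height,
                length(setdiff(unique(as.vector(object@labels)), 0L)),
                100 * mean(!is.na(object@depth))))
})

#' Per-view 3D labeling lifted from 2D masks
#'
#' For each point of the cloud: the mask label inherited from this view
#' (-1 = no grouping information) and a per-point confidence score
#' (0 wherever the label is -1).
#'
#' @slot viewId integer view identifier.
#' @slot labels integer vector over the cloud, -1 = unassigned.
#' @slot conf numeric vector of confidence scores (>= 0).
#' @export
setClass("ViewLabeling",
    representation(viewId = "integer", labels = "integer", conf = "numeric"))

setValidity("ViewLabeling", function(object) {
    msg <- NULL
    if (length(object@labels) != length(object@conf))
        msg <- c(msg, "labels and conf must have equal length")
    if (any(object@conf < 0))
        msg <- c(msg, "confidences must be non-negative")
    if (any(object@conf[object@labels == -1L] != 0))
        msg <- c(msg, "conf must be 0 wherever label is -1")
    if (is.null(msg)) TRUE else msg
})

#' @export
ViewLabeling <- function(viewId, labels, conf) {
    new("ViewLabeling", viewId = as.integer(viewId),
        labels = as.integer(labels), conf = as.numeric(conf))
}

setMethod("show", "ViewLabeling", function(object) {
    n <- length(object@labels)
    k <- sum(object@labels >= 0L)
    cat(sprintf("ViewLabeling (view %d): %d/%d points assigned, %d groups\n",
                object@viewId, k, n,
                length(unique(object@labels[object@labels >= 0L]))))
})

## ---------------------------------------------------------------------------
## Fusion
## ---------------------------------------------------------------------------

#' Fusion parameters
#'
#' @slot eThreshold relative depth-error gate; a projected point is accepted
#'   only if |(d - Zc)/d| is below this (default 0.005, i.e. 0.5\%).
#' @slot lambda weight of the view-angle term against the depth term in the
#'   confidence score, in (0, 1) (default 0.9).
#' @slot tauMatch mutual overlap ratio above which two groups are declared
#'   the same instance (default 0.5).
#' @slot tauUnmatched fraction of a group's mass on "unassigned" above which
#'   the whole group is treated as new (default 0.8).
#' @slot distanceMode "literal" uses the normalized depth as printed in the
#'   score definition (farther = higher); "proximity" uses one minus it.
#' @export
setClass("FusionConfig",
    representation(eThreshold = "numeric", lambda = "numeric",
                   tauMatch = "numeric", tauUnmatched = "numeric",
                   distanceMode = "character"))

setValidity("FusionConfig", function(object) {
    msg <- NULL
    if (object@eThreshold <= 0 || object@eThreshold >= 1)
        msg <- c(msg, "eThreshold must be in (0, 1)")
    if (object@lambda <= 0 || object@lambda >= 1)
        msg <- c(msg, "lambda must be in (0, 1)")
    if (object@tauMatch <= 0 || object@tauMatch > 1)
        msg <- c(msg, "tauMatch must be in (0, 1]")
    if (object@tauUnmatched <= 0 || object@tauUnmatched > 1)
        msg <- c(msg, "tauUnmatched must be in (0, 1]")
    if (!object@distanceMode %in% c("literal", "proximity"))
        msg <- c(msg, "distanceMode must be 'literal' or 'proximity'")
    if (is.null(msg)) TRUE else msg
})

#' Construct a fusion configuration
#'
#' Defaults follow the pipeline's operating point: depth-error gate at 0.5\%
#' and view-angle weight 0.9.
#'
#' @param eThreshold,lambda,tauMatch,tauUnmatched,distanceMode see
#'   [FusionConfig-class].
#' @return A [FusionConfig-class] object.
#' @examples
#' FusionConfig()
#' @export
FusionConfig <- function(eThreshold = 0.005, lambda = 0.9, tauMatch = 0.5,
                         tauUnmatched = 0.8, distanceMode = "literal") {
    new("FusionConfig", eThreshold = eThreshold, lambda = lambda,
        tauMatch = tauMatch, tauUnmatched = tauUnmatched,
        distanceMode = distanceMode)
}

setMethod("show", "FusionConfig", function(object) {
    cat(sprintf(paste0("FusionConfig: e<%.3g, lambda=%.2f, tauMatch=%.2f, ",
                       "tauUnmatched=%.2f, mode=%s\n"),
                object@eThreshold, object@lambda, object@tauMatch,
                object@tauUnmatched, object@distanceMode))
})

#' Running fused segmentation over the original cloud
#'
#' @slot labels integer per-point instance label (-1 = unassigned).
#' @slot conf numeric per-point confidence mass (0 where unassigned).
#' @slot nextLabel next fresh label id.
#' @slot mergeCount number of per-view merges folded in so far.
#' @export
setClass("FusionState",
    representation(labels = "integer", conf = "numeric",
                   nextLabel = "integer", mergeCount = "integer"))

setValidity("FusionState", function(object) {
    msg <- NULL
    if (length(object@labels) != length(object@conf))
        msg <- c(msg, "labels and conf must have equal length")
    if (any(object@conf < 0))
        msg <- c(msg, "confidence mass must be non-negative")
    if (any(object@conf[object@labels == -1L] != 0))
        msg <- c(msg, "conf must be 0 where unassigned")
    if (is.null(msg)) TRUE else msg
})

#' Create an empty fusion state over n points
#' @param n number of points in the cloud.
#' @return A [FusionState-class] with every point unassigned.
#' @export
emptyFusionState <- function(n) {
    new("FusionState", labels = rep(-1L, n), conf = rep(0, n),
        nextLabel = 0L, mergeCount = 0L)
}

setMethod("show", "FusionState", function(object) {
    cat(sprintf("FusionState: %d/%d points in %d groups after %d merges\n",
                sum(object@labels >= 0L), length(object@labels),
                length(unique(object@labels[object@labels >= 0L])),
                object@mergeCount))
})

## ---------------------------------------------------------------------------
## Masks
## ---------------------------------------------------------------------------

#' A set of binary 2D masks for one view
#'
#' Masks are stored sparsely as 1-based linear pixel indices into a
#' height x width raster (column-major, matching R matrices).
#'
#' @slot viewId integer view identifier.
#' @slot masks named list of integer index vectors; names are mask ids.
#' @slot width,height raster size.
#' @export
setClass("MaskSet",
    representation(viewId = "integer", masks = "list",
                   width = "integer", height = "integer"))

setValidity("MaskSet", function(object) {
    msg <- NULL
    if (length(object@masks) && is.null(names(object@masks)))
        msg <- c(msg, "masks must be named by mask id")
    if (anyDuplicated(names(object@masks)))
        msg <- c(msg, "mask ids must be unique within a view")
    npix <- object@width * object@height
    for (m in object@masks)
        if (length(m) < 1L || any(m < 1L) || any(m > npix))
            msg <- c(msg, "mask pixel indices out of raster range")
    if (is.null(msg)) TRUE else unique(msg)
})

#' @export
MaskSet <- function(viewId, masks, width, height) {
    masks <- lapply(masks, function(m) sort(unique(as.integer(m))))
    new("MaskSet", viewId = as.integer(viewId), masks = masks,
        width = as.integer(width), height = as.integer(height))
}

setMethod("show", "MaskSet", function(object) {
    cat(sprintf("MaskSet (view %d): %d masks on %dx%d raster\n",
                object@viewId, length(object@masks),
                object@width, object@height))
})

## ---------------------------------------------------------------------------
## Preprocessing
## ---------------------------------------------------------------------------

#' Fitted 3D circle
#'
#' @slot center length-3 circle center.
#' @slot radius circle radius (> 0, model units).
#' @slot normal unit normal of the circle's plane.
#' @slot inliers integer indices of inlier points.
#' @slot inlierFraction fraction of candidate points that are inliers.
#' @export
setClass("CircleFit",
    representation(center = "numeric", radius = "numeric", normal = "numeric",
                   inliers = "integer", inlierFraction = "numeric"))

setValidity("CircleFit", function(object) {
    msg <- NULL
    if (object@radius <= 0) msg <- c(msg, "radius must be positive")
    if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-6)
        msg <- c(msg, "plane normal must be unit length")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CircleFit", function(object) {
    cat(sprintf("CircleFit: r=%.6g, center (%.4g, %.4g, %.4g), %.1f%% inliers\n",
                object@radius, object@center[1], object@center[2],
                object@center[3], 100 * object@inlierFraction))
})

#' Metric scale calibration from the turntable circle
#'
#' @slot scale world units (e.g. meters) per model unit.
#' @slot rotation 3x3 rotation taking the fitted plane normal to +Z.
#' @slot translation length-3 translation applied after rotation, so that
#'   transformed coordinates are \code{R p + t} with the circle center at
#'   the origin in the Z = 0 plane.
#' @export
setClass("ScaleCalibration",
    representation(scale = "numeric", rotation = "matrix",
                   translation = "numeric"))

setValidity("ScaleCalibration", function(object) {
    msg <- NULL
    if (object@scale <= 0) msg <- c(msg, "scale must be positive")
    if (max(abs(crossprod(object@rotation) - diag(3))) > 1e-8)
        msg <- c(msg, "calibration rotation must be orthonormal")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ScaleCalibration", function(object) {
    cat(sprintf("ScaleCalibration: %.6g world units per model unit\n",
                object@scale))
})

## ---------------------------------------------------------------------------
## Synthetic scenes
## ---------------------------------------------------------------------------

#' Synthetic turntable scene
#'
#' A leaf-like scene with per-point ground truth, used in place of the
#' camera + reconstruction + segmenter front end.
#'
#' @slot cloud a [PointCloud-class] with RGB, normals and gtLabels.
#' @slot nLeaves number of leaf instances.
#' @slot turntableCenter,turntableRadius the turntable circle (Z = 0 plane).
#' @slot seed generator seed.
#' @export
setClass("SyntheticScene",
    representation(cloud = "PointCloud", nLeaves = "integer",
                   turntableCenter = "numeric", turntableRadius = "numeric",
                   seed = "integer"))

setMethod("show", "SyntheticScene", function(object) {
    cat(sprintf("SyntheticScene: %d leaves, %d points (seed %d)\n",
                object@nLeaves, nrow(object@cloud@coords), object@seed))
})

#' Mask corruption specification
#'
#' Controlled degradation of rendered ground-truth mask rasters, emulating
#' typical automatic-segmenter failure modes: under-segmentation (merge),
#' over-segmentation (split), missed instances (dropout) and boundary noise
#' (morphological erosion/dilation).
#'
#' @slot mergeProb,splitProb,dropoutProb per-mask probabilities in [0, 1].
#' @slot boundaryRadius radius in pixels of random erode/dilate (0 = off).
#' @slot seed RNG seed for the corruption draws.
#' @export
setClass("CorruptionSpec",
    representation(mergeProb = "numeric", splitProb = "numeric",
                   dropoutProb = "numeric", boundaryRadius = "numeric",
                   seed = "integer"))

setValidity("CorruptionSpec", function(object) {
    p <- c(object@mergeProb, object@splitProb, object@dropoutProb)
    if (any(p < 0 | p > 1)) "probabilities must be in [0, 1]" else TRUE
})

#' @param mergeProb,splitProb,dropoutProb,boundaryRadius,seed see
#'   [CorruptionSpec-class].
#' @rdname CorruptionSpec-class
#' @export
CorruptionSpec <- function(mergeProb = 0, splitProb = 0, dropoutProb = 0,
                           boundaryRadius = 0, seed = 1L) {
    new("CorruptionSpec", mergeProb = mergeProb, splitProb = splitProb,
        dropoutProb = dropoutProb, boundaryRadius = boundaryRadius,
        seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Metrics
## ---------------------------------------------------------------------------

#' Segmentation evaluation report
#'
#' Point-level counts and rates, object-level mean IoU and average precision
#' at the configured IoU thresholds, and (optionally) count-agreement
#' statistics across samples.
#'
#' @slot tp,fp,fn point-level counts.
#' @slot precision,recall,f1 point-level rates (NA when undefined).
#' @slot miou mean IoU over ground-truth instances.
#' @slot ap named numeric of average precision per IoU threshold.
#' @slot r2,mape,rmse count-agreement statistics (NA unless computed).
#' @export
setClass("MetricsReport",
    representation(tp = "numeric", fp = "numeric", fn = "numeric",
                   precision = "numeric", recall = "numeric", f1 = "numeric",
                   miou = "numeric", ap = "numeric",
                   r2 = "numeric", mape = "numeric", rmse = "numeric"))

setMethod("show", "MetricsReport", function(object) {
    cat("MetricsReport\n")
    cat(sprintf("  point-level : TP=%d FP=%d FN=%d  precision=%.4f recall=%.4f F1=%.4f\n",
                object@tp, object@fp, object@fn, object@precision,
                object@recall, object@f1))
    cat(sprintf("  object-level: mIoU=%.4f  %s\n", object@miou,
                paste(sprintf("AP%s=%.4f", sub("^0\\.", "", names(object@ap)),
                              object@ap), collapse = "  ")))
    if (!is.na(object@r2) || !is.na(object@mape) || !is.na(object@rmse))
        cat(sprintf("  counts      : R2=%.4f MAPE=%.2f%% RMSE=%.4f\n",
                    object@r2, object@mape, object@rmse))
})
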