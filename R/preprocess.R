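## Point-cloud cleanup chain for turntable captures: voxel downsampling,
## RANSAC 3D circle fit of the turntable for metric scale and orientation,
## pass-through / RGB / statistical filtering, and frame restoration.

#' Voxel-grid downsampling
#'
#' One representative point (the centroid of the members) per occupied
#' voxel; RGB/normals/labels of the representative are those of the first
#' member (labels are categorical, and for display attributes the first
#' member is as good as any).
#'
#' @param cloud a [PointCloud-class].
#' @param voxelSize edge length of the cubic voxels (> 0).
#' @return The downsampled [PointCloud-class].
#' @export
voxelDownsample <- function(cloud, voxelSize) {
    stopifnot(voxelSize > 0)
    xyz <- coords(cloud)
    key <- paste(floor(xyz[, 1] / voxelSize),
                 floor(xyz[, 2] / voxelSize),
                 floor(xyz[, 3] / voxelSize))
    f <- factor(key, levels = unique(key))  # stable voxel order
    cent <- rowsum(xyz, f) / as.vector(table(f)[levels(f)])
    first <- which(!duplicated(key))
    PointCloud(cent,
               rgb = if (!is.null(cloud@rgb)) cloud@rgb[first, , drop = FALSE],
               normals = if (!is.null(cloud@normals))
                   cloud@normals[first, , drop = FALSE],
               gtLabels = if (!is.null(cloud@gtLabels)) cloud@gtLabels[first])
}

## Internal: circumcircle of 3 points in 3D. Returns list(center, radius,
## normal) or NULL when (near-)collinear.
circumcircle3d <- function(p1, p2, p3) {
    a <- p2 - p1; b <- p3 - p1
    n <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    n2 <- sum(n^2)
    if (n2 < 1e-24) return(NULL)
    aa <- sum(a^2); bb <- sum(b^2); ab <- sum(a * b)
    d <- 2 * (aa * bb - ab^2)
    if (d < 1e-24) return(NULL)
    s <- (bb * (aa - ab)) / d
    t <- (aa * (bb - ab)) / d
    center <- p1 + s * a + t * b
    list(center = center, radius = sqrt(sum((p1 - center)^2)),
         normal = n / sqrt(n2))
}

## Internal: distance of points to a circle curve in 3D.
circleDistance <- function(xyz, center, radius, normal) {
    w <- sweep(xyz, 2L, center, "-")
    out <- as.vector(w %*% normal)
    radial <- sqrt(pmax(rowSums(w^2) - out^2, 0))
    sqrt((radial - radius)^2 + out^2)
}

#' RANSAC 3D circle fit
#'
#' Repeated 3-point hypotheses (plane through the sample, circumcircle
#' within the plane); inliers are points within \code{inlierTol} of the
#' circle curve in 3D, where the tolerance defaults to 0.5\% of the
#' hypothesized radius.  The best-consensus circle is refined by a
#' least-squares refit on its inliers (plane by principal components, then
#' an algebraic circle fit in the plane).
#'
#' @param xyz N x 3 matrix of candidate points (e.g. a height slab around
#'   the turntable rim), N >= 3, not all collinear.
#' @param nIter number of RANSAC iterations (default 1000).
#' @param inlierTol absolute inlier tolerance, or NULL for 0.5\% of each
#'   hypothesis' radius (default NULL).
#' @param seed RNG seed for the hypothesis draws.
#' @param refit refine with an inlier least-squares fit (default TRUE).
#' @return A [CircleFit-class].
#' @export
ransacCircleFit <- function(xyz, nIter = 1000L, inlierTol = NULL,
                            seed = 1L, refit = TRUE) {
    xyz <- as.matrix(xyz)
    if (nrow(xyz) < 3L) stop("need at least 3 points")
    best <- NULL; bestCount <- -1L
    withr::with_seed(seed, {
        for (it in seq_len(nIter)) {
            s <- sample.int(nrow(xyz), 3L)
            cc <- circumcircle3d(xyz[s[1], ], xyz[s[2], ], xyz[s[3], ])
            if (is.null(cc)) next
            tol <- if (is.null(inlierTol)) 0.005 * cc$radius else inlierTol
            nin <- sum(circleDistance(xyz, cc$center, cc$radius, cc$normal)
                       < tol)
            if (nin > bestCount) { bestCount <- nin; best <- cc }
        }
    })
    if (is.null(best)) stop("all RANSAC samples were collinear")
    tol <- if (is.null(inlierTol)) 0.005 * best$radius else inlierTol
    inl <- which(circleDistance(xyz, best$center, best$radius, best$normal)
                 < tol)
    if (refit && length(inl) >= 3L) {
        ref <- fitCircleLSQ(xyz[inl, , drop = FALSE])
        if (!is.null(ref)) {
            tol <- if (is.null(inlierTol)) 0.005 * ref$radius else inlierTol
            inl2 <- which(circleDistance(xyz, ref$center, ref$radius,
                                         ref$normal) < tol)
            if (length(inl2) >= length(inl)) { best <- ref; inl <- inl2 }
        }
    }
    if (best$normal[3] < 0) best$normal <- -best$normal
    new("CircleFit", center = as.numeric(best$center), radius = best$radius,
        normal = as.numeric(best$normal), inliers = as.integer(inl),
        inlierFraction = length(inl) / nrow(xyz))
}

## Internal: least-squares circle through >= 3 points: plane by PCA, then
## Kasa algebraic circle fit in plane coordinates.
fitCircleLSQ <- function(xyz) {
    ctr <- colMeans(xyz)
    w <- sweep(xyz, 2L, ctr, "-")
    sv <- svd(w)
    normal <- sv$v[, 3]
    e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
    x <- as.vector(w %*% e1); y <- as.vector(w %*% e2)
    A <- cbind(2 * x, 2 * y, 1)
    b <- x^2 + y^2
    sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    r2 <- sol[3] + sol[1]^2 + sol[2]^2
    if (r2 <= 0) return(NULL)
    list(center = ctr + sol[1] * e1 + sol[2] * e2,
         radius = sqrt(r2), normal = normal)
}

## Internal: minimal rotation taking unit vector a onto unit vector b.
rotationBetween <- function(a, b) {
    v <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    cth <- sum(a * b)
    if (cth < -1 + 1e-12) {  # antipodal: rotate pi about any orthogonal axis
        ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        v <- ax - sum(ax * a) * a
        v <- v / sqrt(sum(v^2))
        return(2 * outer(v, v) - diag(3))
    }
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
                 3, 3, byrow = TRUE)
    diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Metric scale calibration from a fitted turntable circle
#'
#' The reconstruction lives in an arbitrary normalized frame; a reference
#' object of known physical size fixes the metric scale.  With the
#' turntable's real diameter, \code{scale = realDiameter / (2 radius)}, and
#' a rigid transform rotates the fitted plane normal to +Z and moves the
#' circle center to the origin.
#'
#' @param fit a [CircleFit-class].
#' @param realDiameter the turntable's physical diameter (world units).
#' @return A [ScaleCalibration-class].
#' @examples
#' fit <- new("CircleFit", center = c(0, 0, 0), radius = 0.05,
#'            normal = c(0, 0, 1), inliers = 1L, inlierFraction = 1)
#' calibrateScale(fit, 0.30)  # scale 3 world units per model unit
#' @export
calibrateScale <- function(fit, realDiameter) {
    stopifnot(realDiameter > 0)
    R <- rotationBetween(fit@normal, c(0, 0, 1))
    new("ScaleCalibration", scale = realDiameter / (2 * fit@radius),
        rotation = R, translation = as.numeric(-R %*% fit@center))
}

#' Apply / invert a calibration transform
#'
#' \code{applyCalibration} maps model coordinates into the aligned frame
#' (\code{R p + t}), optionally applying the metric scale;
#' \code{invertCalibration} restores the original coordinates exactly, so
#' the estimated camera poses remain applicable after filtering.
#'
#' @param cloud a [PointCloud-class].
#' @param calibration a [ScaleCalibration-class].
#' @param applyScale multiply by the metric scale factor (default FALSE:
#'   filtering thresholds are usually given in the aligned model frame).
#' @return The transformed [PointCloud-class].
#' @export
applyCalibration <- function(cloud, calibration, applyScale = FALSE) {
    xyz <- coords(cloud) %*% t(calibration@rotation)
    xyz <- sweep(xyz, 2L, calibration@translation, "+")
    if (applyScale) xyz <- xyz * calibration@scale
    initialize(cloud, coords = xyz)
}

#' @rdname applyCalibration
#' @export
invertCalibration <- function(cloud, calibration, applyScale = FALSE) {
    xyz <- coords(cloud)
    if (applyScale) xyz <- xyz / calibration@scale
    xyz <- sweep(xyz, 2L, calibration@translation, "-")
    initialize(cloud, coords = xyz %*% calibration@rotation)
}

#' Pass-through filter
#'
#' Keeps points whose coordinate on one axis lies in a closed interval
#' (used e.g. to delete the pot and soil below the aligned turntable plane).
#'
#' @param cloud a [PointCloud-class].
#' @param axis 1, 2 or 3 (or "x"/"y"/"z").
#' @param lo,hi inclusive bounds.
#' @return The filtered [PointCloud-class].
#' @export
passthroughFilter <- function(cloud, axis = "z", lo = -Inf, hi = Inf) {
    if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
    v <- coords(cloud)[, axis]
    subsetCloud(cloud, v >= lo & v <= hi)
}

#' RGB background filter
#'
#' Removes points whose color falls in the configured background box.  The
#' default box matches a low-saturation white/gray studio: points whose
#' 8-bit channel spread \code{max(R,G,B) - min(R,G,B)} is below
#' \code{maxChroma} are treated as background remnants and removed.
#'
#' @param cloud a [PointCloud-class] with RGB.
#' @param maxChroma channel-spread threshold on the 8-bit scale
#'   (default 25); the bound is inclusive on the keep side
#'   (spread >= maxChroma is kept).
#' @return The filtered [PointCloud-class].
#' @export
rgbFilter <- function(cloud, maxChroma = 25) {
    if (is.null(cloud@rgb)) stop("cloud has no RGB attribute")
    spread <- apply(cloud@rgb, 1L, max) - apply(cloud@rgb, 1L, min)
    subsetCloud(cloud, spread >= maxChroma)
}

#' Statistical outlier removal
#'
#' Removes points whose mean distance to their k nearest neighbours exceeds
#' the global mean by more than \code{stdMult} standard deviations - the
#' standard treatment for the scattered erroneous points a multi-view
#' reconstruction leaves around thin structures.
#'
#' @param cloud a [PointCloud-class].
#' @param k number of neighbours (default 20).
#' @param stdMult standard-deviation multiplier (default 2).
#' @return The filtered [PointCloud-class] (a subset of the input).
#' @export
statisticalFilter <- function(cloud, k = 20L, stdMult = 2) {
    md <- knnMeanDist(coords(cloud), k)
    s <- sd(md)
    if (is.na(s) || s == 0) return(cloud)
    subsetCloud(cloud, md <= mean(md) + stdMult * s)
}
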