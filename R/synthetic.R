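## Synthetic turntable fixture generator standing in for the camera +
## SfM/MVS + 2D segmenter front end: leaf-like 3D scenes with ground truth,
## a ring of calibrated cameras, z-buffer point-splat renders (depth, normal
## and instance-mask rasters that are mutually consistent by construction),
## and controlled mask corruption.

#' Generate a synthetic leaf scene
#'
#' Leaves are planar elliptical surface patches arranged around a central
#' vertical stem axis at staggered heights and azimuths (a young rosette
#' seedling), uniformly sampled to points.  Tilts are kept moderate and the
#' vertical stagger generous so that distinct leaves are well separated
#' relative to the depth-gating tolerance of the lifting stage, as on a real
#' seedling whose leaves do not interpenetrate.  Deterministic given
#' \code{seed}.
#'
#' @param nLeaves number of leaf instances (default 8).
#' @param pointsPerLeaf points sampled per leaf (default 400).
#' @param seed RNG seed.
#' @param tiltRange leaf tilt from horizontal, degrees (default c(8, 18)).
#' @param sizeRange semi-major axis range in scene units (default
#'   c(0.09, 0.13)).
#' @param heightStep vertical spacing between consecutive leaves
#'   (default 0.12).
#' @param turntableRadius radius of the turntable circle at Z = 0
#'   (default 0.5).
#' @return A [SyntheticScene-class]; the cloud carries RGB, per-point unit
#'   normals and ground-truth labels 0..nLeaves-1.
#' @export
generateScene <- function(nLeaves = 8L, pointsPerLeaf = 400L, seed = 42L,
                          tiltRange = c(8, 18), sizeRange = c(0.09, 0.13),
                          heightStep = 0.12, turntableRadius = 0.5) {
    stopifnot(nLeaves >= 1L, pointsPerLeaf >= 10L)
    withr::with_seed(as.integer(seed), {
        coordsL <- vector("list", nLeaves)
        normalsL <- vector("list", nLeaves)
        rgbL <- vector("list", nLeaves)
        for (i in seq_len(nLeaves)) {
            az <- (i - 1) * 2 * pi / nLeaves + runif(1, -8, 8) * pi / 180
            tilt <- runif(1, tiltRange[1], tiltRange[2]) * pi / 180
            a <- runif(1, sizeRange[1], sizeRange[2])
            b <- a * runif(1, 0.55, 0.75)
            h <- 0.25 + (i - 1) * heightStep
            rad <- runif(1, 0.15, 0.25)
            ctr <- c(rad * cos(az), rad * sin(az), h)
            ## leaf frame: normal tilted off +Z toward the outward radial
            n <- c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt))
            e1 <- c(-sin(az), cos(az), 0)
            e2 <- c(n[2] * e1[3] - n[3] * e1[2],
                    n[3] * e1[1] - n[1] * e1[3],
                    n[1] * e1[2] - n[2] * e1[1])
            ## uniform sample of the ellipse interior
            r <- sqrt(runif(pointsPerLeaf)); th <- runif(pointsPerLeaf, 0, 2 * pi)
            u <- a * r * cos(th); v <- b * r * sin(th)
            pts <- cbind(ctr[1] + u * e1[1] + v * e2[1],
                         ctr[2] + u * e1[2] + v * e2[2],
                         ctr[3] + u * e1[3] + v * e2[3])
            coordsL[[i]] <- pts
            normalsL[[i]] <- matrix(n, pointsPerLeaf, 3L, byrow = TRUE)
            g <- sample(90:190, 1)
            rgbL[[i]] <- matrix(as.integer(c(round(g * 0.35), g,
                                             round(g * 0.3))),
                                pointsPerLeaf, 3L, byrow = TRUE)
        }
        cloud <- PointCloud(do.call(rbind, coordsL),
                            rgb = do.call(rbind, rgbL),
                            normals = do.call(rbind, normalsL),
                            gtLabels = rep(seq_len(nLeaves) - 1L,
                                           each = pointsPerLeaf))
        new("SyntheticScene", cloud = cloud, nLeaves = as.integer(nLeaves),
            turntableCenter = c(0, 0, 0), turntableRadius = turntableRadius,
            seed = as.integer(seed))
    })
}

#' Turntable camera ring
#'
#' Poses for a ring of cameras at uniform azimuth intervals of
#' \code{360/nViews} degrees (11.25 degrees at the default 32 views),
#' elevations interpolated over \code{elevation}, all looking at
#' \code{center}.  Camera axes follow the COLMAP convention (+x right,
#' +y down, +z forward).
#'
#' @param nViews number of views (default 32).
#' @param elevation elevation range in degrees above the horizon
#'   (default c(30, 45)).
#' @param radius camera distance from \code{center} (default 4).
#' @param center look-at point (default the scene's leaf stack center).
#' @return List of [Pose-class] objects in capture (azimuth) order.
#' @export
cameraRing <- function(nViews = 32L, elevation = c(30, 45), radius = 4,
                       center = c(0, 0, 0.65)) {
    stopifnot(nViews >= 1L, radius > 0)
    elev <- if (nViews == 1L) elevation[1] else
        seq(elevation[1], elevation[2], length.out = nViews)
    lapply(seq_len(nViews), function(k) {
        az <- (k - 1) * 2 * pi / nViews
        el <- elev[k] * pi / 180
        C <- center + radius * c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
        zc <- (center - C) / sqrt(sum((center - C)^2))      # forward
        xc <- c(zc[2], -zc[1], 0)                           # right (= zc x up)
        xc <- xc / sqrt(sum(xc^2))
        yc <- c(zc[2] * xc[3] - zc[3] * xc[2],              # down
                zc[3] * xc[1] - zc[1] * xc[3],
                zc[1] * xc[2] - zc[2] * xc[1])
        R <- rbind(xc, yc, zc, deparse.level = 0)
        Pose(R, as.numeric(-R %*% C))
    })
}

#' Z-buffer point-splat render of a scene
#'
#' Each point is splatted as a disc of \code{splatRadius} pixels; the
#' nearest point wins every contested pixel.  The depth raster stores the
#' winner's exact camera-frame depth, the normal raster its surface normal
#' and the label raster its ground-truth instance id plus one (0 =
#' background), so cloud and rasters are geometrically consistent by
#' construction - the property a real depth-fused reconstruction only
#' approximates.
#'
#' @param scene a [SyntheticScene-class] (or any cloud with normals and
#'   gtLabels).
#' @param camera a [CameraModel-class].
#' @param pose a [Pose-class].
#' @param viewId view identifier stored in the bundle.
#' @param splatRadius splat radius in pixels (default 2).
#' @return A [ViewBundle-class] with depth, normal, labels, rgb and winner
#'   rasters.
#' @export
renderView <- function(scene, camera, pose, viewId = 0L, splatRadius = 2L) {
    cloud <- if (is(scene, "SyntheticScene")) scene@cloud else scene
    if (is.null(cloud@normals) || is.null(cloud@gtLabels))
        stop("renderView needs a cloud with normals and gtLabels")
    H <- camera@height; W <- camera@width
    pr <- projectPoints(coords(cloud), camera, pose)
    ui <- round(pr$u); vi <- round(pr$v)

    off <- expand.grid(dx = -splatRadius:splatRadius,
                       dy = -splatRadius:splatRadius)
    off <- off[off$dx^2 + off$dy^2 <= splatRadius^2, , drop = FALSE]

    idx <- which(pr$hit)
    pid <- rep(idx, each = nrow(off))
    px <- rep(ui[idx], each = nrow(off)) + off$dx
    py <- rep(vi[idx], each = nrow(off)) + off$dy
    keep <- px >= 0 & px < W & py >= 0 & py < H
    pid <- pid[keep]; px <- px[keep]; py <- py[keep]
    z <- pr$zc[pid]
    ## paint far-to-near so the nearest point's write survives
    ord <- order(-z, -pid)
    lin <- px[ord] * H + (py[ord] + 1L)  # column-major into the H x W matrix

    depth <- matrix(NA_real_, H, W)
    winner <- matrix(NA_integer_, H, W)
    depth[lin] <- z[ord]
    winner[lin] <- pid[ord]

    normal <- array(NA_real_, c(H, W, 3L))
    lab <- matrix(0L, H, W)
    won <- which(!is.na(winner))
    wpid <- winner[won]
    for (d in 1:3) {
        plane <- matrix(NA_real_, H, W)
        plane[won] <- cloud@normals[wpid, d]
        normal[, , d] <- plane
    }
    lab[won] <- cloud@gtLabels[wpid] + 1L

    rgb <- NULL
    if (!is.null(cloud@rgb)) {
        rgb <- array(0.9, c(H, W, 3L))  # light gray studio background
        for (d in 1:3) {
            plane <- rgb[, , d]
            plane[won] <- cloud@rgb[wpid, d] / 255
            rgb[, , d] <- plane
        }
    }
    new("ViewBundle", viewId = as.integer(viewId), camera = camera,
        pose = pose, depth = depth, normal = normal, labels = lab,
        rgb = rgb, winner = winner)
}

#' Render every view of a camera ring
#'
#' @param scene a [SyntheticScene-class].
#' @param camera a [CameraModel-class] shared by all views.
#' @param poses list of [Pose-class] from [cameraRing].
#' @param splatRadius splat radius in pixels.
#' @return List of [ViewBundle-class], viewIds 1..n in capture order.
#' @export
renderViews <- function(scene, camera, poses, splatRadius = 2L) {
    lapply(seq_along(poses), function(i)
        renderView(scene, camera, poses[[i]], viewId = i,
                   splatRadius = splatRadius))
}

#' Corrupt a rendered mask raster
#'
#' Applies, per mask and independently with the configured probabilities:
#' merge (the mask is unified with the raster-nearest other mask), split
#' (the mask is bisected by a random line through its centroid, one half
#' getting a fresh label), dropout (the mask is zeroed), and optionally a
#' random erosion or dilation of radius \code{boundaryRadius}.  Only the
#' label raster changes; depth and normals stay intact, exactly like a 2D
#' segmenter erring on a correctly reconstructed scene.  Deterministic
#' given \code{spec@seed} and the view id.
#'
#' @param bundle a [ViewBundle-class].
#' @param spec a [CorruptionSpec-class].
#' @return The corrupted [ViewBundle-class].
#' @export
corruptMasks <- function(bundle, spec) {
    lab <- bundle@labels
    H <- nrow(lab); W <- ncol(lab)
    withr::with_seed(spec@seed + 7919L * bundle@viewId, {
        ids <- setdiff(sort(unique(as.vector(lab))), 0L)
        nextId <- max(c(ids, 0L)) + 1L
        for (k in ids) {
            if (!any(lab == k)) next  # consumed by an earlier merge
            u <- runif(3)
            if (u[1] < spec@dropoutProb) {
                lab[lab == k] <- 0L
                next
            }
            if (u[2] < spec@mergeProb) {
                others <- setdiff(unique(as.vector(lab)), c(0L, k))
                if (length(others)) {
                    cen <- maskCentroid(lab, k)
                    dc <- vapply(others, function(o) {
                        oc <- maskCentroid(lab, o)
                        sum((cen - oc)^2)
                    }, numeric(1))
                    lab[lab == others[which.min(dc)]] <- k
                }
            }
            if (u[3] < spec@splitProb) {
                idx <- which(lab == k)
                if (length(idx) >= 2L) {
                    x <- (idx - 1L) %/% H; y <- (idx - 1L) %% H
                    th <- runif(1, 0, pi)
                    side <- (x - mean(x)) * cos(th) +
                            (y - mean(y)) * sin(th) > 0
                    if (any(side) && any(!side)) {
                        lab[idx[side]] <- nextId
                        nextId <- nextId + 1L
                    }
                }
            }
            if (spec@boundaryRadius > 0 && any(lab == k)) {
                m <- matrix(0, H, W); m[lab == k] <- 1
                brush <- EBImage::makeBrush(2 * spec@boundaryRadius + 1,
                                            shape = "disc")
                m2 <- if (runif(1) < 0.5) EBImage::erode(m, brush)
                      else EBImage::dilate(m, brush)
                lab[lab == k] <- 0L
                lab[m2 > 0.5 & bundle@labels > 0L] <- k
            }
        }
    })
    initialize(bundle, labels = lab)
}

## Internal: centroid (x, y) of a mask id in a label raster.
maskCentroid <- function(lab, k) {
    idx <- which(lab == k)
    H <- nrow(lab)
    c(mean((idx - 1L) %/% H), mean((idx - 1L) %% H))
}
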