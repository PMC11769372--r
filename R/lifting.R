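## Transfer of 2D mask labels into 3D per view, with depth-consistency
## gating, backside rejection and viewpoint/depth confidence scoring.

#' Per-point confidence score
#'
#' \eqn{s = \lambda \max(0, -\cos\phi) + (1-\lambda) d_n}: a weighted blend
#' of view-angle quality (frontal views of a surface are most reliable) and
#' normalized imaging depth \eqn{d_n \in [0,1]}.  With
#' \code{distanceMode = "proximity"} the depth term is \eqn{(1-\lambda)(1-d_n)}
#' so that closer points score higher; the literal mode keeps the depth term
#' as printed in the score definition.
#'
#' @param cosphi cosine(s) of the viewing-ray/normal angle, from
#'   [viewAngleCos].
#' @param dn normalized depth(s) in [0, 1].
#' @param lambda weight in (0, 1).
#' @param distanceMode "literal" or "proximity".
#' @return Confidence score(s) in [0, 1].
#' @examples
#' confidenceScore(-1, 0.5, lambda = 0.9)  # 0.95
#' @export
confidenceScore <- function(cosphi, dn, lambda = 0.9,
                            distanceMode = c("literal", "proximity")) {
    if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
    distanceMode <- match.arg(distanceMode)
    dterm <- if (distanceMode == "literal") dn else 1 - dn
    lambda * pmax(0, -cosphi) + (1 - lambda) * dterm
}

#' Lift one view's 2D masks onto the cloud
#'
#' Projects every cloud point into the view and inherits the mask label of
#' the pixel it lands on, guarded by three rejections: no hit (behind the
#' camera, outside the raster, or no depth data at the pixel), a
#' depth-consistency gate \eqn{|e| \ge} \code{eThreshold} (the view-frustum
#' ambiguity: a pixel corresponds to a whole ray, so only points at the
#' imaged surface depth may inherit its label), and a backside test
#' (\eqn{\cos\phi \ge 0}: a segmentation of a surface seen edge-on or from
#' behind is disregarded).  Surviving points get the pixel's label and a
#' [confidenceScore] with per-view min-max normalized depth.
#'
#' @param cloud a [PointCloud-class].
#' @param view a [ViewBundle-class].
#' @param config a [FusionConfig-class].
#' @return A [ViewLabeling-class] over the cloud.
#' @export
liftView <- function(cloud, view, config = FusionConfig()) {
    n <- nPoints(cloud)
    pr <- projectPoints(coords(cloud), view@camera, view@pose)
    labels <- rep(-1L, n)
    conf <- numeric(n)

    cand <- which(pr$hit)
    if (length(cand)) {
        ui <- round(pr$u[cand]); vi <- round(pr$v[cand])
        pix <- cbind(vi + 1L, ui + 1L)
        d <- view@depth[pix]
        e <- (d - pr$zc[cand]) / d
        ok <- !is.na(e) & abs(e) < config@eThreshold
        cand <- cand[ok]; pix <- pix[ok, , drop = FALSE]; d <- d[ok]
    }
    if (length(cand)) {
        nrm <- cbind(view@normal[, , 1][pix], view@normal[, , 2][pix],
                     view@normal[, , 3][pix])
        C <- cameraCenter(view@pose)
        cosphi <- viewAngleCos(coords(cloud)[cand, , drop = FALSE], nrm, C)
        lab <- view@labels[pix]
        ok <- cosphi < 0 & lab > 0L
        cand <- cand[ok]
        if (length(cand)) {
            dv <- view@depth[!is.na(view@depth)]
            rng <- range(dv)
            dn <- if (diff(rng) > 0) (d[ok] - rng[1]) / diff(rng)
                  else rep(0.5, length(cand))
            dn <- pmin(1, pmax(0, dn))
            labels[cand] <- lab[ok]
            conf[cand] <- confidenceScore(cosphi[ok], dn, config@lambda,
                                          config@distanceMode)
        }
    }
    ViewLabeling(view@viewId, labels, conf)
}

#' Lift all views of a scene
#'
#' @param cloud a [PointCloud-class].
#' @param views list of [ViewBundle-class] objects.
#' @param config a [FusionConfig-class].
#' @param prefilter if TRUE, apply [prefilterGroups] to every lifted
#'   labeling (removes per-group 3D outliers at the cost of recall;
#'   default FALSE).
#' @param ... passed to [prefilterGroups].
#' @return List of [ViewLabeling-class] objects in view order.
#' @export
liftAllViews <- function(cloud, views, config = FusionConfig(),
                         prefilter = FALSE, ...) {
    lapply(views, function(v) {
        vl <- liftView(cloud, v, config)
        if (prefilter) prefilterGroups(vl, cloud, ...) else vl
    })
}

## Internal: mean distance to the k nearest neighbours for each row of a
## coordinate matrix.  Exact O(n^2) distances, computed blockwise so memory
## stays flat for clouds of a few tens of thousands of points.
knnMeanDist <- function(xyz, k, block = 512L) {
    n <- nrow(xyz)
    k <- min(k, n - 1L)
    if (k < 1L) return(rep(0, n))
    sq <- rowSums(xyz^2)
    out <- numeric(n)
    for (s in seq(1L, n, by = block)) {
        e <- min(s + block - 1L, n)
        d2 <- outer(sq[s:e], sq, "+") -
            2 * xyz[s:e, , drop = FALSE] %*% t(xyz)
        d2[d2 < 0] <- 0
        ## self-distance is 0, so the k nearest neighbours are the k+1
        ## smallest entries minus the self term
        out[s:e] <- apply(d2, 1L, function(r)
            sum(sqrt(sort(r, partial = k + 1L)[seq_len(k + 1L)])) / k)
    }
    out
}

#' Statistical pre-filtering of lifted groups
#'
#' Erroneously lifted points tend to be spatially isolated from the leaf
#' surface their group occupies.  Per label group, points whose mean
#' k-nearest-neighbour distance exceeds the group mean by more than
#' \code{stdMult} standard deviations are unassigned (label -1, confidence
#' 0); groups that end up smaller than \code{minGroupSize} are dissolved
#' entirely.
#'
#' @param labeling a [ViewLabeling-class].
#' @param cloud the [PointCloud-class] the labeling indexes.
#' @param k neighbours used for the mean-distance test (default 10).
#' @param stdMult standard-deviation multiplier (default 2).
#' @param minGroupSize minimum surviving group size (default 5).
#' @return The filtered [ViewLabeling-class].
#' @export
prefilterGroups <- function(labeling, cloud, k = 10L, stdMult = 2,
                            minGroupSize = 5L) {
    labels <- labeling@labels
    conf <- labeling@conf
    for (g in unique(labels[labels >= 0L])) {
        idx <- which(labels == g)
        if (length(idx) < minGroupSize) {
            labels[idx] <- -1L; conf[idx] <- 0
            next
        }
        md <- knnMeanDist(coords(cloud)[idx, , drop = FALSE], k)
        s <- sd(md)
        if (is.na(s) || s == 0) next
        out <- md > mean(md) + stdMult * s
        labels[idx[out]] <- -1L; conf[idx[out]] <- 0
        if (sum(!out) < minGroupSize) {
            labels[idx] <- -1L; conf[idx] <- 0
        }
    }
    ViewLabeling(labeling@viewId, labels, conf)
}
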