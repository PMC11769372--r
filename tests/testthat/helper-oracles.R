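# Independent oracles the implementation is checked against.  These are
# deliberately naive (full homogeneous products, exhaustive loops over
# points and group pairs) and share no code with the package internals.

# Full 3x4 homogeneous projection: x = K [R|t] p_h, then divide by depth.
oracleProject <- function(p, fx, fy, cx, cy, R, t) {
    K <- matrix(c(fx, 0, cx, 0, fy, cy, 0, 0, 1), 3, 3, byrow = TRUE)
    P <- K %*% cbind(R, t)
    x <- P %*% c(p, 1)
    c(u = x[1] / x[3], v = x[2] / x[3], zc = x[3])
}

# Random rotation via QR of a Gaussian matrix.
randomRotation <- function() {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
}

# Exhaustive point/group-pair evaluation of a labeling against ground
# truth: greedy descending-IoU one-to-one matching, point counts, mIoU.
oracleEval <- function(pred, gt) {
    pid <- sort(unique(pred[pred >= 0]))
    gid <- sort(unique(gt[gt >= 0]))
    ious <- matrix(0, length(pid), length(gid))
    for (i in seq_along(pid)) for (j in seq_along(gid)) {
        a <- pred == pid[i]; b <- gt == gid[j]
        ious[i, j] <- sum(a & b) / sum(a | b)
    }
    pairs <- NULL
    M <- ious
    while (length(M) && any(M > 0)) {
        ij <- which(M == max(M), arr.ind = TRUE)
        # deterministic tie-break: smallest pred label, then gt label
        ij <- ij[order(pid[ij[, 1]], gid[ij[, 2]]), , drop = FALSE][1, ]
        pairs <- rbind(pairs, c(pid[ij[1]], gid[ij[2]], M[ij[1], ij[2]]))
        M[ij[1], ] <- 0; M[, ij[2]] <- 0
    }
    tp <- 0
    if (!is.null(pairs)) for (r in seq_len(nrow(pairs)))
        tp <- tp + sum(pred == pairs[r, 1] & gt == pairs[r, 2])
    list(tp = tp, fp = sum(pred >= 0) - tp, fn = sum(gt >= 0) - tp,
         miou = if (length(gid)) sum(if (is.null(pairs)) 0 else pairs[, 3]) /
             length(gid) else 0,
         pairs = pairs)
}

# Average precision by direct precision-recall enumeration: rank the
# predicted groups by score, claim the best still-free gt group when its
# IoU reaches the threshold, and sum the PR staircase.
oracleAP <- function(pred, gt, scores, thr) {
    pid <- sort(unique(pred[pred >= 0]))
    gid <- sort(unique(gt[gt >= 0]))
    if (!length(pid)) return(0)
    sc <- scores[as.character(pid)]
    sc[is.na(sc)] <- 0
    ord <- pid[order(-sc, pid)]
    free <- gid
    tp <- logical(length(ord))
    for (i in seq_along(ord)) {
        if (!length(free)) break
        iou <- sapply(free, function(g) {
            a <- pred == ord[i]; b <- gt == g
            sum(a & b) / sum(a | b)
        })
        best <- which.max(iou)
        if (iou[best] >= thr) { tp[i] <- TRUE; free <- free[-best] }
    }
    ap <- 0; rPrev <- 0
    for (i in seq_along(ord)) {
        p <- sum(tp[1:i]) / i
        r <- sum(tp[1:i]) / length(gid)
        ap <- ap + p * (r - rPrev)
        rPrev <- r
    }
    ap
}

# Points on a 3D circle in a tilted plane, with optional Gaussian noise and
# uniform box outliers.
circleFixture <- function(n = 500, radius = 5, center = c(1, -2, 3),
                          normal = c(1, 1, 2), noiseSd = 0,
                          outlierFrac = 0, seed = 99) {
    normal <- normal / sqrt(sum(normal^2))
    e1 <- c(normal[2], -normal[1], 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
            normal[3] * e1[1] - normal[1] * e1[3],
            normal[1] * e1[2] - normal[2] * e1[1])
    withr::with_seed(seed, {
        th <- runif(n, 0, 2 * pi)
        pts <- t(sapply(th, function(a)
            center + radius * cos(a) * e1 + radius * sin(a) * e2))
        if (noiseSd > 0) pts <- pts + matrix(rnorm(3 * n, 0, noiseSd), n, 3)
        nOut <- round(outlierFrac * n)
        if (nOut > 0) {
            idx <- sample.int(n, nOut)
            pts[idx, ] <- matrix(runif(3 * nOut, -10, 10), nOut, 3)
        }
        pts
    })
}

# Shared small rendered fixture (cached across tests in one file run).
.fixtureCache <- new.env(parent = emptyenv())
smallSceneFixture <- function() {
    if (is.null(.fixtureCache$small)) {
        scene <- generateScene(5, 200, seed = 3)
        cam <- CameraModel(600, width = 320, height = 240)
        poses <- cameraRing(8, radius = 4, center = c(0, 0, 0.5))
        views <- renderViews(scene, cam, poses)
        .fixtureCache$small <- list(scene = scene, cam = cam,
                                    poses = poses, views = views)
    }
    .fixtureCache$small
}

# Draw simple shapes as mask index vectors on an H x W raster.
drawDisc <- function(cx, cy, r, W, H) {
    g <- expand.grid(x = 0:(W - 1), y = 0:(H - 1))
    keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
    g$x[keep] * H + g$y[keep] + 1L
}
drawRect <- function(x0, y0, w, h, W, H) {
    g <- expand.grid(x = x0:(x0 + w - 1L), y = y0:(y0 + h - 1L))
    g$x * H + g$y + 1L
}
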