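## Three-stage post-filter reducing a raw automatic mask set to leaf-only
## masks: saturation filter (drop background/pot), overlap filter (drop
## coarse duplicates, keep the finer granularity), shape filter (drop
## elongated stem-like masks).

#' Convert a MaskSet to/from an indexed label raster
#'
#' The indexed dialect stores 0 for background and k for mask k.
#'
#' @param raster H x W integer matrix.
#' @param viewId view identifier for the resulting set.
#' @return `maskSetFromRaster`: a [MaskSet-class]; `rasterFromMaskSet`: an
#'   H x W integer matrix.
#' @export
maskSetFromRaster <- function(raster, viewId = 0L) {
    ids <- sort(setdiff(unique(as.vector(raster)), 0L))
    masks <- lapply(ids, function(k) which(raster == k))
    names(masks) <- as.character(ids)
    MaskSet(viewId, masks, width = ncol(raster), height = nrow(raster))
}

#' @param maskSet a [MaskSet-class].
#' @rdname maskSetFromRaster
#' @export
rasterFromMaskSet <- function(maskSet) {
    r <- matrix(0L, maskSet@height, maskSet@width)
    ## descending area so that, if any residual overlap exists, the smaller
    ## (finer) mask wins the shared pixels
    ord <- order(-vapply(maskSet@masks, length, 1L))
    for (i in ord) r[maskSet@masks[[i]]] <- as.integer(names(maskSet@masks)[i])
    r
}

## Internal: 8-bit HSV-style saturation of an RGB raster in [0,1] or [0,255].
## S = 255 * (max - min) / max, 0 where max = 0 (the convention of the
## mainstream image libraries, so a threshold like S > 40 is meaningful).
saturation255 <- function(rgb) {
    if (max(rgb) <= 1) rgb <- rgb * 255
    mx <- pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3])
    mn <- pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3])
    s <- ifelse(mx > 0, 255 * (mx - mn) / mx, 0)
    matrix(s, dim(rgb)[1], dim(rgb)[2])
}

#' Saturation filter
#'
#' Retains exactly the masks whose mean 8-bit HSV saturation over their
#' pixels exceeds \code{sMin}.  In a controlled studio the background is
#' low-saturation white/gray, so leaf masks pass and background, pot and
#' paper masks are dropped.
#'
#' @param maskSet a [MaskSet-class].
#' @param image H x W x 3 RGB array (range [0, 1] or [0, 255]).
#' @param sMin saturation threshold on the 0-255 scale (default 40).
#' @return The filtered [MaskSet-class].
#' @export
saturationFilter <- function(maskSet, image, sMin = 40) {
    stopifnot(dim(image)[1] == maskSet@height,
              dim(image)[2] == maskSet@width)
    if (sMin < 0 || sMin > 255) stop("sMin must be on the 8-bit [0,255] scale")
    s <- saturation255(image)
    keep <- vapply(maskSet@masks, function(m) {
        if (length(m) == 0L) { warning("empty mask excluded"); return(FALSE) }
        mean(s[m]) > sMin
    }, logical(1))
    MaskSet(maskSet@viewId, maskSet@masks[keep],
            maskSet@width, maskSet@height)
}

#' Overlap filter
#'
#' For every pair of masks with IoU at or above \code{iouMin} the
#' larger-area mask is removed (the finer granularity is retained; on equal
#' areas the lower mask id wins).  Residual pixel overlaps between surviving
#' masks (part-whole relations below the IoU threshold) are resolved by
#' assigning shared pixels to the smaller mask.  The output is pixel-disjoint.
#'
#' @param maskSet a [MaskSet-class].
#' @param iouMin IoU threshold in (0, 1] (default 0.5).
#' @return The filtered, pixel-disjoint [MaskSet-class].
#' @export
overlapFilter <- function(maskSet, iouMin = 0.5) {
    stopifnot(iouMin > 0, iouMin <= 1)
    masks <- maskSet@masks
    k <- length(masks)
    if (k >= 2L) {
        areas <- vapply(masks, length, 1L)
        drop <- logical(k)
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
            inter <- length(intersect(masks[[i]], masks[[j]]))
            if (inter == 0L) next
            iou <- inter / (areas[i] + areas[j] - inter)
            if (iou >= iouMin) {
                ## remove the coarser (larger) mask; ties keep the lower id
                if (areas[i] > areas[j]) drop[i] <- TRUE
                else if (areas[j] > areas[i]) drop[j] <- TRUE
                else drop[c(i, j)[which.max(as.integer(names(masks)[c(i, j)]))]] <- TRUE
            }
        }
        masks <- masks[!drop]
    }
    ## residual overlap: smaller masks claim shared pixels first
    if (length(masks) >= 2L) {
        ord <- order(vapply(masks, length, 1L),
                     as.integer(names(masks)))
        claimed <- integer(0)
        for (i in ord) {
            masks[[i]] <- setdiff(masks[[i]], claimed)
            claimed <- c(claimed, masks[[i]])
        }
        masks <- masks[vapply(masks, length, 1L) > 0L]
    }
    MaskSet(maskSet@viewId, masks, maskSet@width, maskSet@height)
}

## Internal: exact minimum enclosing circle (move-to-front Welzl, iterative
## over boundary support of size <= 3) of 2D points given as an n x 2 matrix.
minEnclosingCircle <- function(pts) {
    circ2 <- function(a, b) {
        c((a + b) / 2, sqrt(sum((a - b)^2)) / 2)
    }
    circ3 <- function(a, b, c3) {
        ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]
        cx <- c3[1]; cy <- c3[2]
        d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(d) < 1e-12) return(NULL)  # collinear
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
        c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
    }
    inC <- function(circle, p, eps = 1e-9)
        sqrt(sum((p - circle[1:2])^2)) <= circle[3] * (1 + eps) + eps
    trivial <- function(supp) {
        n <- nrow(supp)
        if (n == 0L) return(c(0, 0, 0))
        if (n == 1L) return(c(supp[1, ], 0))
        if (n == 2L) return(circ2(supp[1, ], supp[2, ]))
        for (i in 1:2) for (j in (i + 1):3) {
            cc <- circ2(supp[i, ], supp[j, ])
            k <- setdiff(1:3, c(i, j))
            if (inC(cc, supp[k, ])) return(cc)
        }
        cc <- circ3(supp[1, ], supp[2, ], supp[3, ])
        if (is.null(cc)) {  # collinear support: span of the extremes
            d12 <- sum((supp[1, ] - supp[2, ])^2)
            d13 <- sum((supp[1, ] - supp[3, ])^2)
            d23 <- sum((supp[2, ] - supp[3, ])^2)
            m <- which.max(c(d12, d13, d23))
            pr <- list(c(1, 2), c(1, 3), c(2, 3))[[m]]
            return(circ2(supp[pr[1], ], supp[pr[2], ]))
        }
        cc
    }
    n <- nrow(pts)
    ## deterministic scrambled order (fixed multiplier hash) for expected
    ## linear behavior without touching the global RNG
    ord <- order((seq_len(n) * 2654435761) %% (n + 1L), seq_len(n))
    pts <- pts[ord, , drop = FALSE]
    circle <- c(0, 0, -1)
    for (i in seq_len(n)) {
        if (circle[3] >= 0 && inC(circle, pts[i, ])) next
        circle <- c(pts[i, ], 0)
        for (j in seq_len(i - 1L)) {
            if (inC(circle, pts[j, ])) next
            circle <- circ2(pts[i, ], pts[j, ])
            for (k in seq_len(j - 1L)) {
                if (inC(circle, pts[k, ])) next
                cc <- circ3(pts[i, ], pts[j, ], pts[k, ])
                circle <- if (is.null(cc))
                    trivial(rbind(pts[i, ], pts[j, ], pts[k, ])) else cc
            }
        }
    }
    list(center = circle[1:2], radius = circle[3])
}

## Internal: boundary pixels (those with a 4-neighbor outside the mask) as
## (x, y) coordinates; boundary suffices for the enclosing circle and keeps
## the cost linear in contour length.
maskBoundaryXY <- function(idx, width, height) {
    r <- matrix(FALSE, height, width)
    r[idx] <- TRUE
    up <- rbind(r[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, r[-height, , drop = FALSE])
    lf <- cbind(r[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, r[, -width, drop = FALSE])
    b <- r & !(up & dn & lf & rt)
    w <- which(b)
    cbind(x = (w - 1L) %/% height, y = (w - 1L) %% height)
}

#' Shape ratio of a mask
#'
#' Ratio of the area of the minimum enclosing circle of the mask's pixels to
#' the mask's pixel area.  Full shapes (discs) score near 1, squares near
#' \eqn{\pi/2}, and elongated stem-like bars score far above; degenerate
#' masks of fewer than 3 pixels return \code{Inf}.
#'
#' @param idx integer vector of 1-based linear pixel indices (column-major).
#' @param width,height raster size.
#' @return The (unitless) area ratio.
#' @export
shapeRatio <- function(idx, width, height) {
    if (length(idx) < 3L) return(Inf)
    xy <- maskBoundaryXY(idx, width, height)
    mec <- minEnclosingCircle(xy)
    unname(pi * mec$radius^2 / length(idx))
}

#' Shape filter
#'
#' Retains masks whose [shapeRatio] is at most \code{rMax}.  Leaves are
#' "full" (ratio near 1-2), stems are elongated (ratio far above), so a
#' single threshold separates them.
#'
#' @param maskSet a [MaskSet-class].
#' @param rMax maximum allowed ratio, > 1 (default 4).
#' @return The filtered [MaskSet-class].
#' @export
shapeFilter <- function(maskSet, rMax = 4) {
    stopifnot(rMax > 1)
    keep <- vapply(maskSet@masks, function(m)
        shapeRatio(m, maskSet@width, maskSet@height) <= rMax, logical(1))
    MaskSet(maskSet@viewId, maskSet@masks[keep],
            maskSet@width, maskSet@height)
}

#' Full three-stage mask filter chain
#'
#' Saturation, then overlap, then shape, in that order (saturation first so
#' the quadratic overlap stage sees few masks; shape last so that part-whole
#' resolution has already sharpened mask outlines).  The chain is idempotent.
#'
#' @param maskSet a [MaskSet-class] of raw automatic masks.
#' @param image H x W x 3 RGB array for the saturation stage.
#' @param sMin saturation threshold, 8-bit scale (default 40).
#' @param iouMin duplicate-overlap IoU threshold (default 0.5).
#' @param rMax maximum shape ratio (default 4).
#' @return The leaf-only, pixel-disjoint [MaskSet-class].
#' @export
filterMasks <- function(maskSet, image, sMin = 40, iouMin = 0.5, rMax = 4) {
    shapeFilter(overlapFilter(saturationFilter(maskSet, image, sMin),
                              iouMin), rMax)
}
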