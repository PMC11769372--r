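## Pinhole projection, depth-consistency gating and view-angle terms.
## Pixel convention: 0-based, pixel centers on integer coordinates; raster
## lookups round (u, v) to the nearest integer.

#' Project world points into a view
#'
#' Applies the pinhole model: \eqn{x_c = R p + t}, \eqn{Z_c = x_{c,z}},
#' \eqn{u = f_x x_{c,x}/Z_c + c_x}, \eqn{v = f_y x_{c,y}/Z_c + c_y}.
#' Points behind the camera (\eqn{Z_c \le 0}) or whose rounded pixel falls
#' outside the raster get no hit rather than being clamped: the projective
#' division is meaningless there.
#'
#' @param p numeric length-3 vector or N x 3 matrix of world coordinates.
#' @param camera a [CameraModel-class].
#' @param pose a [Pose-class] (world to camera).
#' @return A data.frame with columns \code{u}, \code{v}, \code{zc} and
#'   logical \code{hit}; \code{u}/\code{v}/\code{zc} are NA where there is
#'   no valid hit (behind the camera), and \code{hit} is FALSE also for
#'   projections that round outside the raster.
#' @examples
#' cam <- CameraModel(1, 1, cx = 0, cy = 0, width = 10, height = 10)
#' projectPoints(c(1, 2, 2), cam, Pose(diag(3), c(0, 0, 0)))
#' @export
projectPoints <- function(p, camera, pose) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 3L, byrow = TRUE)
    if (!all(is.finite(p))) stop("non-finite point coordinates")
    xc <- p %*% t(pose@rotation)
    xc <- sweep(xc, 2L, pose@translation, "+")
    zc <- xc[, 3L]
    front <- zc > 0
    u <- ifelse(front, camera@fx * xc[, 1L] / zc + camera@cx, NA_real_)
    v <- ifelse(front, camera@fy * xc[, 2L] / zc + camera@cy, NA_real_)
    ui <- round(u); vi <- round(v)
    inside <- front & ui >= 0 & ui <= camera@width - 1L &
        vi >= 0 & vi <= camera@height - 1L
    data.frame(u = u, v = v, zc = ifelse(front, zc, NA_real_),
               hit = !is.na(inside) & inside)
}

#' Relative depth-consistency error
#'
#' \eqn{e(u,v) = (d(u,v) - Z_c) / d(u,v)} against a reference depth map.
#' A 2D pixel corresponds to a whole viewing ray in 3D (the view frustum
#' ambiguity); gating on \eqn{|e|} excludes points whose camera-frame depth
#' disagrees with the surface actually imaged at that pixel.
#'
#' @param u,v continuous pixel coordinates (0-based; rounded for lookup).
#' @param zc camera-frame depth(s) of the queried point(s).
#' @param depth H x W depth matrix in world units, NA = no data.
#' @return Numeric vector of relative errors; NA where the depth map has no
#'   data at the pixel (the gate must treat that as a distinct failure).
#' @examples
#' depthError(0, 0, 1.99, matrix(2, 1, 1))
#' @export
depthError <- function(u, v, zc, depth) {
    ui <- round(u); vi <- round(v)
    H <- nrow(depth); W <- ncol(depth)
    ok <- ui >= 0 & ui <= W - 1L & vi >= 0 & vi <= H - 1L
    d <- rep(NA_real_, length(u))
    d[ok] <- depth[cbind(vi[ok] + 1L, ui[ok] + 1L)]
    (d - zc) / d
}

#' Cosine of the angle between viewing ray and surface normal
#'
#' With viewpoint vector \eqn{v = p - C} (camera center to point) and unit
#' surface normal \eqn{n}, returns \eqn{\cos\phi = v \cdot n / |v|}.
#' Front-facing surfaces (normal toward the camera) give negative values;
#' non-negative values mean the surface is seen edge-on or from the back,
#' where a 2D segmentation of it is meaningless.
#'
#' @param p length-3 vector or N x 3 matrix of world points.
#' @param n length-3 unit normal or N x 3 matrix of unit normals.
#' @param center length-3 camera center in world coordinates.
#' @return Numeric vector of cosines in [-1, 1].
#' @examples
#' viewAngleCos(c(0, 0, 0), c(0, 0, -1), c(0, 0, -1))  # frontal: -1
#' @export
viewAngleCos <- function(p, n, center) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 3L, byrow = TRUE)
    if (is.null(dim(n))) n <- matrix(n, ncol = 3L, byrow = TRUE)
    if (nrow(n) == 1L && nrow(p) > 1L)
        n <- n[rep(1L, nrow(p)), , drop = FALSE]
    v <- sweep(p, 2L, center, "-")
    nv <- sqrt(rowSums(v^2))
    if (any(nv == 0)) stop("point coincides with the camera center")
    cosphi <- rowSums(v * n) / nv
    pmin(1, pmax(-1, cosphi))
}

## Internal: rotation matrix from unit quaternion (w, x, y, z),
## COLMAP convention (world -> camera).
quatToRot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3L, byrow = TRUE)
}

## Internal: unit quaternion (w, x, y, z) from rotation matrix.
rotToQuat <- function(R) {
    tr <- R[1, 1] + R[2, 2] + R[3, 3]
    if (tr > 0) {
        s <- sqrt(tr + 1) * 2
        q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
               (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
    } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
        s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
        q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
               (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (R[2, 2] > R[3, 3]) {
        s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
        q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
               0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
        s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
        q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
               (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
    if (q[1] < 0) q <- -q
    q / sqrt(sum(q^2))
}
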