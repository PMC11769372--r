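#' Accessors
#'
#' Small accessor generics for the package's data classes, so user code never
#' touches slots directly.
#'
#' @param object an object of one of the package classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname accessors
#' @export
setMethod("coords", "PointCloud", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setMethod("nPoints", "PointCloud", function(object) nrow(object@coords))

#' @rdname accessors
#' @export
setGeneric("pointColors", function(object) standardGeneric("pointColors"))

#' @rdname accessors
#' @export
setMethod("pointColors", "PointCloud", function(object) object@rgb)

#' @rdname accessors
#' @export
setGeneric("pointNormals", function(object) standardGeneric("pointNormals"))

#' @rdname accessors
#' @export
setMethod("pointNormals", "PointCloud", function(object) object@normals)

#' @rdname accessors
#' @export
setGeneric("gtLabels", function(object) standardGeneric("gtLabels"))

#' @rdname accessors
#' @export
setMethod("gtLabels", "PointCloud", function(object) object@gtLabels)

#' @rdname accessors
#' @export
setMethod("gtLabels", "SyntheticScene", function(object)
    object@cloud@gtLabels)

#' @rdname accessors
#' @export
setGeneric("instanceLabels", function(object) standardGeneric("instanceLabels"))

#' @rdname accessors
#' @export
setMethod("instanceLabels", "ViewLabeling", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("instanceLabels", "FusionState", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("confidence", function(object) standardGeneric("confidence"))

#' @rdname accessors
#' @export
setMethod("confidence", "ViewLabeling", function(object) object@conf)

#' @rdname accessors
#' @export
setMethod("confidence", "FusionState", function(object) object@conf)

#' Camera center in world coordinates
#'
#' The optical center \eqn{C = -R^\top t} of a pose.
#'
#' @param pose a [Pose-class].
#' @return Length-3 numeric vector.
#' @examples
#' cameraCenter(Pose(diag(3), c(0, 0, -4)))
#' @export
cameraCenter <- function(pose) {
    as.numeric(-crossprod(pose@rotation, pose@translation))
}

#' Subset a point cloud by point index
#'
#' @param cloud a [PointCloud-class].
#' @param idx integer or logical index over the points.
#' @return The subsetted [PointCloud-class].
#' @export
subsetCloud <- function(cloud, idx) {
    PointCloud(cloud@coords[idx, , drop = FALSE],
               rgb = if (!is.null(cloud@rgb)) cloud@rgb[idx, , drop = FALSE],
               normals = if (!is.null(cloud@normals))
                   cloud@normals[idx, , drop = FALSE],
               gtLabels = if (!is.null(cloud@gtLabels)) cloud@gtLabels[idx])
}
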