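## On-disk dialects: ASCII PLY clouds, COLMAP text camera models, raw
## float32 rasters with a JSON sidecar, indexed-PNG mask rasters, and JSON
## labelings/calibrations/metrics.

#' Read / write an ASCII PLY point cloud
#'
#' Supports the vertex properties this pipeline uses: \code{x y z}, optional
#' \code{red green blue} (uchar), optional integer \code{label} (ground
#' truth or predicted instance), optional \code{nx ny nz}.  Coordinates are
#' written at full double precision; round-trips are exact within the
#' printed precision.
#'
#' @param path file path.
#' @return A [PointCloud-class].
#' @export
readPLY <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    con <- file(path, "r")
    on.exit(close(con))
    nVert <- 0L; props <- character(0); inVertex <- FALSE
    repeat {
        line <- readLines(con, 1L)
        if (!length(line)) stop("malformed PLY header")
        tok <- strsplit(trimws(line), "\\s+")[[1]]
        if (tok[1] == "element") {
            inVertex <- tok[2] == "vertex"
            if (inVertex) nVert <- as.integer(tok[3])
        } else if (tok[1] == "property" && inVertex) {
            props <- c(props, tok[length(tok)])
        } else if (tok[1] == "format" && tok[2] != "ascii") {
            stop("only ASCII PLY is supported")
        } else if (tok[1] == "end_header") break
    }
    dat <- matrix(scan(con, what = numeric(), n = nVert * length(props),
                       quiet = TRUE), nrow = nVert, byrow = TRUE)
    colnames(dat) <- props
    col <- function(nm) unname(dat[, nm, drop = FALSE])
    PointCloud(col(c("x", "y", "z")),
               rgb = if (all(c("red", "green", "blue") %in% props))
                   col(c("red", "green", "blue")),
               normals = if (all(c("nx", "ny", "nz") %in% props))
                   col(c("nx", "ny", "nz")),
               gtLabels = if ("label" %in% props) unname(dat[, "label"]))
}

#' @param cloud a [PointCloud-class].
#' @param labels optional integer vector written as the \code{label}
#'   property (defaults to the cloud's gtLabels when present).
#' @rdname readPLY
#' @export
writePLY <- function(cloud, path, labels = cloud@gtLabels) {
    n <- nPoints(cloud)
    props <- c("property double x", "property double y", "property double z")
    cols <- list(format(coords(cloud)[, 1], digits = 17),
                 format(coords(cloud)[, 2], digits = 17),
                 format(coords(cloud)[, 3], digits = 17))
    if (!is.null(cloud@rgb)) {
        props <- c(props, paste("property uchar", c("red", "green", "blue")))
        cols <- c(cols, list(cloud@rgb[, 1], cloud@rgb[, 2], cloud@rgb[, 3]))
    }
    if (!is.null(labels)) {
        props <- c(props, "property int label")
        cols <- c(cols, list(as.integer(labels)))
    }
    if (!is.null(cloud@normals)) {
        props <- c(props, paste("property double", c("nx", "ny", "nz")))
        cols <- c(cols, list(format(cloud@normals[, 1], digits = 17),
                             format(cloud@normals[, 2], digits = 17),
                             format(cloud@normals[, 3], digits = 17)))
    }
    header <- c("ply", "format ascii 1.0",
                paste("element vertex", n), props, "end_header")
    body <- do.call(paste, cols)
    writeLines(c(header, body), path)
    invisible(path)
}

#' Export a fused segmentation as a colored PLY
#'
#' One random (seeded) color per label; unassigned points are dark gray.
#'
#' @param cloud a [PointCloud-class].
#' @param labels per-point integer labels (-1 = unassigned).
#' @param path output file.
#' @param seed color permutation seed.
#' @return The path, invisibly.
#' @export
writeColoredPLY <- function(cloud, labels, path, seed = 1L) {
    ids <- sort(unique(labels[labels >= 0L]))
    cols <- withr::with_seed(seed,
        matrix(sample.int(256, 3L * max(length(ids), 1L),
                          replace = TRUE) - 1L, ncol = 3L))
    rgb <- matrix(60L, length(labels), 3L)
    for (i in seq_along(ids))
        rgb[labels == ids[i], ] <- rep(cols[i, ], each = sum(labels == ids[i]))
    writePLY(PointCloud(coords(cloud), rgb = rgb), path, labels = labels)
}

#' Read / write a COLMAP text camera model
#'
#' \code{cameras.txt} (PINHOLE entries: fx fy cx cy) and \code{images.txt}
#' (per image: quaternion qw qx qy qz, translation, camera id, name;
#' followed by the 2D-point line, written empty).  The quaternion maps
#' world to camera, as COLMAP defines it.
#'
#' @param dir directory containing/receiving the two files.
#' @return A list with \code{cameras} (named list of
#'   [CameraModel-class]) and \code{images} (data-frame-free list with
#'   \code{name}, \code{cameraId}, \code{pose} per image, in id order).
#' @export
readColmapModel <- function(dir) {
    camLines <- grep("^\\s*(#|$)", readLines(file.path(dir, "cameras.txt")),
                     value = TRUE, invert = TRUE)
    cameras <- list()
    for (ln in camLines) {
        tok <- strsplit(trimws(ln), "\\s+")[[1]]
        if (tok[2] != "PINHOLE")
            stop("only the PINHOLE camera model is supported, got ", tok[2])
        cameras[[tok[1]]] <- CameraModel(
            fx = as.numeric(tok[5]), fy = as.numeric(tok[6]),
            cx = as.numeric(tok[7]), cy = as.numeric(tok[8]),
            width = as.integer(tok[3]), height = as.integer(tok[4]))
    }
    ## keep blank lines: every image record is one pose line followed by a
    ## (possibly empty) 2D-point line
    imgLines <- grep("^\\s*#", readLines(file.path(dir, "images.txt")),
                     value = TRUE, invert = TRUE)
    images <- list()
    i <- 1L
    while (i <= length(imgLines)) {
        if (!nzchar(trimws(imgLines[i]))) { i <- i + 1L; next }
        tok <- strsplit(trimws(imgLines[i]), "\\s+")[[1]]
        q <- as.numeric(tok[2:5]); t <- as.numeric(tok[6:8])
        images[[length(images) + 1L]] <- list(
            imageId = as.integer(tok[1]), name = tok[10],
            cameraId = tok[9], pose = Pose(quatToRot(q), t))
        i <- i + 2L  # skip the points2D line
    }
    images <- images[order(vapply(images, `[[`, 1L, "imageId"))]
    list(cameras = cameras, images = images)
}

#' @param cameras named list of [CameraModel-class] (names = camera ids).
#' @param images list of lists with \code{imageId}, \code{name},
#'   \code{cameraId}, \code{pose}.
#' @rdname readColmapModel
#' @export
writeColmapModel <- function(dir, cameras, images) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    camLines <- c("# Camera list: CAMERA_ID, MODEL, WIDTH, HEIGHT, PARAMS[]")
    for (id in names(cameras)) {
        cm <- cameras[[id]]
        camLines <- c(camLines, sprintf(
            "%s PINHOLE %d %d %.17g %.17g %.17g %.17g",
            id, cm@width, cm@height, cm@fx, cm@fy, cm@cx, cm@cy))
    }
    writeLines(camLines, file.path(dir, "cameras.txt"))
    imgLines <- c("# Image list: IMAGE_ID, QW, QX, QY, QZ, TX, TY, TZ, CAMERA_ID, NAME")
    for (im in images) {
        q <- rotToQuat(im$pose@rotation)
        t <- im$pose@translation
        imgLines <- c(imgLines, sprintf(
            "%d %.17g %.17g %.17g %.17g %.17g %.17g %.17g %s %s",
            im$imageId, q[1], q[2], q[3], q[4], t[1], t[2], t[3],
            im$cameraId, im$name), "")
    }
    writeLines(imgLines, file.path(dir, "images.txt"))
    invisible(dir)
}

#' Read / write float32 raster files
#'
#' The package's raster dialect: raw little-endian float32 values in
#' column-major order with a JSON sidecar \code{<path>.json} holding
#' \code{width}, \code{height} and \code{channels}.  NaN encodes no-data.
#'
#' @param path file path (conventionally \code{.bin}).
#' @return `readRasterBin`: an H x W matrix (1 channel) or H x W x C array.
#' @export
readRasterBin <- function(path) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    vals <- readBin(path, "numeric", size = 4L, endian = "little",
                    n = meta$width * meta$height * meta$channels)
    vals[is.nan(vals)] <- NA_real_
    if (meta$channels == 1L) matrix(vals, meta$height, meta$width)
    else array(vals, c(meta$height, meta$width, meta$channels))
}

#' @param x H x W matrix or H x W x C array.
#' @rdname readRasterBin
#' @export
writeRasterBin <- function(x, path) {
    dims <- dim(x)
    channels <- if (length(dims) == 3L) dims[3] else 1L
    v <- as.vector(x)
    v[is.na(v)] <- NaN
    writeBin(v, path, size = 4L, endian = "little")
    jsonlite::write_json(list(width = dims[2], height = dims[1],
                              channels = channels),
                         paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' Read / write an indexed-PNG mask raster
#'
#' 8-bit grayscale PNG where pixel value k means mask k and 0 background
#' (so at most 255 masks per view, ample for leaf scenes).
#'
#' @param path PNG file path.
#' @return `readMaskPNG`: an H x W integer matrix.
#' @export
readMaskPNG <- function(path) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' @param labels H x W integer matrix (values 0..255).
#' @rdname readMaskPNG
#' @export
writeMaskPNG <- function(labels, path) {
    if (max(labels) > 255L) stop("indexed PNG masks support at most 255 ids")
    png::writePNG(labels / 255, path)
    invisible(path)
}

#' Serialize / read a per-view labeling as JSON
#'
#' \code{\{view_id, labels: [int], conf: [float]\}}; the cloud's point order
#' defines the 0-based indexing.
#'
#' @param path JSON file path.
#' @return `readLabelingJSON`: a [ViewLabeling-class].
#' @export
readLabelingJSON <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    ViewLabeling(x$view_id, x$labels, x$conf)
}

#' @param labeling a [ViewLabeling-class] or [FusionState-class].
#' @rdname readLabelingJSON
#' @export
writeLabelingJSON <- function(labeling, path) {
    x <- if (is(labeling, "FusionState"))
        list(view_id = -1L, labels = labeling@labels, conf = labeling@conf)
    else
        list(view_id = labeling@viewId, labels = labeling@labels,
             conf = labeling@conf)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write / read a full synthetic scene directory
#'
#' The exact dialects the rest of the pipeline reads: \code{cloud.ply}
#' (with ground-truth labels and normals), \code{gt.json},
#' \code{cameras.txt}/\code{images.txt}, per-view \code{depth_NNN.bin} and
#' \code{normal_NNN.bin} float32 rasters, and \code{masks/mask_NNN.png}
#' indexed masks.
#'
#' @param scene a [SyntheticScene-class].
#' @param views list of [ViewBundle-class] from [renderViews].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writeSceneDir <- function(scene, views, dir) {
    dir.create(file.path(dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
    writePLY(scene@cloud, file.path(dir, "cloud.ply"))
    jsonlite::write_json(
        list(n_leaves = scene@nLeaves, seed = scene@seed,
             turntable_center = scene@turntableCenter,
             turntable_radius = scene@turntableRadius,
             gt_labels = scene@cloud@gtLabels),
        file.path(dir, "gt.json"), auto_unbox = TRUE, digits = NA)
    cam <- views[[1]]@camera
    images <- lapply(views, function(v) list(
        imageId = v@viewId, name = sprintf("view_%03d.png", v@viewId),
        cameraId = "1", pose = v@pose))
    writeColmapModel(dir, list(`1` = cam), images)
    for (v in views) {
        writeRasterBin(v@depth, file.path(dir, sprintf("depth_%03d.bin",
                                                       v@viewId)))
        writeRasterBin(v@normal, file.path(dir, sprintf("normal_%03d.bin",
                                                        v@viewId)))
        writeMaskPNG(v@labels, file.path(dir, "masks",
                                         sprintf("mask_%03d.png", v@viewId)))
    }
    invisible(dir)
}

#' @rdname writeSceneDir
#' @return `readSceneDir`: a list with \code{cloud}, \code{gt} (list) and
#'   \code{views} (list of [ViewBundle-class]).
#' @export
readSceneDir <- function(dir) {
    cloud <- readPLY(file.path(dir, "cloud.ply"))
    gt <- jsonlite::read_json(file.path(dir, "gt.json"),
                              simplifyVector = TRUE)
    model <- readColmapModel(dir)
    views <- lapply(model$images, function(im) {
        new("ViewBundle", viewId = im$imageId,
            camera = model$cameras[[im$cameraId]], pose = im$pose,
            depth = readRasterBin(file.path(dir, sprintf("depth_%03d.bin",
                                                         im$imageId))),
            normal = readRasterBin(file.path(dir, sprintf("normal_%03d.bin",
                                                          im$imageId))),
            labels = readMaskPNG(file.path(dir, "masks",
                                           sprintf("mask_%03d.png",
                                                   im$imageId))),
            rgb = NULL, winner = NULL)
    })
    list(cloud = cloud, gt = gt, views = views)
}
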