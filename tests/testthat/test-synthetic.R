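# Scene generator, camera ring, z-buffer renderer and mask corruption.

test_that("scene generation is deterministic and labels are contiguous", {
    s1 <- generateScene(8, 100, seed = 42)
    s2 <- generateScene(8, 100, seed = 42)
    expect_identical(coords(s1@cloud), coords(s2@cloud))
    expect_identical(gtLabels(s1), gtLabels(s2))
    expect_identical(sort(unique(gtLabels(s1))), 0:7)
    s3 <- generateScene(8, 100, seed = 43)
    expect_false(identical(coords(s1@cloud), coords(s3@cloud)))
    # normals are unit length
    expect_equal(rowSums(pointNormals(s1@cloud)^2),
                 rep(1, 800), tolerance = 1e-9)
})

test_that("camera ring spacing and radius follow the turntable geometry", {
    poses <- cameraRing(32, radius = 4, center = c(0, 0, 0.65))
    az <- sapply(poses, function(p) {
        C <- cameraCenter(p)
        atan2(C[2], C[1])
    })
    gaps <- diff(az) %% (2 * pi)
    expect_equal(gaps, rep(11.25 * pi / 180, 31), tolerance = 1e-9)
    for (p in poses)
        expect_equal(sqrt(sum((cameraCenter(p) - c(0, 0, 0.65))^2)), 4,
                     tolerance = 1e-9)
    el <- sapply(poses, function(p) {
        C <- cameraCenter(p) - c(0, 0, 0.65)
        asin(C[3] / sqrt(sum(C^2))) * 180 / pi
    })
    expect_true(all(el >= 30 - 1e-9 & el <= 45 + 1e-9))

    four <- cameraRing(4, radius = 2)
    az4 <- sapply(four, function(p) atan2(cameraCenter(p)[2],
                                          cameraCenter(p)[1]))
    expect_equal(diff(az4) %% (2 * pi), rep(pi / 2, 3), tolerance = 1e-9)
})

test_that("rendered rasters are mutually consistent with the cloud", {
    fx <- smallSceneFixture()
    v <- fx$views[[3]]
    # every rendered pixel stores its winning point's exact depth
    won <- which(!is.na(v@winner))
    pid <- v@winner[won]
    pr <- projectPoints(coords(fx$scene@cloud), v@camera, v@pose)
    expect_identical(v@depth[won], pr$zc[pid])
    # and the winner's label and normal
    expect_identical(as.integer(v@labels[won]),
                     gtLabels(fx$scene)[pid] + 1L)
    expect_identical(v@normal[, , 1][won],
                     pointNormals(fx$scene@cloud)[pid, 1])
    # z-buffer: two stacked surfaces, front owns the contested pixels
    cam <- CameraModel(100, 100, cx = 5, cy = 5, width = 11, height = 11)
    stacked <- PointCloud(rbind(c(0, 0, 1), c(0, 0, 3)),
                          normals = rbind(c(0, 0, -1), c(0, 0, -1)),
                          gtLabels = c(0L, 1L))
    b <- renderView(stacked, cam, Pose(diag(3), c(0, 0, 0)))
    expect_identical(b@labels[6, 6], 1L)
    expect_equal(b@depth[6, 6], 1)
})

test_that("back-projecting rendered depth reprojects onto the same pixel", {
    fx <- smallSceneFixture()
    v <- fx$views[[1]]
    won <- which(!is.na(v@depth))[seq(1, sum(!is.na(v@depth)), by = 97)]
    u <- (won - 1) %/% nrow(v@depth)
    vv <- (won - 1) %% nrow(v@depth)
    d <- v@depth[won]
    K <- v@camera
    xc <- cbind((u - K@cx) / K@fx * d, (vv - K@cy) / K@fy * d, d)
    p <- sweep(xc, 2, v@pose@translation, "-") %*% v@pose@rotation
    pr <- projectPoints(p, K, v@pose)
    expect_equal(round(pr$u), u)
    expect_equal(round(pr$v), vv)
    expect_lt(max(abs(pr$zc - d)), 1e-9)
})

test_that("mask corruption is controlled, seeded, and label-exact", {
    fx <- smallSceneFixture()
    v <- fx$views[[2]]
    # all-zero spec: identity
    expect_identical(corruptMasks(v, CorruptionSpec(seed = 3))@labels,
                     v@labels)
    # full dropout zeroes the raster
    gone <- corruptMasks(v, CorruptionSpec(dropoutProb = 1, seed = 3))
    expect_true(all(gone@labels == 0L))
    # a certain merge reduces the distinct label count by >= 1
    before <- length(setdiff(unique(as.vector(v@labels)), 0L))
    merged <- corruptMasks(v, CorruptionSpec(mergeProb = 1, seed = 3))
    after <- length(setdiff(unique(as.vector(merged@labels)), 0L))
    expect_lt(after, before)
    # determinism
    c1 <- corruptMasks(v, CorruptionSpec(0.3, 0.3, 0.2, seed = 11))
    c2 <- corruptMasks(v, CorruptionSpec(0.3, 0.3, 0.2, seed = 11))
    expect_identical(c1@labels, c2@labels)
    # a split adds a label without touching depth or normals
    split <- corruptMasks(v, CorruptionSpec(splitProb = 1, seed = 5))
    expect_gt(length(setdiff(unique(as.vector(split@labels)), 0L)), before - 1)
    expect_identical(split@depth, v@depth)
    expect_identical(split@normal, v@normal)
})

test_that("boundary morphology shrinks or grows masks inside the footprint", {
    fx <- smallSceneFixture()
    v <- fx$views[[4]]
    bm <- corruptMasks(v, CorruptionSpec(boundaryRadius = 2, seed = 9))
    expect_false(identical(bm@labels, v@labels))
    # never invents labels outside the rendered surface
    expect_true(all(bm@labels[v@labels == 0L] == 0L))
})
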