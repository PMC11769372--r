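# Lifting 2D mask labels onto the cloud: depth gating, backside rejection,
# confidence scores and per-group outlier pre-filtering.

# One flat surface patch facing the camera at depth d, with a one-pixel
# label raster trick: a tiny constructed bundle around a single point.
tinyBundle <- function(depthValue, labelValue, normal = c(0, 0, -1)) {
    cam <- CameraModel(100, 100, cx = 2, cy = 2, width = 5, height = 5)
    pose <- Pose(diag(3), c(0, 0, 0))
    depth <- matrix(depthValue, 5, 5)
    nrm <- array(rep(normal, each = 25), c(5, 5, 3))
    lab <- matrix(labelValue, 5, 5)
    new("ViewBundle", viewId = 1L, camera = cam, pose = pose, depth = depth,
        normal = nrm, labels = lab, rgb = NULL, winner = NULL)
}

test_that("a consistent point inherits the pixel label, gated otherwise", {
    cloud <- PointCloud(matrix(c(0, 0, 2), 1))
    ok <- liftView(cloud, tinyBundle(2.0, 3L))
    expect_identical(instanceLabels(ok), 3L)
    expect_gt(confidence(ok)[1], 0)

    # 2% depth perturbation against a 0.5% gate
    bad <- liftView(cloud, tinyBundle(2.0 * 1.02, 3L))
    expect_identical(instanceLabels(bad), -1L)
    expect_identical(confidence(bad), 0)

    # backside surface is disregarded regardless of depth
    back <- liftView(cloud, tinyBundle(2.0, 3L, normal = c(0, 0, 1)))
    expect_identical(instanceLabels(back), -1L)

    # background pixel (label 0) carries no grouping information
    bg <- liftView(cloud, tinyBundle(2.0, 0L))
    expect_identical(instanceLabels(bg), -1L)
})

test_that("occluded points are rejected by the depth gate", {
    # two stacked surfaces: the front one owns the pixels
    pts <- rbind(c(0, 0, 1), c(0, 0, 2))
    cloud <- PointCloud(pts, normals = rbind(c(0, 0, -1), c(0, 0, -1)),
                        gtLabels = c(0L, 1L))
    cam <- CameraModel(100, 100, cx = 2, cy = 2, width = 5, height = 5)
    bundle <- renderView(cloud, cam, Pose(diag(3), c(0, 0, 0)))
    vl <- liftView(cloud, bundle)
    expect_identical(instanceLabels(vl)[1], 1L)   # front point: label 0 + 1
    expect_identical(instanceLabels(vl)[2], -1L)  # occluded
})

test_that("confidence score follows the printed blend and clamps backside", {
    expect_equal(confidenceScore(-1, 0.5, lambda = 0.9), 0.95)
    expect_equal(confidenceScore(0.5, 0.3, lambda = 0.9), 0.03)
    expect_equal(confidenceScore(0, 0, lambda = 0.5), 0)
    expect_equal(confidenceScore(-1, 0.5, lambda = 0.9,
                                 distanceMode = "proximity"), 0.95)
    expect_equal(confidenceScore(-0.5, 0.2, lambda = 0.9,
                                 distanceMode = "proximity"),
                 0.9 * 0.5 + 0.1 * 0.8)
    expect_error(confidenceScore(-1, 0.5, lambda = 1.2), "lambda")
    # monotone non-increasing in cos(phi) at fixed depth term
    cph <- seq(-1, 1, by = 0.05)
    s <- confidenceScore(cph, 0.4)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
})

test_that("group pre-filtering removes displaced points and tiny groups", {
    withr::with_seed(10, {
        compact <- matrix(runif(600, 0, 0.1), ncol = 3)
        far <- c(10, 10, 10)   # ~100x the group diameter away
        cloud <- PointCloud(rbind(compact, far))
        vl <- ViewLabeling(1L, rep(0L, 201), rep(0.5, 201))
        out <- prefilterGroups(vl, cloud)
        expect_identical(instanceLabels(out)[201], -1L)
        expect_identical(confidence(out)[201], 0)
        expect_gt(sum(instanceLabels(out) == 0L), 190)

        # a clean single-patch group survives essentially intact: the 2-sigma
        # rule may clip a few boundary points but never guts the group
        vl2 <- ViewLabeling(1L, c(rep(0L, 200), -1L), c(rep(0.5, 200), 0))
        out2 <- prefilterGroups(vl2, PointCloud(rbind(compact, far)))
        expect_gte(sum(instanceLabels(out2)[1:200] == 0L), 190L)

        # a 2-point group dissolves under minGroupSize = 5
        vl3 <- ViewLabeling(1L, c(1L, 1L, rep(-1L, 199)),
                            c(0.2, 0.2, rep(0, 199)))
        out3 <- prefilterGroups(vl3, PointCloud(rbind(compact, far)))
        expect_true(all(instanceLabels(out3) == -1L))
    })
})

test_that("clean renders lift back to exact ground truth per view", {
    fx <- smallSceneFixture()
    gt <- gtLabels(fx$scene)
    for (v in fx$views[c(1, 4, 7)]) {
        vl <- liftView(fx$scene@cloud, v)
        lab <- instanceLabels(vl)
        assigned <- lab >= 0L
        expect_gt(mean(assigned), 0.3)
        # inherited label is the ground-truth instance id + 1, always
        expect_identical(lab[assigned], gt[assigned] + 1L)
        expect_true(all(confidence(vl)[assigned] > 0))
        expect_true(all(confidence(vl)[!assigned] == 0))
    }
})

test_that("the depth gate trades coverage for precision monotonically", {
    fx <- smallSceneFixture()
    spec <- CorruptionSpec(mergeProb = 0.15, splitProb = 0.15,
                           dropoutProb = 0.1, seed = 5)
    cviews <- lapply(fx$views, corruptMasks, spec = spec)
    gt <- gtLabels(fx$scene)
    prec <- c(); labeled <- c()
    for (e in c(0.001, 0.005, 0.02)) {
        cfg <- FusionConfig(eThreshold = e)
        lb <- liftAllViews(fx$scene@cloud, cviews, cfg)
        tp <- 0; np <- 0
        for (l in lb) {
            pm <- pointMetrics(instanceLabels(l), gt)
            tp <- tp + pm$tp; np <- np + pm$tp + pm$fp
        }
        prec <- c(prec, tp / np)
        labeled <- c(labeled, np)
    }
    expect_true(all(diff(prec) <= 1e-12))
    expect_true(all(diff(labeled) >= 0))
})
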