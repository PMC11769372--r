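# Overlap tables, pair classification and the incremental merge rules.

test_that("overlap tables match the hand-enumerated example", {
    ot <- overlapTables(c(1, 1, 2, 2, -1), c(5, 5, 5, 6, 6))
    expect_equal(ot$qx["1", "5"], 1.0)
    expect_equal(ot$qx["2", "5"], 0.5)
    expect_equal(ot$qx["2", "6"], 0.5)
    expect_equal(ot$qy["5", "1"], 2 / 3)
    expect_equal(ot$qy["5", "2"], 1 / 3)
    expect_equal(ot$qy["6", "2"], 0.5)
    expect_equal(ot$qy["6", "-1"], 0.5)
    # rows are normalized distributions
    expect_true(all(abs(rowSums(ot$qx) - 1) < 1e-9))
    expect_true(all(abs(rowSums(ot$qy) - 1) < 1e-9))
    expect_error(overlapTables(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("identical labelings give identity tables, disjoint map to -1", {
    a <- c(0, 0, 1, 1, 2)
    ot <- overlapTables(a, a)
    for (g in c("0", "1", "2")) {
        expect_equal(ot$qx[g, g], 1.0)
        expect_equal(ot$qy[g, g], 1.0)
    }
    dj <- overlapTables(c(0, 0, -1, -1), c(-1, -1, 4, 4))
    expect_equal(dj$qx["0", "-1"], 1.0)
    expect_equal(dj$qy["4", "-1"], 1.0)
})

test_that("pair classification separates unmatched, matched and conflicts", {
    cfg <- FusionConfig(tauMatch = 0.5, tauUnmatched = 0.8)
    # group 1 has 90% of its mass on unassigned -> unmatched
    a <- c(rep(1L, 10), rep(-1L, 10))
    b <- c(5L, rep(-1L, 9), rep(-1L, 10))
    cls <- classifyPairs(overlapTables(a, b), cfg)
    expect_identical(cls$unmatchedA, 1L)

    # identical groups: matched at tau 0.5
    cls2 <- classifyPairs(overlapTables(c(1, 1, 1), c(5, 5, 5)), cfg)
    expect_identical(nrow(cls2$conflicts), 0L)
    expect_identical(cls2$matched$a, 1L)
    expect_identical(cls2$matched$b, 5L)

    # one-sided overlap (gx = 0.5, gy = 0.2) fails the mutual test
    a3 <- c(rep(1L, 4), rep(-1L, 6))
    b3 <- c(rep(5L, 2), 5L, 5L, rep(5L, 6))   # b covers all 10
    ot3 <- overlapTables(a3, b3)
    expect_equal(ot3$qy["5", "1"], 0.4)
    cls3 <- classifyPairs(ot3, cfg)
    expect_identical(nrow(cls3$matched), 0L)
    expect_identical(cls3$conflicts$a, 1L)
})

test_that("group mean matches a summation oracle", {
    expect_equal(groupMean(c(0.2, 0.4, 0.6)), 0.4)
    expect_equal(groupMean(0.77), 0.77)
    withr::with_seed(14, {
        x <- runif(1000)
        expect_lt(abs(groupMean(x) - sum(x) / 1000), 1e-12)
    })
    expect_error(groupMean(numeric(0)), "empty")
})

test_that("merging into an empty state adopts the view verbatim", {
    vl <- ViewLabeling(1L, c(0L, 0L, 1L, 2L, -1L), c(.1, .2, .3, .4, 0))
    st <- mergePair(emptyFusionState(5L), vl)
    expect_identical(length(unique(instanceLabels(st)[instanceLabels(st) >= 0L])), 3L)
    expect_identical(confidence(st), confidence(vl))
    expect_identical(instanceLabels(st)[5], -1L)
})

test_that("matched groups unify under the state label with summed confidence", {
    st <- new("FusionState", labels = c(7L, 7L, -1L), conf = c(0.5, 0.6, 0),
              nextLabel = 8L, mergeCount = 1L)
    vl <- ViewLabeling(2L, c(1L, 1L, -1L), c(0.3, 0.2, 0))
    out <- mergePair(st, vl)
    expect_identical(instanceLabels(out), c(7L, 7L, -1L))
    expect_equal(confidence(out), c(0.8, 0.8, 0))
})

test_that("conflicts resolve by group mean with absolute-difference update", {
    # state group mean 0.8 vs incoming mean 0.6 on a 2-point overlap;
    # the overlap keeps the state's label with conf |0.8-0.6| = 0.2,
    # and the incoming group's non-overlap point keeps its own (new) label
    st <- new("FusionState", labels = c(3L, 3L, -1L, -1L, -1L, -1L),
              conf = c(0.8, 0.8, 0, 0, 0, 0), nextLabel = 4L,
              mergeCount = 1L)
    vl <- ViewLabeling(2L, c(9L, 9L, 9L, 9L, 9L, -1L),
                       c(0.6, 0.6, 0.6, 0.6, 0.6, 0))
    cfg <- FusionConfig(tauMatch = 0.95, tauUnmatched = 0.95)
    out <- mergePair(st, vl, cfg)
    expect_identical(instanceLabels(out)[1:2], c(3L, 3L))
    expect_equal(confidence(out)[1:2], c(0.2, 0.2))
    newLab <- instanceLabels(out)[3]
    expect_gte(newLab, 4L)
    expect_identical(instanceLabels(out)[3:5], rep(newLab, 3L))
    expect_equal(confidence(out)[3:5], rep(0.6, 3))

    # reversed means: the incoming side claims the overlap
    st2 <- new("FusionState", labels = c(3L, 3L, -1L, -1L, -1L, -1L),
               conf = c(0.4, 0.4, 0, 0, 0, 0), nextLabel = 4L,
               mergeCount = 1L)
    out2 <- mergePair(st2, vl, cfg)
    lab2 <- instanceLabels(out2)
    expect_gte(lab2[1], 4L)
    expect_identical(lab2[1:5], rep(lab2[1], 5L))
    expect_equal(confidence(out2)[1:2], c(0.2, 0.2))
    expect_equal(confidence(out2)[3:5], rep(0.6, 3))
})

test_that("unmatched incoming groups enter whole with inherited confidences", {
    st <- new("FusionState", labels = c(3L, rep(-1L, 9L)),
              conf = c(0.9, rep(0, 9L)), nextLabel = 4L, mergeCount = 1L)
    vl <- ViewLabeling(2L, c(9L, rep(9L, 8L), -1L), c(rep(0.25, 9L), 0))
    out <- mergePair(st, vl)   # 8/9 of group 9 on unassigned -> unmatched
    lab <- instanceLabels(out)
    expect_identical(lab[1:9], rep(lab[1], 9L))
    expect_gte(lab[1], 4L)
    expect_equal(confidence(out)[1:9], rep(0.25, 9))
})

test_that("fusing the same view twice doubles confidence, keeps the partition", {
    fx <- smallSceneFixture()
    vl <- liftView(fx$scene@cloud, fx$views[[2]])
    once <- incrementalFuse(list(vl))
    twice <- incrementalFuse(list(vl, vl))
    expect_identical(instanceLabels(twice) >= 0L, instanceLabels(once) >= 0L)
    tab <- table(instanceLabels(once), instanceLabels(twice))
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    expect_equal(confidence(twice), 2 * confidence(once))
    expect_error(incrementalFuse(list()), "at least one")
})

test_that("fusion state stays a partition with non-negative confidence", {
    fx <- smallSceneFixture()
    spec <- CorruptionSpec(mergeProb = 0.2, splitProb = 0.2,
                           dropoutProb = 0.15, seed = 21)
    cviews <- lapply(fx$views, corruptMasks, spec = spec)
    lb <- liftAllViews(fx$scene@cloud, cviews)
    state <- emptyFusionState(nPoints(fx$scene@cloud))
    for (l in lb) {
        state <- mergePair(state, l)
        expect_true(validObject(state))
        lab <- instanceLabels(state)
        expect_true(all(confidence(state) >= 0))
        expect_true(all(confidence(state)[lab == -1L] == 0))
        expect_true(all(lab[lab >= 0L] < state@nextLabel))
    }
})

test_that("clean multi-view fusion recovers ground truth up to relabeling", {
    fx <- smallSceneFixture()
    lb <- liftAllViews(fx$scene@cloud, fx$views)
    st <- incrementalFuse(lb)
    gt <- gtLabels(fx$scene)
    vis <- Reduce("|", lapply(lb, function(l) instanceLabels(l) >= 0L))
    tab <- table(instanceLabels(st)[vis], gt[vis])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    # rotating the view order changes nothing but the label names
    for (r in c(3, 6)) {
        rot <- incrementalFuse(c(lb[r:length(lb)], lb[1:(r - 1)]))
        tab2 <- table(instanceLabels(st), instanceLabels(rot))
        expect_true(all(rowSums(tab2 > 0) == 1) &&
                    all(colSums(tab2 > 0) == 1))
    }
})
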