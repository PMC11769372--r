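# Evaluation suite against hand-computed examples and brute-force oracles.

test_that("point metrics match direct set arithmetic", {
    # pred group of 10 points, 9 shared with its gt group of 12
    gt <- c(rep(0L, 12), rep(-1L, 3))
    pred <- c(rep(4L, 9), rep(-1L, 3), rep(4L, 1), rep(-1L, 2))
    pm <- pointMetrics(pred, gt)
    expect_identical(pm$tp, 9L)
    expect_identical(pm$fp, 1L)
    expect_identical(pm$fn, 3L)
    expect_equal(pm$precision, 0.9)
    expect_equal(pm$recall, 0.75)
    expect_equal(pm$f1, 2 * 9 / 22)

    ident <- pointMetrics(gt, gt)
    expect_equal(c(ident$precision, ident$recall, ident$f1), c(1, 1, 1))

    empty <- pointMetrics(rep(-1L, 12), gt)
    expect_identical(empty$tp, 0L)
    expect_equal(empty$recall, 0)
    expect_true(is.na(empty$precision))
})

test_that("instance matching is greedy, one-to-one, and handles splits", {
    a <- c(0, 0, 1, 1, 2, 2)
    m <- matchInstances(a, a)
    expect_identical(nrow(m), 3L)
    expect_true(all(m$iou == 1))

    # one gt group split into two predictions: larger half matches
    gt <- rep(0L, 10)
    pred <- c(rep(1L, 6), rep(2L, 4))
    ms <- matchInstances(pred, gt)
    expect_identical(nrow(ms), 1L)
    expect_identical(ms$pred, 1L)
    expect_equal(ms$iou, 0.6)

    none <- matchInstances(c(0L, 0L, -1L, -1L), c(-1L, -1L, 3L, 3L))
    expect_identical(nrow(none), 0L)
})

test_that("mean IoU averages over gt groups with zeros for misses", {
    m <- matchInstances(c(0, 0, 1, 1), c(0, 0, 1, 1))
    expect_equal(meanIoU(m), 1.0)
    # two gt groups at IoU 0.8 and 0.6 -> 0.7
    gt <- c(rep(0L, 5), rep(1L, 5))
    pred <- c(rep(3L, 4), -1L, rep(4L, 3), -1L, 9L)
    mm <- matchInstances(pred, gt)
    expect_equal(sort(mm$iou), c(0.6, 0.8))
    expect_equal(meanIoU(mm), 0.7)
    expect_equal(meanIoU(matchInstances(rep(-1L, 4), c(0L, 0L, 1L, 1L))), 0)
})

test_that("average precision reproduces the ranked PR staircase", {
    # 2 gt groups; ranked predictions [TP, FP, TP] -> AP = 5/6
    gt <- c(rep(0L, 10), rep(1L, 10), rep(-1L, 6))
    pred <- c(rep(1L, 10), rep(-1L, 10), rep(2L, 3), rep(-1L, 3))
    pred[11:20] <- 3L
    scores <- c(`1` = 0.9, `2` = 0.5, `3` = 0.2)
    expect_equal(averagePrecision(pred, gt, scores, 0.5), 5 / 6)

    expect_equal(averagePrecision(gt, gt, NULL, 0.5), 1.0)
    # all predictions below the IoU threshold (IoU 3/10 against gt 0)
    off <- c(rep(7L, 3), rep(-1L, 23))
    expect_equal(averagePrecision(off, gt, NULL, 0.5), 0)
    expect_error(averagePrecision(pred, rep(-1L, 26), NULL, 0.5),
                 "ground-truth")
})

test_that("metrics agree exactly with brute-force oracles on random labelings", {
    withr::with_seed(123, {
        apWorse <- 0L
        for (trial in 1:100) {
            n <- sample(10:50, 1)
            gt <- sample(c(-1L, 0L, 1L, 2L, 3L), n, replace = TRUE)
            pred <- sample(c(-1L, 0L, 1L, 2L, 3L, 4L), n, replace = TRUE)
            want <- oracleEval(pred, gt)
            m <- matchInstances(pred, gt)
            pm <- pointMetrics(pred, gt, m)
            expect_identical(pm$tp, as.integer(want$tp))
            expect_identical(pm$fp, as.integer(want$fp))
            expect_identical(pm$fn, as.integer(want$fn))
            expect_equal(meanIoU(m), want$miou)
            if (any(gt >= 0) && any(pred >= 0)) {
                ids <- as.character(sort(unique(pred[pred >= 0])))
                scores <- stats::setNames(runif(length(ids)), ids)
                for (thr in c(0.25, 0.5, 0.75)) {
                    expect_equal(averagePrecision(pred, gt, scores, thr),
                                 oracleAP(pred, gt, scores, thr))
                }
                # AP is non-increasing in the IoU threshold
                aps <- sapply(c(0.3, 0.5, 0.75),
                              function(t) averagePrecision(pred, gt,
                                                           scores, t))
                expect_true(all(diff(aps) <= 1e-12))
            }
        }
    })
})

test_that("count agreement follows the closed forms", {
    perfect <- countAgreement(c(3, 5, 8), c(3, 5, 8))
    expect_equal(c(perfect$r2, perfect$mape, perfect$rmse), c(1, 0, 0))
    ca <- countAgreement(c(10, 20), c(9, 22))
    expect_equal(ca$mape, 10)
    expect_equal(ca$rmse, sqrt(5 / 2))
    # constant predictor at the mean has R^2 = 0
    y <- c(4, 6, 10, 12)
    expect_equal(countAgreement(y, rep(mean(y), 4))$r2, 0)
    expect_error(countAgreement(c(0, 1), c(1, 1)), "zero")
})

test_that("report rates stay in range on stressed inputs", {
    withr::with_seed(77, for (i in 1:20) {
        n <- sample(5:40, 1)
        gt <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
        pred <- sample(c(-1L, 0L, 1L, 2L), n, replace = TRUE)
        if (!any(gt >= 0)) gt[1] <- 0L
        rep <- evaluateSegmentation(pred, gt, conf = runif(n))
        vals <- c(rep@recall, rep@miou, rep@ap)
        if (!is.na(rep@precision)) vals <- c(vals, rep@precision)
        expect_true(all(vals >= 0 & vals <= 1))
    })
})
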