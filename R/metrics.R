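## Evaluation suite: point-level TP/FP/FN -> precision/recall/F1, greedy
## instance matching -> mIoU and AP at IoU thresholds, and count-agreement
## statistics (R^2, MAPE, RMSE) across samples.

## Internal: split a label vector into a named list of index sets
## (labels >= 0 only).
labelGroups <- function(labels) {
    labels <- as.integer(labels)
    keep <- labels >= 0L
    split(which(keep), labels[keep])
}

#' Greedy one-to-one instance matching
#'
#' Matches predicted groups to ground-truth groups in descending IoU; each
#' group on either side is used at most once.  This is the standard pairing
#' used throughout instance-segmentation evaluation and is applied
#' consistently for the point-level counts, mIoU and AP.
#'
#' @param pred,gt integer label vectors over the same points
#'   (-1 = unassigned).
#' @return A data.frame with columns \code{pred}, \code{gt}, \code{iou},
#'   one row per matched pair, plus attributes \code{nPred} and \code{nGt}
#'   (total group counts).
#' @export
matchInstances <- function(pred, gt) {
    pg <- labelGroups(pred); gg <- labelGroups(gt)
    cand <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
    for (i in seq_along(pg)) for (j in seq_along(gg)) {
        inter <- length(intersect(pg[[i]], gg[[j]]))
        if (inter == 0L) next
        iou <- inter / (length(pg[[i]]) + length(gg[[j]]) - inter)
        cand <- rbind(cand, data.frame(
            pred = as.integer(names(pg)[i]), gt = as.integer(names(gg)[j]),
            iou = iou))
    }
    cand <- cand[order(-cand$iou, cand$pred, cand$gt), , drop = FALSE]
    ## greedy: a pair is kept only if neither side was claimed earlier
    res <- cand[0, ]
    usedP <- integer(0); usedG <- integer(0)
    for (r in seq_len(nrow(cand))) {
        if (cand$pred[r] %in% usedP || cand$gt[r] %in% usedG) next
        res <- rbind(res, cand[r, ])
        usedP <- c(usedP, cand$pred[r]); usedG <- c(usedG, cand$gt[r])
    }
    rownames(res) <- NULL
    attr(res, "nPred") <- length(pg)
    attr(res, "nGt") <- length(gg)
    res
}

#' Point-level counts and rates
#'
#' True positives are the points shared between a predicted group and the
#' ground-truth group it is matched to, summed over matched pairs; every
#' other predicted point (including whole unmatched predicted groups) is a
#' false positive, and every ground-truth point not recovered is a false
#' negative:
#' \eqn{TP = |S_{pred} \cap S_{gt}|}, \eqn{FP = |S_{pred}| - TP},
#' \eqn{FN = |S_{gt}| - TP}, with precision \eqn{TP/(TP+FP)}, recall
#' \eqn{TP/(TP+FN)} and F1 their harmonic mean.
#'
#' @param pred,gt integer label vectors over the same points.
#' @param matching optional precomputed [matchInstances] result.
#' @return A list with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}, \code{f1} (rates are NA when undefined).
#' @export
pointMetrics <- function(pred, gt, matching = matchInstances(pred, gt)) {
    pg <- labelGroups(pred); gg <- labelGroups(gt)
    tp <- 0L
    for (r in seq_len(nrow(matching)))
        tp <- tp + length(intersect(pg[[as.character(matching$pred[r])]],
                                    gg[[as.character(matching$gt[r])]]))
    npred <- sum(lengths(pg)); ngt <- sum(lengths(gg))
    fp <- npred - tp; fn <- ngt - tp
    precision <- if (npred > 0) tp / npred else NA_real_
    recall <- if (ngt > 0) tp / ngt else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
        2 * precision * recall / (precision + recall) else NA_real_
    list(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
}

#' Mean IoU over ground-truth instances
#'
#' Average of the matched IoU per ground-truth group; unmatched ground-truth
#' groups contribute 0 (a missed instance is a zero-overlap instance).
#'
#' @param matching a [matchInstances] result.
#' @return The mean IoU in [0, 1].
#' @export
meanIoU <- function(matching) {
    nGt <- attr(matching, "nGt")
    if (is.null(nGt) || nGt == 0L) return(0)
    sum(matching$iou) / nGt
}

#' Average precision at an IoU threshold
#'
#' Predictions are ranked by descending score (group mean confidence); in
#' rank order, a prediction is a true positive iff its best IoU with a
#' still-unclaimed ground-truth group reaches \code{iouThreshold}.  The
#' average precision is the step-summed area
#' \eqn{AP = \sum_i P(i) (R(i) - R(i-1))} of the resulting
#' precision-recall curve.
#'
#' @param pred,gt integer label vectors over the same points.
#' @param scores named numeric vector of ranking scores per predicted group
#'   (names = label values); defaults to 0 for groups without a score.
#' @param iouThreshold IoU threshold in (0, 1).
#' @return AP in [0, 1].
#' @export
averagePrecision <- function(pred, gt, scores = NULL, iouThreshold = 0.5) {
    stopifnot(iouThreshold > 0, iouThreshold < 1)
    pg <- labelGroups(pred); gg <- labelGroups(gt)
    if (length(gg) == 0L) stop("no ground-truth groups")
    if (length(pg) == 0L) return(0)
    ids <- names(pg)
    sc <- rep(0, length(ids)); names(sc) <- ids
    if (!is.null(scores)) {
        hit <- intersect(ids, names(scores))
        sc[hit] <- scores[hit]
    }
    ord <- ids[order(-sc, as.integer(ids))]
    claimed <- character(0)
    isTP <- logical(length(ord))
    for (i in seq_along(ord)) {
        free <- setdiff(names(gg), claimed)
        if (!length(free)) break
        ious <- vapply(free, function(g) {
            inter <- length(intersect(pg[[ord[i]]], gg[[g]]))
            inter / (length(pg[[ord[i]]]) + length(gg[[g]]) - inter)
        }, numeric(1))
        j <- which.max(ious)
        if (ious[j] >= iouThreshold) {
            isTP[i] <- TRUE
            claimed <- c(claimed, free[j])
        }
    }
    prec <- cumsum(isTP) / seq_along(isTP)
    rec <- cumsum(isTP) / length(gg)
    sum(prec * diff(c(0, rec)))
}

#' Count-agreement statistics
#'
#' Agreement between ground-truth and predicted per-sample counts (e.g.
#' leaves per plant): the coefficient of determination
#' \eqn{R^2 = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y)^2}, the mean
#' absolute percentage error (in percent) and the root-mean-square error.
#'
#' @param y numeric vector of ground-truth counts (non-zero for MAPE).
#' @param yhat numeric vector of predicted counts, same length.
#' @return A list with \code{r2}, \code{mape} (percent), \code{rmse}.
#' @examples
#' countAgreement(c(10, 20), c(9, 22))  # MAPE 10%, RMSE ~1.581
#' @export
countAgreement <- function(y, yhat) {
    stopifnot(length(y) == length(yhat), length(y) > 0)
    if (any(y == 0)) stop("MAPE undefined for zero ground-truth counts")
    ss <- sum((y - mean(y))^2)
    r2 <- if (ss > 0) 1 - sum((y - yhat)^2) / ss else NA_real_
    list(r2 = r2,
         mape = 100 * mean(abs((y - yhat) / y)),
         rmse = sqrt(mean((y - yhat)^2)))
}

#' Full evaluation of a fused segmentation
#'
#' Computes the point-level counts and rates, mIoU, and AP at the requested
#' IoU thresholds, optionally restricted to a subset of points (e.g. the
#' points visible in at least one view).
#'
#' @param pred integer predicted labels (-1 = unassigned), or a
#'   [FusionState-class].
#' @param gt integer ground-truth labels.
#' @param conf per-point confidences used to rank groups for AP (taken from
#'   the fusion state when \code{pred} is one).
#' @param subset optional logical or integer index restricting evaluation.
#' @param apThresholds IoU thresholds for AP (default 0.50 and 0.75).
#' @return A [MetricsReport-class].
#' @export
evaluateSegmentation <- function(pred, gt, conf = NULL, subset = NULL,
                                 apThresholds = c(0.5, 0.75)) {
    if (is(pred, "FusionState")) {
        if (is.null(conf)) conf <- pred@conf
        pred <- pred@labels
    }
    pred <- as.integer(pred); gt <- as.integer(gt)
    if (is.null(conf)) conf <- numeric(length(pred))
    if (!is.null(subset)) {
        pred <- pred[subset]; gt <- gt[subset]; conf <- conf[subset]
    }
    matching <- matchInstances(pred, gt)
    pm <- pointMetrics(pred, gt, matching)
    scores <- vapply(labelGroups(pred), function(idx) mean(conf[idx]),
                     numeric(1))
    ap <- vapply(apThresholds, function(t)
        averagePrecision(pred, gt, scores, t), numeric(1))
    names(ap) <- format(apThresholds)
    new("MetricsReport", tp = as.numeric(pm$tp), fp = as.numeric(pm$fp),
        fn = as.numeric(pm$fn), precision = pm$precision,
        recall = pm$recall, f1 = pm$f1, miou = meanIoU(matching), ap = ap,
        r2 = NA_real_, mape = NA_real_, rmse = NA_real_)
}
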