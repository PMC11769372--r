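## Incremental confidence-driven merging of per-view labelings into one
## 3D instance segmentation of the original cloud.

#' Overlap tables between two labelings
#'
#' The correspondence mapping between a running (or per-view) labeling A and
#' an incoming labeling B over the same cloud: for every pair of labels
#' (including -1 = unassigned) the shared point indices are recorded, and
#' each side's counts are row-normalized into overlap ratios \eqn{\gamma}.
#' Row \code{qx[a, ]} distributes group a's points over B's labels (summing
#' to 1); \code{qy[b, ]} is the symmetric table for B over A's labels.
#'
#' @param labelsA,labelsB integer label vectors of equal length
#'   (-1 = unassigned).
#' @return A list with \code{qx} (A-groups x B-labels ratio matrix),
#'   \code{qy} (B-groups x A-labels), and \code{counts} (joint counts over
#'   all label pairs including -1).  Dimnames are label values as strings.
#' @examples
#' ot <- overlapTables(c(1, 1, 2, 2, -1), c(5, 5, 5, 6, 6))
#' ot$qx  # 1 -> {5: 1}, 2 -> {5: .5, 6: .5}
#' @export
overlapTables <- function(labelsA, labelsB) {
    if (length(labelsA) != length(labelsB))
        stop("labelings must have equal length")
    la <- as.integer(labelsA); lb <- as.integer(labelsB)
    keep <- la != -1L | lb != -1L
    la <- la[keep]; lb <- lb[keep]
    ua <- sort(unique(la)); ub <- sort(unique(lb))
    counts <- table(factor(la, levels = ua), factor(lb, levels = ub))
    counts <- matrix(as.numeric(counts), length(ua), length(ub),
                     dimnames = list(as.character(ua), as.character(ub)))
    arows <- setdiff(rownames(counts), "-1")
    brows <- setdiff(colnames(counts), "-1")
    qx <- counts[arows, , drop = FALSE]
    qx <- qx / pmax(rowSums(qx), 1)
    qy <- t(counts)[brows, , drop = FALSE]
    qy <- qy / pmax(rowSums(qy), 1)
    list(qx = qx, qy = qy, counts = counts)
}

#' Classify group pairs before a merge
#'
#' A group is \emph{unmatched} when the majority of its points (at least
#' \code{tauUnmatched} of its mass) lie on unassigned points of the other
#' labeling; it carries essentially new information.  A pair of groups is
#' \emph{matched} when the overlap ratio is at least \code{tauMatch} in both
#' directions; the two masks are two views of the same instance.  Every
#' remaining overlapping pair (one-sided overlap, partial overlap, proper
#' subset) is a \emph{conflict} to be resolved by confidence.
#'
#' A group can sit in at most one matched pair: if the thresholds admit
#' several, the pair with the larger two-sided ratio wins and the others are
#' demoted to conflicts (deterministic).
#'
#' @param tables result of [overlapTables].
#' @param config a [FusionConfig-class].
#' @return A list with integer vectors \code{unmatchedA},
#'   \code{unmatchedB} and data.frames \code{matched}, \code{conflicts}
#'   with columns \code{a}, \code{b}, \code{overlap} (shared point count).
#' @export
classifyPairs <- function(tables, config = FusionConfig()) {
    qx <- tables$qx; qy <- tables$qy; counts <- tables$counts
    aIds <- as.integer(rownames(qx)); bIds <- as.integer(rownames(qy))
    unmatchedA <- if ("-1" %in% colnames(qx))
        aIds[qx[, "-1"] >= config@tauUnmatched] else integer(0)
    unmatchedB <- if ("-1" %in% colnames(qy))
        bIds[qy[, "-1"] >= config@tauUnmatched] else integer(0)

    pairs <- which(counts > 0, arr.ind = TRUE)
    res <- data.frame(a = integer(0), b = integer(0), overlap = numeric(0),
                      gxy = numeric(0), gyx = numeric(0))
    for (r in seq_len(nrow(pairs))) {
        a <- as.integer(rownames(counts)[pairs[r, 1]])
        b <- as.integer(colnames(counts)[pairs[r, 2]])
        if (a == -1L || b == -1L) next
        if (a %in% unmatchedA || b %in% unmatchedB) next
        res <- rbind(res, data.frame(
            a = a, b = b, overlap = counts[pairs[r, 1], pairs[r, 2]],
            gxy = qx[as.character(a), as.character(b)],
            gyx = qy[as.character(b), as.character(a)]))
    }
    isMatch <- res$gxy >= config@tauMatch & res$gyx >= config@tauMatch
    matched <- res[isMatch, , drop = FALSE]
    ## enforce one-to-one matching: strongest two-sided ratio first
    if (nrow(matched) > 1L) {
        matched <- matched[order(-pmin(matched$gxy, matched$gyx),
                                 matched$a, matched$b), , drop = FALSE]
        keep <- !duplicated(matched$a) & !duplicated(matched$b)
        demoted <- matched[!keep, , drop = FALSE]
        matched <- matched[keep, , drop = FALSE]
    } else demoted <- matched[0, , drop = FALSE]
    conflicts <- rbind(res[!isMatch, , drop = FALSE], demoted)
    conflicts <- conflicts[order(-conflicts$overlap, conflicts$a,
                                 conflicts$b), , drop = FALSE]
    list(unmatchedA = unmatchedA, unmatchedB = unmatchedB,
         matched = matched[, c("a", "b", "overlap")],
         conflicts = conflicts[, c("a", "b", "overlap")])
}

#' Mean confidence of a group
#'
#' Arithmetic mean of the member points' confidence scores; the quantity two
#' conflicting groups are compared on.
#'
#' @param conf numeric vector of confidences (non-empty).
#' @return The mean.
#' @examples
#' groupMean(c(0.2, 0.4, 0.6))
#' @export
groupMean <- function(conf) {
    if (length(conf) == 0L) stop("empty group has no mean confidence")
    mean(conf)
}

#' Merge one incoming per-view labeling into the fusion state
#'
#' Three rules, applied in order with each point resolved at most once:
#' \enumerate{
#'   \item Unmatched incoming groups are added wholesale as new groups with
#'     fresh labels; their points inherit the incoming confidences.
#'   \item Matched pairs are unified under the state's label (the union of
#'     both point sets), and confidences are summed point by point - mutual
#'     validation across viewpoints increases reliability mass.
#'   \item Conflicts are resolved by comparing the two groups' mean
#'     confidences: the overlap region takes the higher-mean side's label
#'     and its confidence becomes the pointwise absolute difference
#'     \eqn{|s_x - s_y|}; non-overlap points keep their own label and
#'     confidence.  On an exact tie the existing state wins (biased toward
#'     accumulated evidence).  Conflict pairs are processed in descending
#'     overlap size.
#' }
#' Incoming-group points that end up claimed by no rule but lie on
#' unassigned state points enter as a fresh group for their incoming label
#' (the label "keeps itself" on the losing side outside the overlap).
#'
#' @param state a [FusionState-class].
#' @param incoming a [ViewLabeling-class] over the same cloud.
#' @param config a [FusionConfig-class].
#' @return The updated [FusionState-class].
#' @export
mergePair <- function(state, incoming, config = FusionConfig()) {
    if (length(state@labels) != length(incoming@labels))
        stop("state and incoming labeling cover different clouds")
    sLab <- state@labels;  sConf <- state@conf
    iLab <- incoming@labels; iConf <- incoming@conf
    outLab <- sLab; outConf <- sConf
    resolved <- logical(length(sLab))
    nextLabel <- state@nextLabel

    tables <- overlapTables(sLab, iLab)
    cls <- classifyPairs(tables, config)

    ## group means from the pre-merge scores (deterministic w.r.t. rule order)
    meanA <- vapply(as.integer(rownames(tables$qx)), function(a)
        groupMean(sConf[sLab == a]), numeric(1))
    names(meanA) <- rownames(tables$qx)
    meanB <- vapply(as.integer(rownames(tables$qy)), function(b)
        groupMean(iConf[iLab == b]), numeric(1))
    names(meanB) <- rownames(tables$qy)

    ## fresh state label for an incoming label, memoized per merge
    freshFor <- local({
        map <- list()
        function(b) {
            key <- as.character(b)
            if (is.null(map[[key]])) {
                map[[key]] <<- nextLabel
                nextLabel <<- nextLabel + 1L
            }
            map[[key]]
        }
    })

    ## (i) unmatched incoming groups: added verbatim as new groups
    for (b in cls$unmatchedB) {
        idx <- which(iLab == b & !resolved)
        lb <- freshFor(b)
        outLab[idx] <- lb
        outConf[idx] <- iConf[idx]
        resolved[idx] <- TRUE
    }

    ## (ii) matched pairs: union under the state's label, confidences summed
    if (nrow(cls$matched)) {
        m <- cls$matched[order(-cls$matched$overlap), , drop = FALSE]
        for (r in seq_len(nrow(m))) {
            a <- m$a[r]; b <- m$b[r]
            idx <- which((sLab == a | iLab == b) & !resolved)
            outLab[idx] <- a
            outConf[idx] <- ifelse(sLab[idx] == a, sConf[idx], 0) +
                            ifelse(iLab[idx] == b, iConf[idx], 0)
            resolved[idx] <- TRUE
        }
    }

    ## (iii) conflicts: overlap region to the higher-mean group,
    ## confidence = |s_x - s_y|; descending overlap, first resolution wins
    if (nrow(cls$conflicts)) {
        for (r in seq_len(nrow(cls$conflicts))) {
            a <- cls$conflicts$a[r]; b <- cls$conflicts$b[r]
            idx <- which(sLab == a & iLab == b & !resolved)
            if (!length(idx)) next
            stateWins <- meanA[as.character(a)] >= meanB[as.character(b)]
            outLab[idx] <- if (stateWins) a else freshFor(b)
            outConf[idx] <- abs(sConf[idx] - iConf[idx])
            resolved[idx] <- TRUE
        }
    }

    ## leftovers of non-unmatched incoming groups on unassigned state points
    ## keep their own (fresh) label with their own confidence
    left <- which(iLab >= 0L & sLab == -1L & !resolved)
    for (b in unique(iLab[left])) {
        idx <- left[iLab[left] == b]
        outLab[idx] <- freshFor(b)
        outConf[idx] <- iConf[idx]
        resolved[idx] <- TRUE
    }

    new("FusionState", labels = outLab, conf = outConf,
        nextLabel = nextLabel, mergeCount = state@mergeCount + 1L)
}

#' Incrementally fuse per-view labelings
#'
#' Folds [mergePair] over the views in capture order (adjacent turntable
#' angles overlap most, which keeps matches unambiguous).
#'
#' @param labelings non-empty list of [ViewLabeling-class] objects.
#' @param config a [FusionConfig-class].
#' @param onMerge optional callback \code{function(state, iteration)} invoked
#'   after every merge, e.g. to record per-iteration metrics.
#' @return The final [FusionState-class].
#' @export
incrementalFuse <- function(labelings, config = FusionConfig(),
                            onMerge = NULL) {
    if (length(labelings) == 0L) stop("at least one view labeling required")
    state <- emptyFusionState(length(labelings[[1]]@labels))
    for (i in seq_along(labelings)) {
        state <- mergePair(state, labelings[[i]], config)
        if (!is.null(onMerge)) onMerge(state, i)
    }
    state
}
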