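#' Overlap table between ground-truth and predicted label masks
#'
#' Computes pixel-overlap counts for every (truth, prediction) pair and the
#' per-pair intersection-over-union `|A n B| / |A u B|`. Objects absent from
#' the overlap keep zero entries.
#'
#' @param truth,pred [LabelMask-class] objects on the same grid.
#' @return a [MatchTable-class].
#' @export
matchObjects <- function(truth, pred) {
  stopifnot(is(truth, "LabelMask"), is(pred, "LabelMask"))
  if (!identical(dim(truth), dim(pred))) stop("masks differ in shape")
  tp <- pixels(truth)
  pp <- pixels(pred)
  kt <- nObjects(truth)
  kp <- nObjects(pred)
  tAreas <- tabulate(tp[tp > 0L], nbins = kt)
  pAreas <- tabulate(pp[pp > 0L], nbins = kp)
  ov <- matrix(0, kt, kp)
  sel <- tp > 0L & pp > 0L
  if (any(sel)) {
    pairIdx <- (tp[sel] - 1L) + kt * (pp[sel] - 1L)  # 0-based linear index
    cnt <- table(pairIdx)
    ov[as.integer(names(cnt)) + 1L] <- as.numeric(cnt)
  }
  iou <- ov
  if (kt > 0 && kp > 0) {
    un <- outer(tAreas, pAreas, "+") - ov
    iou <- ifelse(un > 0, ov / un, 0)
  }
  new("MatchTable", overlap = ov, iou = iou,
      truthAreas = as.integer(tAreas), predAreas = as.integer(pAreas))
}

#' Categorise ground-truth cells and count detection outcomes
#'
#' Formalises the human evaluation categories with deterministic rules:
#' \describe{
#'   \item{missed}{no prediction overlaps the cell (counts FN).}
#'   \item{under-segmented}{the cell's majority (> 50\% of its area) lies in
#'     a prediction that also holds another cell's majority (a multi-cell
#'     detection; one member per detection counts TP, the rest FN), or the
#'     cell's frame is much larger than the cell itself
#'     (`frameRatio` times its area; counts TP).}
#'   \item{correctly segmented}{more than 90\% of the cell's area lies
#'     inside its best-matching prediction, that prediction's best match is
#'     this cell, and the prediction holds no other cell's majority
#'     (counts TP).}
#'   \item{over-segmented}{the remainder: the cell is split across
#'     predictions or only a small section is detected; the largest fragment
#'     counts TP.}
#' }
#' Predictions overlapping no ground-truth cell count as debris / false
#' positives. Best matches maximise IoU with ties broken towards the lower
#' label ID. Every ground-truth cell lands in exactly one category, so
#' `manuallyCounted = correct + missed + under + over`.
#'
#' @param mt a [MatchTable-class] from [matchObjects()].
#' @param frameRatio heuristic threshold for a "much larger than the cell"
#'   single-cell frame (default 2x the cell area).
#' @return an [EvalReport-class].
#' @export
categorizeMatches <- function(mt, frameRatio = 2) {
  stopifnot(is(mt, "MatchTable"))
  kt <- nrow(mt@overlap)
  kp <- ncol(mt@overlap)
  ov <- mt@overlap
  iou <- mt@iou
  tA <- as.numeric(mt@truthAreas)
  pA <- as.numeric(mt@predAreas)

  category <- character(kt)
  tp <- 0L; fn <- 0L
  # majority containment: prediction j "contains" cell i when it holds
  # > 50% of i's area; each cell has at most one such frame
  containedIn <- rep(NA_integer_, kt)
  if (kt > 0 && kp > 0) {
    for (i in seq_len(kt)) {
      j <- which(ov[i, ] > 0.5 * tA[i])
      if (length(j) == 1L) containedIn[i] <- j
    }
  }
  nContained <- if (kp > 0) tabulate(containedIn[!is.na(containedIn)], kp)
                else integer(0)

  bestPred <- rep(NA_integer_, kt)
  for (i in seq_len(kt)) {
    if (kp == 0L || all(ov[i, ] == 0)) next
    bestPred[i] <- which.max(iou[i, ])          # ties: lower prediction ID
  }
  bestTruth <- rep(NA_integer_, kp)
  for (j in seq_len(kp)) {
    if (kt == 0L || all(ov[, j] == 0)) next
    bestTruth[j] <- which.max(iou[, j])         # ties: lower truth ID
  }

  underTPGiven <- rep(FALSE, kp)
  for (i in seq_len(kt)) {
    if (kp == 0L || is.na(bestPred[i])) { category[i] <- "missed"; fn <- fn + 1L; next }
    j <- containedIn[i]
    if (!is.na(j) && nContained[j] >= 2L) {
      category[i] <- "under"
      # one cell per under-segmented multi-cell detection counts TP:
      # the member with the largest overlap (ties: lower truth ID)
      members <- which(!is.na(containedIn) & containedIn == j)
      chosen <- members[which.max(ov[members, j])]
      if (i == chosen && !underTPGiven[j]) { tp <- tp + 1L; underTPGiven[j] <- TRUE }
      else if (i != chosen) fn <- fn + 1L
      next
    }
    if (!is.na(j) && pA[j] > frameRatio * tA[i]) {
      category[i] <- "under"                    # oversized single-cell frame
      tp <- tp + 1L
      next
    }
    jb <- bestPred[i]
    otherMajority <- nContained[jb] >= 1L &&
      !(!is.na(containedIn[i]) && containedIn[i] == jb && nContained[jb] == 1L)
    if (ov[i, jb] > 0.9 * tA[i] && !is.na(bestTruth[jb]) &&
        bestTruth[jb] == i && !otherMajority) {
      category[i] <- "correct"
      tp <- tp + 1L
    } else {
      category[i] <- "over"                     # split or partial detection;
      tp <- tp + 1L                             # largest fragment counts TP
    }
  }

  debris <- if (kp > 0) sum(colSums(ov) == 0 & pA > 0) else 0L
  fp <- as.integer(debris)
  correct <- sum(category == "correct")

  new("EvalReport",
      manuallyCounted = kt,
      correctlySegmented = as.integer(correct),
      missed = as.integer(sum(category == "missed")),
      underSegmented = as.integer(sum(category == "under")),
      overSegmented = as.integer(sum(category == "over")),
      debris = as.integer(debris),
      truePositives = as.integer(tp), falsePositives = fp,
      falseNegatives = as.integer(fn),
      accuracy = accuracy(tp, fp, fn),
      sensitivity = sensitivity(tp, fn),
      percentCorrect = if (kt > 0) percentCorrect(correct, kt) else NaN,
      meanIoU = if (kt > 0) meanIoU(mt) else NaN,
      gtCategory = category)
}

#' Detection metrics of the evaluation protocol
#'
#' `accuracy(tp, fp, fn)` is `100 * tp / (tp + fp + fn)`;
#' `sensitivity(tp, fn)` is `100 * tp / (tp + fn)`;
#' `percentCorrect(correct, manual)` is `100 * correct / manual`.
#' Zero denominators yield `NaN` with a warning (`percentCorrect` errors, as
#' an evaluation without manually counted cells is meaningless).
#'
#' @param tp,fp,fn true-positive, false-positive, false-negative counts.
#' @return a percentage in `[0, 100]`.
#' @examples
#' accuracy(92, 4, 4)       # 92
#' sensitivity(94, 6)       # 94
#' percentCorrect(86, 100)  # 86
#' @export
accuracy <- function(tp, fp, fn) {
  den <- tp + fp + fn
  if (den <= 0) { warning("accuracy undefined: no detections or cells"); return(NaN) }
  100 * tp / den
}

#' @rdname accuracy
#' @export
sensitivity <- function(tp, fn) {
  den <- tp + fn
  if (den <= 0) { warning("sensitivity undefined: no cells"); return(NaN) }
  100 * tp / den
}

#' @param correct number of correctly segmented cells.
#' @param manual number of manually counted (ground-truth) cells.
#' @rdname accuracy
#' @export
percentCorrect <- function(correct, manual) {
  if (manual <= 0) stop("percentCorrect undefined: no manually counted cells")
  100 * correct / manual
}

#' Mean best-match IoU over ground-truth cells
#'
#' Each ground-truth cell contributes the IoU of its best-matching
#' prediction, or 0 when nothing overlaps it (unmatched cells are kept, not
#' dropped); the mean over ground-truth cells is returned.
#'
#' @param mt a [MatchTable-class].
#' @return mean IoU in `[0, 1]`.
#' @export
meanIoU <- function(mt) {
  stopifnot(is(mt, "MatchTable"))
  kt <- nrow(mt@iou)
  if (kt == 0L) stop("meanIoU undefined: empty ground truth")
  best <- if (ncol(mt@iou) == 0L) rep(0, kt) else apply(mt@iou, 1, max)
  mean(best)
}

#' One-step evaluation of a segmentation against ground truth
#'
#' @param truth ground-truth [LabelMask-class].
#' @param pred predicted [LabelMask-class].
#' @param frameRatio see [categorizeMatches()].
#' @return an [EvalReport-class].
#' @export
evaluateSegmentation <- function(truth, pred, frameRatio = 2) {
  categorizeMatches(matchObjects(truth, pred), frameRatio = frameRatio)
}

#' Pool evaluation reports over images
#'
#' Sums the category and detection counts of per-image reports and
#' recomputes the pooled metrics from the summed counts; the pooled mean IoU
#' is the ground-truth-cell-weighted mean of the per-image values.
#'
#' @param reports a list of [EvalReport-class] objects.
#' @return an [EvalReport-class] with pooled counts and metrics.
#' @export
poolReports <- function(reports) {
  stopifnot(length(reports) > 0, all(vapply(reports, is, TRUE, "EvalReport")))
  g <- function(slot) sum(vapply(reports, methods::slot, 0L, slot))
  manual <- g("manuallyCounted")
  correct <- g("correctlySegmented")
  tp <- g("truePositives"); fp <- g("falsePositives"); fn <- g("falseNegatives")
  ious <- vapply(reports, methods::slot, 0, "meanIoU")
  w <- vapply(reports, methods::slot, 0L, "manuallyCounted")
  new("EvalReport",
      manuallyCounted = manual, correctlySegmented = correct,
      missed = g("missed"), underSegmented = g("underSegmented"),
      overSegmented = g("overSegmented"), debris = g("debris"),
      truePositives = tp, falsePositives = fp, falseNegatives = fn,
      accuracy = accuracy(tp, fp, fn), sensitivity = sensitivity(tp, fn),
      percentCorrect = percentCorrect(correct, manual),
      meanIoU = sum(ious * w) / sum(w),
      gtCategory = unlist(lapply(reports, methods::slot, "gtCategory")))
}
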