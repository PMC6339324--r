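maskFrom <- function(m) LabelMask(matrix(as.integer(m), nrow(m)), cal1())

test_that("object matching produces overlap counts and IoU by set arithmetic", {
  lab <- randomLabelMask(48, 3, seed = 2)
  mt <- matchObjects(lab, lab)
  expect_equal(diag(mt@iou), rep(1, nObjects(lab)))
  expect_equal(mt@overlap[row(mt@overlap) != col(mt@overlap)],
               rep(0, nObjects(lab)^2 - nObjects(lab)))

  # disjoint masks: all-zero table
  a <- matrix(0L, 10, 10); a[2:4, 2:4] <- 1L
  b <- matrix(0L, 10, 10); b[7:9, 7:9] <- 1L
  mt2 <- matchObjects(maskFrom(a), maskFrom(b))
  expect_true(all(mt2@overlap == 0))

  # 100-px truth, prediction covers 80 plus 20 extra -> IoU = 80/120
  t1 <- matrix(0L, 20, 20); t1[1:10, 1:10] <- 1L
  p1 <- matrix(0L, 20, 20); p1[3:12, 1:10] <- 1L
  mt3 <- matchObjects(maskFrom(t1), maskFrom(p1))
  expect_equal(mt3@overlap[1, 1], 80)
  expect_equal(mt3@iou[1, 1], 80 / 120)

  expect_error(matchObjects(maskFrom(t1), maskFrom(matrix(0L, 5, 5))), "shape")
})

test_that("a perfect prediction is all correctly segmented", {
  lab <- randomLabelMask(64, 5, seed = 3)
  rep <- evaluateSegmentation(lab, lab)
  k <- nObjects(lab)
  expect_equal(rep@correctlySegmented, k)
  expect_equal(rep@missed + rep@underSegmented + rep@overSegmented + rep@debris, 0L)
  expect_equal(rep@accuracy, 100)
  expect_equal(rep@sensitivity, 100)
  expect_equal(rep@percentCorrect, 100)
  expect_equal(rep@meanIoU, 1)
})

test_that("a multi-cell detection counts one TP and the rest FN (under-segmentation)", {
  truth <- matrix(0L, 30, 30)
  truth[5:14, 5:14] <- 1L
  truth[5:14, 16:25] <- 2L
  pred <- matrix(0L, 30, 30)
  pred[5:14, 5:25] <- 1L                       # one frame swallows both cells
  rep <- evaluateSegmentation(maskFrom(truth), maskFrom(pred))
  expect_equal(rep@underSegmented, 2L)
  expect_equal(rep@truePositives, 1L)
  expect_equal(rep@falseNegatives, 1L)
  expect_equal(rep@correctlySegmented, 0L)
  expect_equal(rep@falsePositives, 0L)
})

test_that("a split cell counts as over-segmented with the largest fragment as TP", {
  truth <- matrix(0L, 30, 30)
  truth[6:15, 6:25] <- 1L                      # 10 x 20 cell
  pred <- matrix(0L, 30, 30)
  pred[6:15, 6:17] <- 1L                       # 60% fragment
  pred[6:15, 19:25] <- 2L                      # remaining fragment (gap at 18)
  rep <- evaluateSegmentation(maskFrom(truth), maskFrom(pred))
  expect_equal(rep@overSegmented, 1L)
  expect_equal(rep@truePositives, 1L)
  expect_equal(rep@falsePositives, 0L)         # fragments are not debris
  expect_equal(rep@falseNegatives, 0L)
})

test_that("missed cells and debris are counted as FN and FP", {
  truth <- matrix(0L, 40, 40)
  truth[2:11, 2:11] <- 1L
  truth[20:29, 20:29] <- 2L
  pred <- matrix(0L, 40, 40)
  pred[2:11, 2:11] <- 1L                       # cell 1 found
  pred[33:39, 2:8] <- 2L                       # debris far from any cell
  rep <- evaluateSegmentation(maskFrom(truth), maskFrom(pred))
  expect_equal(rep@missed, 1L)
  expect_equal(rep@falseNegatives, 1L)
  expect_equal(rep@debris, 1L)
  expect_equal(rep@falsePositives, 1L)
  expect_equal(rep@correctlySegmented, 1L)
  expect_equal(rep@accuracy, 100 * 1 / 3)
})

test_that("an oversized frame around a single cell is under-segmentation", {
  truth <- matrix(0L, 40, 40)
  truth[16:25, 16:25] <- 1L                    # 100 px cell
  pred <- matrix(0L, 40, 40)
  pred[6:35, 6:35] <- 1L                       # 900 px frame (9x the cell)
  rep <- evaluateSegmentation(maskFrom(truth), maskFrom(pred))
  expect_equal(rep@underSegmented, 1L)
  expect_equal(rep@correctlySegmented, 0L)
  expect_equal(rep@truePositives, 1L)
})

test_that("the metric formulas follow the evaluation protocol exactly", {
  expect_equal(accuracy(92, 4, 4), 92)
  expect_equal(accuracy(10, 0, 0), 100)
  expect_equal(accuracy(0, 5, 5), 0)
  expect_equal(sensitivity(94, 6), 94)
  expect_equal(sensitivity(1, 0), 100)
  expect_equal(sensitivity(0, 1), 0)
  expect_equal(percentCorrect(86, 100), 86)
  expect_equal(percentCorrect(0, 10), 0)
  expect_equal(percentCorrect(10, 10), 100)
  expect_warning(expect_true(is.nan(accuracy(0, 0, 0))), "undefined")
  expect_warning(expect_true(is.nan(sensitivity(0, 0))), "undefined")
  expect_error(percentCorrect(5, 0), "undefined")
})

test_that("mean IoU averages best matches and zero-fills unmatched cells", {
  truth <- matrix(0L, 30, 30)
  truth[1:10, 1:10] <- 1L
  truth[1:10, 15:24] <- 2L
  predA <- truth                                # identical
  expect_equal(meanIoU(matchObjects(maskFrom(truth), maskFrom(predA))), 1)
  predB <- matrix(0L, 30, 30)                   # empty prediction
  expect_equal(meanIoU(matchObjects(maskFrom(truth), maskFrom(predB))), 0)
  # best IoUs 0.8 and 0.6 -> mean 0.7 (rectangles chosen to hit those values)
  predC <- matrix(0L, 30, 30)
  predC[1:10, 1:8] <- 1L                        # 80/100 of cell 1, IoU 0.8
  predC[1:10, 15:20] <- 2L                      # 60/100 of cell 2, IoU 0.6
  expect_equal(meanIoU(matchObjects(maskFrom(truth), maskFrom(predC))), 0.7)
})

test_that("every ground-truth cell lands in exactly one category (partition)", {
  for (seed in 1:8) {
    truth <- randomLabelMask(72, 5, seed = seed)
    # perturb: erase one cell, merge neighbours by dilation-like growth,
    # split another -- built from the truth with deterministic edits
    px <- pixels(truth)
    pred <- px
    k <- nObjects(truth)
    pred[px == 1L] <- 0L                                    # miss cell 1
    if (k >= 3) pred[pred == 3L & col(pred) %% 2 == 0] <- k + 1L  # split cell 3
    predMask <- LabelMask(pred, cal1())
    rep <- evaluateSegmentation(truth, predMask)
    expect_equal(rep@correctlySegmented + rep@missed +
                 rep@underSegmented + rep@overSegmented,
                 rep@manuallyCounted,
                 info = sprintf("partition failed for seed %d", seed))
    expect_lte(rep@truePositives, rep@manuallyCounted)
  }
})

test_that("metrics are invariant under label permutation", {
  truth <- randomLabelMask(64, 4, seed = 12)
  pred <- randomLabelMask(64, 4, seed = 13)
  rep1 <- evaluateSegmentation(truth, pred)
  # permute prediction labels
  px <- pixels(pred)
  k <- nObjects(pred)
  perm <- rev(seq_len(k))
  px2 <- px; px2[px > 0L] <- perm[px[px > 0L]]
  rep2 <- evaluateSegmentation(truth, LabelMask(px2, cal1()))
  for (s in c("correctlySegmented", "missed", "underSegmented", "overSegmented",
              "truePositives", "falsePositives", "falseNegatives")) {
    expect_identical(slot(rep1, s), slot(rep2, s), info = s)
  }
  expect_equal(rep1@meanIoU, rep2@meanIoU)
})

test_that("pooling sums counts and recomputes metrics from the sums", {
  lab1 <- randomLabelMask(48, 3, seed = 4)
  lab2 <- randomLabelMask(48, 4, seed = 5)
  r1 <- evaluateSegmentation(lab1, lab1)
  r2 <- evaluateSegmentation(lab2, LabelMask(matrix(0L, 48, 48), cal1()))
  pooled <- poolReports(list(r1, r2))
  expect_equal(pooled@manuallyCounted, r1@manuallyCounted + r2@manuallyCounted)
  expect_equal(pooled@truePositives, r1@truePositives)
  expect_equal(pooled@sensitivity,
               100 * r1@truePositives / pooled@manuallyCounted)
  expect_equal(pooled@meanIoU,
               (r1@meanIoU * r1@manuallyCounted + 0) / pooled@manuallyCounted)
})
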