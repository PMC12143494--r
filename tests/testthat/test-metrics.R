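test_that("confusion counts match the definitions and a brute-force loop", {
  gt <- matrix(0L, 10, 10); gt[1:2, 1:5] <- 1L
  expect_identical(confusionCounts(gt, gt, 1L),
                   c(tp = 10L, fp = 0L, fn = 0L, tn = 90L))
  expect_identical(confusionCounts(matrix(0L, 10, 10), gt, 1L),
                   c(tp = 0L, fp = 0L, fn = 10L, tn = 90L))
  expect_error(confusionCounts(matrix(0L, 3, 3), gt, 1L), "shapes")
  set.seed(1)
  for (i in 1:20) {
    pred <- random_labels(c(6, 6), 2)
    gt2 <- random_labels(c(6, 6), 2)
    for (cl in 0:2) {
      cc <- confusionCounts(pred, gt2, cl)
      expect_identical(as.integer(cc), as.integer(bf_confusion(pred, gt2, cl)))
      expect_identical(sum(cc), 36L)
    }
  }
})

test_that("semantic scores follow the formulas and conventions", {
  gt <- matrix(0L, 3, 3); gt[1, ] <- 1L; gt[2, 1] <- 1L     # 4 gt pixels
  pred <- matrix(0L, 3, 3); pred[1, 1:2] <- 1L; pred[3, 2:3] <- 1L  # 4 pred, overlap 2
  sc <- semanticScores(pred, gt, 1L)
  expect_equal(sc$iou, 2 / 6)
  expect_equal(sc$precision, 0.5)
  expect_equal(sc$recall, 0.5)
  expect_equal(sc$f_score, 0.5)
  ## identical non-empty masks
  sc1 <- semanticScores(gt, gt, 1L)
  expect_equal(unlist(sc1), c(iou = 1, precision = 1, recall = 1, f_score = 1))
  ## disjoint non-empty masks
  a <- matrix(0L, 2, 2); a[1, 1] <- 1L
  b <- matrix(0L, 2, 2); b[2, 2] <- 1L
  expect_equal(unlist(semanticScores(a, b, 1L)),
               c(iou = 0, precision = 0, recall = 0, f_score = 0))
  ## empty/empty convention: perfect agreement
  z <- matrix(0L, 2, 2)
  expect_equal(semanticScores(z, z, 1L)$iou, 1)
  ## symmetry of IoU
  expect_equal(semanticScores(pred, gt, 1L)$iou,
               semanticScores(gt, pred, 1L)$iou)
})

test_that("IoU never decreases when a false positive is removed", {
  set.seed(2)
  for (i in 1:20) {
    pred <- random_mask(c(6, 6), 0.4)
    gt <- random_mask(c(6, 6), 0.3)
    fps <- which(pred & !gt)
    if (!length(fps)) next
    pred2 <- pred
    pred2[fps[1]] <- FALSE
    expect_gte(semanticScores(pred2 * 1L, gt * 1L, 1L)$iou,
               semanticScores(pred * 1L, gt * 1L, 1L)$iou)
  }
})

test_that("the distance transform is exact under anisotropic spacing", {
  set.seed(3)
  for (i in 1:10) {
    mask <- random_mask(c(5, 6, 4), 0.15)
    if (!any(mask)) next
    sp <- c(2.5, 1, 1.3)
    dt <- distanceTransform(mask, sp)
    coords <- mask_coords(mask, sp)
    all_coords <- mask_coords(array(TRUE, dim(mask)), sp)
    bf <- array(bf_nn_dist(all_coords, coords), dim(mask))
    expect_lt(max(abs(dt - bf)), 1e-9)
  }
})

test_that("mean false distance equals the bidirectional Hausdorff mean", {
  m <- matrix(0L, 5, 5); m[2, 2] <- 1L
  expect_equal(meanFalseDistance(m, m), 0)
  a <- matrix(0L, 1, 5); a[1, 1] <- 1L
  b <- matrix(0L, 1, 5); b[1, 4] <- 1L
  expect_equal(meanFalseDistance(a, b), 3)
  expect_error(meanFalseDistance(matrix(0L, 5, 5), m), "empty")
  set.seed(4)
  for (i in 1:20) {
    pred <- random_mask(c(5, 5)); gt <- random_mask(c(5, 5))
    if (!any(pred) || !any(gt)) next
    expect_equal(meanFalseDistance(pred * 1L, gt * 1L),
                 bf_mfd(pred * 1L, gt * 1L), tolerance = 1e-12)
    ## symmetric under swapping prediction and truth
    expect_equal(meanFalseDistance(pred * 1L, gt * 1L),
                 meanFalseDistance(gt * 1L, pred * 1L))
  }
})

test_that("CREMI distances match their definitions and the brute-force oracle", {
  m <- matrix(0L, 4, 4); m[2, 2:3] <- 1L
  cs <- cremiScores(m, m)
  expect_equal(cs$adgt, 0); expect_equal(cs$adf, 0)
  expect_equal(cs$cremi_score, 0)
  expect_identical(c(cs$fp, cs$fn), c(0L, 0L))
  a <- matrix(0L, 1, 5); a[1, 1] <- 1L
  b <- matrix(0L, 1, 5); b[1, 5] <- 1L
  cs2 <- cremiScores(a, b)
  expect_equal(cs2$adgt, 4); expect_equal(cs2$adf, 4)
  expect_equal(cs2$cremi_score, 4)
  set.seed(5)
  for (i in 1:20) {
    pred <- random_mask(c(6, 6), 0.25); gt <- random_mask(c(6, 6), 0.25)
    if (!any(pred) || !any(gt)) next
    bf <- bf_adgt_adf(pred * 1L, gt * 1L)
    cs3 <- cremiScores(pred * 1L, gt * 1L)
    expect_equal(cs3$adgt, bf$adgt, tolerance = 1e-12)
    expect_equal(cs3$adf, bf$adf, tolerance = 1e-12)
    ## duality: adgt(pred, gt) == adf(gt, pred)
    expect_equal(cs3$adgt, cremiScores(gt * 1L, pred * 1L)$adf,
                 tolerance = 1e-12)
  }
  ## degenerate prediction: distances not computable, reported missing
  cs4 <- cremiScores(matrix(0L, 4, 4), m)
  expect_true(is.na(cs4$adgt) && is.na(cs4$cremi_score))
  expect_identical(cs4$fn, 2L)
})

test_that("reports aggregate per task and per class as documented", {
  mk <- function(x) methods::new("MetricReport",
    perClass = data.frame(class = 1, iou = x, precision = x, recall = x,
                          f_score = x, mfd = NA_real_),
    aggregate = list(mean_iou = x, mean_f = x, mean_precision = x,
                     mean_recall = x),
    cremi = list())
  tasks <- lapply(c(0.885, 0.890, 0.991, 0.910), mk)
  expect_equal(aggregateReports(tasks)$mean_iou, 0.919)
  expect_equal(aggregateReports(list(mk(0.0), mk(1.0)))$mean_iou, 0.5)
  single <- aggregateReports(list(mk(0.7)))
  expect_equal(single$mean_iou, 0.7)
  expect_error(aggregateReports(list()), "non-empty")
})

test_that("segmentation evaluation produces bounded per-class tables", {
  set.seed(6)
  gt <- random_labels(c(4, 8, 8), 2)
  pred <- random_labels(c(4, 8, 8), 2)
  rep <- evaluateSegmentation(pred, gt)
  tab <- perClassMetrics(rep)
  expect_identical(tab$class, c(1L, 2L))
  for (cl in c("iou", "precision", "recall", "f_score")) {
    expect_true(all(tab[[cl]] >= 0 & tab[[cl]] <= 1))
  }
  expect_true(all(is.na(tab$mfd) | tab$mfd >= 0))
  expect_equal(aggregateMetrics(rep)$mean_iou, mean(tab$iou))
  ## mean-over-classes pooling matches the report aggregate
  expect_equal(aggregateReports(list(rep), "mean_over_classes")$mean_iou,
               aggregateMetrics(rep)$mean_iou)
})
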