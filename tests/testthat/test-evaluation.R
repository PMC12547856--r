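# Metrics: IoU, matching, precision/recall/F1, AP, mAP, confusion matrix.

shape60 <- c(60L, 60L)

test_that("mask_iou matches pixel counting", {
  a <- rect_mask(shape60, 1, 10, 1, 10)
  expect_equal(mask_iou(a, a), 1)
  b <- rect_mask(shape60, 30, 39, 30, 39)
  expect_equal(mask_iou(a, b), 0)
  # two 10x10 squares overlapping in a 10x5 region
  c2 <- rect_mask(shape60, 1, 10, 6, 15)
  expect_equal(mask_iou(a, c2), 50 / 150)
  expect_error(mask_iou(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), "empty")
})

test_that("mask_iou is symmetric and in [0, 1] on random masks", {
  set.seed(4)
  for (i in 1:20) {
    a <- matrix(runif(100) < 0.3, 10, 10)
    b <- matrix(runif(100) < 0.3, 10, 10)
    if (!any(a | b)) next
    v <- mask_iou(a, b)
    expect_identical(v, mask_iou(b, a))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("match_instances is greedy by confidence and class-consistent", {
  t1 <- rect_mask(shape60, 1, 10, 1, 10)
  t2 <- rect_mask(shape60, 1, 10, 12, 21)
  truth <- rois_from_masks(list(t1, t2), c(1L, 1L), shape60)
  # exact prediction -> all matched
  m0 <- match_instances(truth, truth)
  expect_equal(nrow(m0$pairs), 2L)
  expect_length(m0$unmatched_truth, 0L)
  expect_length(m0$unmatched_pred, 0L)
  # one prediction overlapping two truths (IoU 0.6 vs 0.55 rounded):
  # takes the higher-IoU truth, other truth unmatched
  p <- rect_mask(shape60, 1, 10, 3, 12) # IoU vs t1: 80/120=0.667, vs t2: 10/190=0.05
  p2 <- rect_mask(shape60, 1, 10, 8, 17) # vs t1: 30/170=0.18, vs t2: 60/140=0.43
  pred <- rois_from_masks(list(p), 1L, shape60, confidence = 0.9)
  m1 <- match_instances(truth, pred, iou_threshold = 0.5)
  expect_equal(nrow(m1$pairs), 1L)
  expect_equal(m1$pairs$truth_id, truth$table$id[1])
  expect_equal(m1$unmatched_truth, truth$table$id[2])
  # empty prediction -> all truth unmatched
  m2 <- match_instances(truth, roi_set(list(), integer(), shape60))
  expect_length(m2$unmatched_truth, 2L)
  # class mismatch never matches
  predc <- rois_from_masks(list(t1), 2L, shape60, confidence = 0.9)
  m3 <- match_instances(truth, predc)
  expect_equal(nrow(m3$pairs), 0L)
})

test_that("precision/recall/F1 follow their formulas", {
  fake_match <- function(tp, fp, fn) {
    structure(list(pairs = data.frame(truth_id = seq_len(tp),
                                      pred_id = seq_len(tp),
                                      iou = rep(1, tp))[seq_len(tp), ],
                   unmatched_pred = seq_len(fp), unmatched_truth = seq_len(fn),
                   iou_threshold = 0.5), class = "match_result")
  }
  expect_equal(unname(precision_recall_f1(fake_match(5, 0, 0))), c(1, 1, 1))
  r <- precision_recall_f1(fake_match(3, 1, 2))
  expect_equal(unname(r), c(0.75, 0.6, 2 / (1 / 0.75 + 1 / 0.6)), tolerance = 1e-12)
  expect_equal(round(r[["f1"]], 4), 0.6667)
  expect_equal(unname(precision_recall_f1(fake_match(0, 3, 2))), c(0, 0, 0))
  expect_equal(segmentation_loss(fake_match(3, 1, 2)), 0.4)
  expect_equal(segmentation_loss(fake_match(3, 1, 2), as_loss = FALSE), 0.6)
})

test_that("average precision uses all-point interpolation", {
  tmask <- rect_mask(shape60, 10, 19, 10, 19)
  truth <- rois_from_masks(list(tmask), 1L, shape60)
  # single exact detection -> AP 1 at every threshold, mAP 1
  pred <- rois_from_masks(list(tmask), 1L, shape60, confidence = 0.9)
  expect_equal(average_precision(truth, pred, 1), 1)
  expect_equal(map_50_95(truth, pred)$map, 1)
  # one TP (0.9) + one FP (0.8): precision envelope at recall 1 is 1
  fp <- rect_mask(shape60, 40, 49, 40, 49)
  pred2 <- rois_from_masks(list(tmask, fp), c(1L, 1L), shape60,
                           confidence = c(0.9, 0.8))
  expect_equal(average_precision(truth, pred2, 1, 0.5), 1)
  # detection with IoU 0.6: TP at 0.50-0.60, FP at 0.65+, mAP = 3/10
  p06 <- rect_mask(shape60, 10, 19, 10, 15) # IoU 60/100 = 0.6
  pred3 <- rois_from_masks(list(p06), 1L, shape60, confidence = 0.9)
  expect_equal(mask_iou(tmask, p06), 0.6)
  expect_equal(map_50_95(truth, pred3)$map, 0.3)
  # class with no truth instances errors
  expect_error(average_precision(truth, pred, 2), "no truth")
})

test_that("AP is invariant to strictly increasing confidence rescaling", {
  set.seed(6)
  masks_t <- list(disk_mask(6, shape60, c(15, 15)), disk_mask(6, shape60, c(40, 40)),
                  disk_mask(5, shape60, c(15, 45)))
  truth <- rois_from_masks(masks_t, c(1L, 1L, 1L), shape60)
  masks_p <- list(disk_mask(6, shape60, c(16, 15)), disk_mask(5, shape60, c(41, 41)),
                  disk_mask(6, shape60, c(45, 15)), disk_mask(4, shape60, c(15, 44)))
  conf <- c(0.9, 0.6, 0.8, 0.3)
  pred1 <- rois_from_masks(masks_p, rep(1L, 4), shape60, confidence = conf)
  pred2 <- rois_from_masks(masks_p, rep(1L, 4), shape60,
                           confidence = plogis(5 * conf - 2))
  for (th in c(0.5, 0.75)) {
    expect_equal(average_precision(truth, pred1, 1, th),
                 average_precision(truth, pred2, 1, th))
  }
  # thresholds only tighten: mAP50-95 <= AP50 per class
  mm <- map_50_95(truth, pred1)
  expect_true(all(mm$per_class <= mm$ap50 + 1e-12))
})

test_that("confusion matrix follows the matched/background rules", {
  classes <- organelle_classes()
  shape <- c(120L, 120L)
  masks <- lapply(1:6, function(i) disk_mask(6, shape, c(20 * i - 10, 20 * i - 10)))
  truth <- rois_from_masks(masks, 1:6, shape)
  # perfect prediction -> identity, background row/column all 0
  M <- confusion_matrix(truth, truth)
  expect_equal(unname(M[1:6, 1:6]), diag(6))
  expect_true(all(M[7, ] == 0) && all(M[, 7] == 0))
  # one truth mitochondrion, no predictions -> 1.0 in the background row
  t1 <- rois_from_masks(masks[2], 2L, shape)
  M2 <- confusion_matrix(t1, roi_set(list(), integer(), shape))
  expect_equal(M2["background", "mitochondria"], 1)
  # one spurious prediction on empty truth -> 1.0 in the background column
  M3 <- confusion_matrix(roi_set(list(), integer(), shape),
                         rois_from_masks(masks[3], 3L, shape))
  expect_equal(M3["ER", "background"], 1)
  # cross-class confusion: truth class 1 predicted as class 2
  wrong <- rois_from_masks(masks[1], 2L, shape, confidence = 0.8)
  t2 <- rois_from_masks(masks[1], 1L, shape)
  M4 <- confusion_matrix(t2, wrong)
  expect_equal(M4["mitochondria", "nucleolus"], 1)
})

test_that("true-class confusion columns sum to 1", {
  ph <- make_em_phantom(small_spec(seed = 15, vesicles = c(4, 4),
                                   mitochondria = c(3, 3), Golgi = c(2, 2)))
  dets <- run_passes(ph$image, 80L, 2L)
  pred <- merge_passes(dets, 2, image_shape = dim(ph$image))
  M <- confusion_matrix(ph$truth, pred)
  present <- unique(ph$truth$table$class_id)
  sums <- colSums(M)[present]
  expect_true(all(abs(sums - 1) < 1e-9))
})
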