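# Heatmap-to-box proposals, IoU matching, PR curves, AP/mAP and the
# per-image IoU aggregate.

test_that("iou matches area arithmetic and is a symmetric proportion", {
  a <- bbox(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, bbox(20, 20, 30, 30)), 0)
  expect_equal(iou(a, bbox(5, 0, 15, 10)), 1 / 3)
  set.seed(31)
  for (i in 1:1000) {
    b1 <- bbox(x <- runif(1, 0, 50), y <- runif(1, 0, 50),
               x + runif(1, 1, 30), y + runif(1, 1, 30))
    b2 <- bbox(x <- runif(1, 0, 50), y <- runif(1, 0, 50),
               x + runif(1, 1, 30), y + runif(1, 1, 30))
    v <- iou(b1, b2)
    expect_true(v >= 0 && v <= 1)
    expect_equal(v, iou(b2, b1))
  }
  expect_error(bbox(5, 0, 5, 10), "degenerate")
})

test_that("extract_boxes turns connected components into scored detections", {
  z <- matrix(0, 10, 12)
  expect_equal(nrow(extract_boxes(relevance_map(z), 0.5)), 0L)
  # one 3x4 block at rows 3-5, cols 6-9 (1-based) = rows 2-4, cols 5-8 0-based
  m <- z; m[3:5, 6:9] <- 0.3; m[4, 7] <- 0.8
  d <- extract_boxes(relevance_map(m), 0.5, image_id = "p")
  expect_equal(nrow(d), 1L)
  expect_equal(as.numeric(d[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(5, 2, 9, 5))
  expect_equal(d$confidence, 0.8 * 0.5)
  # two blocks separated by a zero row are two detections
  m2 <- z; m2[1:2, 1:2] <- 1; m2[5:6, 1:2] <- 1
  expect_equal(nrow(extract_boxes(relevance_map(m2), 1)), 2L)
  # diagonal touch is one component under 8-connectivity
  m3 <- z; m3[1, 1] <- 1; m3[2, 2] <- 1
  expect_equal(nrow(extract_boxes(relevance_map(m3), 1)), 1L)
  # min_area drops small components
  expect_equal(nrow(extract_boxes(relevance_map(m2), 1, min_area = 5)), 0L)
})

test_that("b disjoint blocks yield exactly b detections, up to b = 5", {
  for (b in 1:5) {
    m <- matrix(0, 40, 40)
    for (i in seq_len(b)) m[(8 * i - 6):(8 * i - 4), 3:6] <- 1
    expect_equal(nrow(extract_boxes(relevance_map(m), 1)), b)
  }
})

test_that("greedy matching consumes each ground-truth box once", {
  gt <- data.frame(image_id = "a", x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  none <- match_detections(detection_frame(), gt, 0.5)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "n_gt"), 1L)
  exact <- detection_frame("a", 0, 0, 10, 10, 0.9)
  expect_true(match_detections(exact, gt, 0.5)$tp)
  # two detections over one GT: higher confidence wins, other is FP
  two <- rbind(detection_frame("a", 0, 0, 10, 10, 0.4),
               detection_frame("a", 1, 0, 11, 10, 0.8))
  lab <- match_detections(two, gt, 0.5)
  expect_equal(lab$tp, c(TRUE, FALSE))
  expect_equal(lab$confidence, c(0.8, 0.4))
  # detection on an unknown image is a false positive
  stray <- detection_frame("zz", 0, 0, 10, 10, 1)
  expect_false(match_detections(stray, gt, 0.1)$tp)
})

test_that("PR curve and AP reproduce the running-count worked example", {
  # 2 GT boxes; detections labelled TP, FP, TP by confidence order
  gt <- rbind(data.frame(image_id = "a", x_min = 0, y_min = 0, x_max = 10, y_max = 10),
              data.frame(image_id = "a", x_min = 30, y_min = 30, x_max = 40, y_max = 40))
  dets <- rbind(detection_frame("a", 0, 0, 10, 10, 0.9),     # TP
                detection_frame("a", 60, 60, 70, 70, 0.8),   # FP
                detection_frame("a", 30, 30, 40, 40, 0.7))   # TP
  curve <- pr_curve(dets, gt, 0.5)
  expect_equal(curve$precision, c(1, 0.5, 2 / 3))
  expect_equal(curve$recall, c(0.5, 0.5, 1))
  expect_false(is.unsorted(curve$recall))
  expect_equal(average_precision(curve), 0.5 * 1 + 0 * 0.5 + 0.5 * (2 / 3))
  # single perfect detection reaches (1, 1) and AP 1
  one <- pr_curve(detection_frame("a", 0, 0, 10, 10, 1), gt[1, ], 0.5)
  expect_equal(unlist(one[, c("precision", "recall")]), c(1, 1),
               ignore_attr = TRUE)
  expect_equal(average_precision(one), 1)
  # all false positives: zero precision and recall everywhere
  bad <- pr_curve(detection_frame("a", 60, 60, 70, 70, 1), gt, 0.5)
  expect_equal(bad$precision, 0)
  expect_equal(bad$recall, 0)
  expect_equal(average_precision(bad), 0)
  expect_equal(average_precision(pr_curve(detection_frame(), gt, 0.5)), 0)
  expect_error(pr_curve(dets, gt[0, ], 0.5), "undefined")
})

test_that("AP agrees with an independent brute-force sweep on 100 instances", {
  set.seed(77)
  for (i in 1:100) {
    inst <- random_eval_instance()
    thr <- runif(1, 0.1, 0.6)
    expect_equal(average_precision(pr_curve(inst$dets, inst$gt, thr)),
                 ap_bruteforce(inst$dets, inst$gt, thr), tolerance = 1e-12)
  }
})

test_that("AP is non-increasing in the IoU threshold and mAP decomposes", {
  set.seed(78)
  thresholds <- seq(0.1, 0.6, length.out = 10)
  for (i in 1:30) {
    inst <- random_eval_instance()
    aps <- vapply(thresholds, function(t)
      average_precision(pr_curve(inst$dets, inst$gt, t)), numeric(1))
    expect_true(all(diff(aps) <= 1e-12))
    m <- mean_average_precision(inst$dets, inst$gt, thresholds)
    expect_equal(m, mean(aps), tolerance = 1e-12)
    expect_true(m <= aps[1] + 1e-12 && m >= aps[10] - 1e-12)
  }
  expect_error(mean_average_precision(detection_frame(),
                                      data.frame(image_id = "a", x_min = 0,
                                                 y_min = 0, x_max = 1, y_max = 1),
                                      numeric(0)), "non-empty")
})

test_that("mean_image_iou pairs boxes greedily and averages over images", {
  gt <- rbind(data.frame(image_id = "a", x_min = 0, y_min = 0, x_max = 10, y_max = 10),
              data.frame(image_id = "a", x_min = 30, y_min = 30, x_max = 40, y_max = 40))
  perfect <- rbind(detection_frame("a", 0, 0, 10, 10, 1),
                   detection_frame("a", 30, 30, 40, 40, 1))
  expect_equal(mean_image_iou(perfect, gt), 1)
  expect_equal(mean_image_iou(detection_frame(), gt), 0)
  expect_equal(mean_image_iou(detection_frame("a", 0, 0, 10, 10, 1), gt), 0.5)
  # a detection cannot serve two GT boxes
  shared <- detection_frame("a", 0, 0, 40, 40, 1)
  expect_equal(mean_image_iou(shared, gt),
               mean(c(100 / 1600, 0)))
  # averaged over images with boxes only
  gt2 <- rbind(gt, data.frame(image_id = "b", x_min = 0, y_min = 0,
                              x_max = 10, y_max = 10))
  expect_equal(mean_image_iou(perfect, gt2), mean(c(1, 0)))
})

test_that("localization_summary returns the JSON-ready record", {
  gt <- data.frame(image_id = "a", x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  res <- localization_summary(detection_frame("a", 0, 0, 10, 10, 1), gt)
  expect_equal(res$iou_mean, 1)
  expect_equal(res$map, 1)
  expect_length(res$ap_per_threshold, 10L)
  expect_equal(res$n_images, 1L)
  expect_equal(res$n_gt_boxes, 1L)
})
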