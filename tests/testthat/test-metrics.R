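test_that("iou handles identity, disjoint and partial overlap", {
  a <- rect(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, rect(10, 10, 2, 2)), 0)
  # 1-pixel overlap over 7-pixel union, checked against rasterised counting
  b <- rect(1, 1, 2, 2)
  expect_equal(iou(a, b), 1 / 7)
  expect_equal(iou(a, b), brute_iou(a, b))
  set.seed(51)
  for (k in 1:25) {
    r1 <- rect(sample(0:10, 1), sample(0:10, 1), sample(1:12, 1), sample(1:12, 1))
    r2 <- rect(sample(0:10, 1), sample(0:10, 1), sample(1:12, 1), sample(1:12, 1))
    expect_equal(iou(r1, r2), brute_iou(r1, r2))
  }
})

test_that("match_detections counts TP/FP/FN per the greedy convention", {
  gts <- data.frame(label = c("Head", "Tail"), x = c(0L, 20L), y = c(0L, 0L),
                    width = c(10L, 10L), height = c(10L, 10L))
  exact <- detections(gts$label, gts$x, gts$y, gts$width, gts$height,
                      c(0.9, 0.8))
  c1 <- match_detections(exact, gts, 0.5)
  expect_identical(c(c1$tp, c1$fp, c1$fn, c1$tn), c(2L, 0L, 0L, 0L))

  # IoU 0.3 < threshold 0.5: the prediction is FP, the gt FN
  low <- detections("Head", 0L, 0L, 10L, 10L, 0.9)
  gt1 <- data.frame(label = "Head", x = 7L, y = 0L, width = 10L, height = 10L)
  expect_equal(iou(rect(0, 0, 10, 10), rect(7, 0, 10, 10)), 3 / 17,
               tolerance = 1e-12)
  c2 <- match_detections(low, gt1, 0.5)
  expect_identical(c(c2$tp, c2$fp, c2$fn), c(0L, 1L, 1L))

  # 3 preds vs 2 gts with mixed overlaps: greedy equals the exhaustive
  # optimal assignment on this instance
  gts3 <- data.frame(label = rep("Dorsum", 2), x = c(0L, 12L), y = c(0L, 0L),
                     width = c(10L, 10L), height = c(10L, 10L))
  preds3 <- detections(rep("Dorsum", 3), c(1L, 11L, 30L), c(0L, 0L, 0L),
                       c(10L, 10L, 10L), c(10L, 10L, 10L), c(0.9, 0.8, 0.7))
  c3 <- match_detections(preds3, gts3, 0.5)
  expect_identical(c3$tp, brute_max_matches(preds3, gts3, 0.5))
  expect_identical(c3$tp + c3$fp, nrow(preds3))
  expect_identical(c3$tp + c3$fn, nrow(gts3))
})

test_that("matching conserves prediction and ground-truth counts", {
  set.seed(52)
  for (k in 1:30) {
    np <- sample(0:6, 1); ng <- sample(1:5, 1)
    preds <- detections(sample(c("Head", "Tail"), np, TRUE),
                        sample(0:30, np, TRUE), sample(0:30, np, TRUE),
                        sample(5:15, np, TRUE), sample(5:15, np, TRUE),
                        runif(np))
    gts <- data.frame(label = sample(c("Head", "Tail"), ng, TRUE),
                      x = sample(0:30, ng, TRUE), y = sample(0:30, ng, TRUE),
                      width = sample(5:15, ng, TRUE),
                      height = sample(5:15, ng, TRUE))
    cc <- match_detections(preds, gts, 0.5)
    expect_identical(cc$tp + cc$fp, np)
    expect_identical(cc$tp + cc$fn, ng)
  }
})

test_that("precision_recall_f1 follows the defining ratios", {
  r <- precision_recall_f1(confusion_counts(tp = 3L, fp = 1L, fn = 2L))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$f1, 2 * 0.45 / 1.35)
  expect_false(r$degenerate)

  deg <- precision_recall_f1(confusion_counts(tp = 0L, fp = 0L, fn = 5L))
  expect_equal(c(deg$precision, deg$recall, deg$f1), c(0, 0, 0))
  expect_true(deg$degenerate)

  # P = R = x implies F1 = x
  for (x in c(0.2, 0.5, 0.9)) {
    cc <- confusion_counts(tp = round(100 * x), fp = round(100 * (1 - x)),
                           fn = round(100 * (1 - x)))
    r2 <- precision_recall_f1(cc)
    expect_equal(r2$f1, r2$precision)
  }
})

test_that("average_precision integrates the monotone envelope", {
  flat <- data.frame(recall = c(0.2, 0.6, 1), precision = c(1, 1, 1))
  expect_equal(average_precision(flat), 1)

  step <- data.frame(recall = c(0.5, 1), precision = c(1, 0))
  expect_equal(average_precision(step), 0.5)

  expect_error(average_precision(data.frame(recall = numeric(),
                                            precision = numeric())),
               class = "lizardtherm_value_error")
})

test_that("average_precision matches fine-grid integration on random curves", {
  set.seed(53)
  for (k in 1:40) {
    pts <- random_pr_points(sample(3:12, 1))
    expect_equal(average_precision(pts), ap_grid_oracle(pts), tolerance = 2e-3)
  }
})

test_that("average_precision is stable under duplicates and monotone in precision", {
  set.seed(54)
  for (k in 1:20) {
    pts <- random_pr_points(8)
    dup <- rbind(pts, pts[sample(8, 3), ])
    expect_equal(average_precision(dup), average_precision(pts))
    up <- pts
    up$precision <- pmin(1, up$precision + runif(8, 0, 0.2))
    expect_gte(average_precision(up), average_precision(pts) - 1e-12)
  }
})

test_that("mean_average_precision averages per-class APs", {
  expect_equal(mean_average_precision(c(A = 0.8, B = 0.6)), 0.7)
  expect_equal(mean_average_precision(c(solo = 0.42)), 0.42)
  set.seed(55)
  aps <- runif(7)
  names(aps) <- lizard_classes()
  expect_equal(mean_average_precision(aps), sum(aps) / 7)
  expect_error(mean_average_precision(numeric()),
               class = "lizardtherm_value_error")
})

test_that("evaluate_detections scores a perfect detector at 1 everywhere", {
  scene <- make_scene(seed = 56)
  gt <- scene$gt_boxes
  preds <- detections(gt$label, gt$x, gt$y, gt$width, gt$height,
                      rep(0.95, nrow(gt)))
  tbl <- evaluate_detections(preds, gt)
  expect_identical(nrow(tbl), 8L)   # 7 classes + ALL
  expect_true(all(tbl$precision == 1))
  expect_true(all(tbl$recall == 1))
  expect_true(all(tbl$ap50 == 1))
  expect_true(all(tbl$ap50_95 == 1))
})
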