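test_that("IoU matches hand-computed cases and is a symmetric [0,1] quantity", {
  a <- bbox(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, bbox(10, 10, 12, 12)), 0)
  # areas 4 and 4, intersection 1, union 7
  expect_equal(iou(a, bbox(1, 1, 3, 3)), 1 / 7)
  # touching edges do not intersect under the half-open convention
  expect_equal(iou(a, bbox(2, 0, 4, 2)), 0)

  set.seed(41)
  for (k in 1:50) {
    b1 <- bbox(runif(1, 0, 5), runif(1, 0, 5), runif(1, 6, 10), runif(1, 6, 10))
    b2 <- bbox(runif(1, 0, 5), runif(1, 0, 5), runif(1, 6, 10), runif(1, 6, 10))
    v <- iou(b1, b2)
    expect_identical(v, iou(b2, b1))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("average precision reproduces hand-worked cases", {
  gt1 <- data.frame(image_id = "a", xmin = 0, ymin = 0, xmax = 10, ymax = 10)
  d_perfect <- data.frame(image_id = "a", xmin = 0, ymin = 0, xmax = 10,
                          ymax = 10, score = 0.9)
  expect_equal(average_precision(d_perfect, gt1, 0.5), 1)

  # higher-scored detection is a false positive, lower-scored one matches:
  # precision envelope max(0, 1/2) over the full recall range
  d2 <- data.frame(image_id = "a",
                   xmin = c(50, 0), ymin = c(50, 0),
                   xmax = c(60, 10), ymax = c(60, 10),
                   score = c(0.9, 0.8))
  expect_equal(average_precision(d2, gt1, 0.5), 0.5)

  expect_equal(average_precision(empty_detections(), gt1, 0.5), 0)
  expect_error(average_precision(d_perfect, gt1[0, ], 0.5), "ground-truth")
})

test_that("average precision equals the per-recall-level oracle on random instances", {
  set.seed(7)
  for (k in 1:40) {
    n_gt <- sample(1:4, 1); n_det <- sample(0:6, 1)
    gts <- data.frame(image_id = sample(c("a", "b"), n_gt, replace = TRUE),
                      xmin = runif(n_gt, 0, 50), ymin = runif(n_gt, 0, 50))
    gts$xmax <- gts$xmin + runif(n_gt, 5, 25)
    gts$ymax <- gts$ymin + runif(n_gt, 5, 25)
    if (n_det == 0) next
    src <- gts[sample(n_gt, n_det, replace = TRUE), ]
    dets <- data.frame(image_id = src$image_id,
                       xmin = src$xmin + rnorm(n_det, 0, 4),
                       ymin = src$ymin + rnorm(n_det, 0, 4))
    dets$xmax <- dets$xmin + (src$xmax - src$xmin) * runif(n_det, 0.7, 1.3)
    dets$ymax <- dets$ymin + (src$ymax - src$ymin) * runif(n_det, 0.7, 1.3)
    dets$score <- sample(seq(0.1, 0.9, by = 0.01), n_det)  # distinct scores
    for (thr in c(0.3, 0.5, 0.75))
      expect_equal(average_precision(dets, gts, thr), ap_oracle(dets, gts, thr))
  }
})

test_that("AP is invariant under strictly monotone score transforms", {
  set.seed(11)
  gts <- data.frame(image_id = "a", xmin = c(0, 30), ymin = c(0, 30),
                    xmax = c(10, 45), ymax = c(10, 45))
  dets <- data.frame(image_id = "a", xmin = c(1, 29, 60), ymin = c(1, 31, 60),
                     xmax = c(10, 44, 70), ymax = c(11, 44, 70),
                     score = c(0.3, 0.6, 0.9))
  base <- average_precision(dets, gts, 0.5)
  for (f in list(function(s) s^3, function(s) exp(s), function(s) 10 * s - 2)) {
    d2 <- dets; d2$score <- f(d2$score)
    expect_equal(average_precision(d2, gts, 0.5), base)
  }
})

test_that("map_at keeps per-threshold APs distinct and reports IoU dispersion", {
  gts <- data.frame(image_id = "a", xmin = 0, ymin = 0, xmax = 20, ymax = 20)
  # stub with IoU exactly 20*12/(2*20*20 - 20*12) ~ 0.429 at overlap 12
  stub <- data.frame(image_id = "a", xmin = 0, ymin = 8, xmax = 20, ymax = 28,
                     score = 0.9, label = "coil")
  ev <- map_at(stub, gts, thresholds = c(0.75, 0.4))
  expect_named(ev$ap_at_threshold, c("ap@0.75", "ap@0.4"))
  expect_equal(unname(ev$ap_at_threshold), c(0, 1))
  expect_equal(ev$map_score, 0)  # first threshold
  expect_equal(ev$mean_iou, iou(bbox(0, 0, 20, 20), bbox(0, 8, 20, 28)))

  perfect <- cbind(gts, score = 1, label = "coil")
  expect_equal(map_at(perfect, gts, 0.75)$map_score, 1)
})

test_that("patient-wise k-fold covers every patient exactly once with balanced folds", {
  ids <- rep(1:13, times = c(30, 25, 20, 15, 12, 10, 9, 8, 8, 8, 6, 5, 4))
  folds <- groupwise_kfold(ids, k = 5, seed = 3)
  sizes <- lengths(lapply(folds, `[[`, "val_patients"))
  expect_true(all(sizes %in% c(2, 3)))  # 13 patients over 5 folds
  all_val <- unlist(lapply(folds, `[[`, "val_patients"))
  expect_equal(sort(all_val), 1:13)     # disjoint and exhaustive
  for (f in folds) {
    expect_length(intersect(ids[f$val], setdiff(unique(ids), f$val_patients)), 0)
    expect_length(intersect(f$val, f$train), 0)
    expect_equal(sort(c(f$val, f$train)), seq_along(ids))
  }
  expect_identical(groupwise_kfold(ids, 5, seed = 3),
                   groupwise_kfold(ids, 5, seed = 3))
  expect_error(groupwise_kfold(1:4, k = 5), "fewer")
})

test_that("Mann-Whitney U handles separation, symmetry and tie conventions", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_two_sided, 0.1)  # 2 / choose(6, 3)
  expect_identical(r$method, "exact")
  expect_false(r$reject)

  x <- c(2, 2, 5, 7)
  r2 <- mann_whitney_u(x, x)
  expect_equal(r2$u_statistic, length(x)^2 / 2)  # identical multisets
  expect_identical(r2$method, "normal_tie_corrected")

  set.seed(5)
  for (k in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(1000, n1 + n2)  # no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    got <- mann_whitney_u(x, y)
    ref <- mwu_exact_oracle(x, y)
    expect_equal(got$u_statistic, ref$u)
    expect_equal(got$p_two_sided, ref$p)
    # complementarity of the two one-sided statistics
    expect_equal(got$u_statistic + mann_whitney_u(y, x)$u_statistic, n1 * n2)
  }
})
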