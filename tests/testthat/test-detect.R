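test_that("a single dark disk yields one keypoint with accurate center and radius", {
  img <- disk_image(128, centers = rbind(c(60, 70)), radii = 20)
  kp <- detect_blobs(img, blob_params(gauss_sigma = 2, min_area = 50,
                                      max_area = 5000))
  expect_equal(nrow(kp), 1)
  expect_lt(abs(kp$row - 60), 1)
  expect_lt(abs(kp$col - 70), 1)
  expect_lt(abs(kp$radius - 20) / 20, 0.15)
})

test_that("uniform images yield no keypoints", {
  expect_equal(nrow(detect_blobs(matrix(0.5, 64, 64), blob_params())), 0)
  expect_equal(nrow(detect_blobs(matrix(0, 64, 64), blob_params())), 0)
})

test_that("nearby blobs merge into a single keypoint under min_dist", {
  img <- disk_image(96, centers = rbind(c(40, 40), c(40, 43)), radii = c(8, 8))
  kp <- detect_blobs(img, blob_params(gauss_sigma = 1.5, min_area = 20,
                                      max_area = 3000,
                                      min_dist_between_blobs = 10))
  expect_equal(nrow(kp), 1)
  expect_lt(abs(kp$col - 41.5), 2)  # between the two centers

  # well-separated disks with a small merge radius stay distinct
  img2 <- disk_image(96, centers = rbind(c(25, 25), c(70, 70)), radii = c(8, 8))
  kp2 <- detect_blobs(img2, blob_params(gauss_sigma = 1.5, min_area = 20,
                                        max_area = 3000,
                                        min_dist_between_blobs = 10))
  expect_equal(nrow(kp2), 2)
})

test_that("detect_blobs matches the literal flood-fill sweep oracle on small images", {
  set.seed(19)
  for (k in 1:8) {
    n_blobs <- sample(0:2, 1)
    img <- if (n_blobs == 0) {
      matrix(runif(64 * 64, 0.8, 1), 64, 64)  # textured, blob-free
    } else {
      ctr <- cbind(runif(n_blobs, 15, 49), runif(n_blobs, 15, 49))
      disk_image(64, ctr, radii = runif(n_blobs, 5, 9)) +
        matrix(runif(64 * 64, 0, 0.05), 64, 64)
    }
    p <- blob_params(gauss_sigma = 1.5, min_area = 15, max_area = 2000,
                     n_thresholds = 16, min_dist_between_blobs = 8)
    got <- detect_blobs(img, p)
    ref <- blob_oracle(img, p)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(got) > 0) {
      expect_equal(got$row, ref$row, tolerance = 1e-10)
      expect_equal(got$col, ref$col, tolerance = 1e-10)
      expect_equal(got$support_area, ref$support_area, tolerance = 1e-10)
      expect_equal(got$n_thresholds, ref$n_thresholds)
    }
  }
})

test_that("8-connected labelling joins diagonals and matches flood fill", {
  m <- matrix(0, 6, 6)
  m[cbind(c(1, 2, 3), c(1, 2, 3))] <- 1  # diagonal chain: one component
  m[6, 6] <- 1
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 2])
  set.seed(2)
  for (k in 1:10) {
    b <- matrix(runif(20 * 20) < 0.35, 20, 20)
    got <- label_components(b)
    ref <- floodfill_label8(b)
    expect_equal(max(got), max(ref))
    # identical partitions up to label naming
    expect_equal(length(unique(paste(got[b], ref[b]))), max(ref))
  }
})

test_that("shrinking the area gate never increases the number of keypoints", {
  sc <- render_frame(phantom_spec(seed = 3))
  pf <- prepare_frame(sc$frame, sc$truth$boxes)
  base <- blob_params_from_truth(pf$boxes)
  n_base <- nrow(detect_blobs(pf$pixels, base))
  for (f in c(0.8, 0.5)) {
    shrunk <- base
    mid <- sqrt(base$min_area * base$max_area)
    shrunk$min_area <- mid * (base$min_area / mid)^f
    shrunk$max_area <- mid * (base$max_area / mid)^f
    expect_lte(nrow(detect_blobs(pf$pixels, shrunk)), n_base)
  }
})

test_that("keypoint centers are stable under faint zero-mean noise", {
  img <- disk_image(128, centers = rbind(c(64, 64)), radii = 18)
  p <- blob_params(gauss_sigma = 3, min_area = 100, max_area = 5000)
  kp0 <- detect_blobs(img, p)
  set.seed(23)
  for (k in 1:5) {
    noisy <- img + matrix(rnorm(128 * 128, 0, 0.01), 128, 128)
    kp <- detect_blobs(noisy, p)
    expect_equal(nrow(kp), 1)
    expect_lt(sqrt((kp$row - kp0$row)^2 + (kp$col - kp0$col)^2), 1)
  }
})

test_that("keypoints become square circumscribed boxes, clipped at borders", {
  kps <- data.frame(row = 50, col = 50, radius = 10, support_area = pi * 100,
                    n_thresholds = 5)
  det <- keypoints_to_detections(kps, c(512, 512))
  expect_equal(unlist(det[1, 1:4]),
               c(xmin = 40, ymin = 40, xmax = 60, ymax = 60))
  expect_equal(det$score, 1)
  expect_equal(det$label, "coil")

  border <- data.frame(row = 2, col = 2, radius = 10, support_area = pi * 100,
                       n_thresholds = 5)
  db <- keypoints_to_detections(border, c(64, 64))
  expect_equal(unlist(db[1, 1:4]), c(xmin = 0, ymin = 0, xmax = 12, ymax = 12))
  expect_gt((db$xmax - db$xmin) * (db$ymax - db$ymin), 0)

  expect_equal(nrow(keypoints_to_detections(empty_keypoints_df(), c(64, 64))), 0)
})

test_that("detector backends satisfy the pipeline contract", {
  sc <- render_frame(phantom_spec(seed = 2))
  pf <- prepare_frame(sc$frame, sc$truth$boxes)

  d_blob <- run_backend(backend_blob(blob_params_from_truth(pf$boxes)),
                        pf$pixels)
  expect_true(all(c("xmin", "ymin", "xmax", "ymax", "score", "label") %in%
                    names(d_blob)))
  expect_true(all(d_blob$xmax <= 512 & d_blob$ymax <= 512))

  d_stub <- run_backend(backend_stub(pf$boxes, score = 0.99), pf$pixels)
  expect_equal(nrow(d_stub), nrow(pf$boxes))
  expect_equal(d_stub$score, rep(0.99, nrow(pf$boxes)))

  # a silent backend produces a clean "no detection" outcome
  expect_equal(nrow(run_backend(backend_empty(), pf$pixels)), 0)

  # a crashing backend is contained: warning + empty result
  boom <- function(pixels) stop("boom")
  expect_warning(d_err <- run_backend(boom, pf$pixels), "boom")
  expect_equal(nrow(d_err), 0)
})

test_that("sparse irregular coils are localized worse than dense ones on average", {
  best_iou <- function(sc) {
    pf <- prepare_frame(sc$frame, sc$truth$boxes)
    det <- run_backend(backend_blob(blob_params_from_truth(pf$boxes)),
                       pf$pixels)
    if (nrow(det) == 0) return(0)
    gt <- df_box(pf$boxes)
    max(vapply(seq_len(nrow(det)), function(i) iou(det_bbox(det, i), gt),
               numeric(1)))
  }
  seeds <- 31:38
  dense <- vapply(seeds, function(s) best_iou(render_frame(
    phantom_spec(seed = s, coil_mode = "spiral", n_distractors = 0))),
    numeric(1))
  sparse <- vapply(seeds, function(s) best_iou(render_frame(
    phantom_spec(seed = s, coil_mode = "irregular", n_distractors = 0))),
    numeric(1))
  # the wire of a loose framing coil encloses mostly background, so its
  # blurred basin is shallower and the fitted box less faithful
  expect_lt(mean(sparse), mean(dense))
})
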