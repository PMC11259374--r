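#' Parameters for the multi-threshold dark-blob detector
#'
#' The detector binarizes a Gaussian-blurred frame at a sweep of
#' thresholds, extracts connected components per threshold, groups
#' component centroids across thresholds and keeps groups that satisfy an
#' area gate and a repeatability gate. Polarity is fixed to dark: coils
#' are the strongest absorbers, so candidate pixels are those *below*
#' each threshold.
#'
#' When `threshold_min`/`threshold_max` are `NULL`, the sweep spans the
#' blurred frame's intensity quantiles `threshold_quantiles` (default 1st
#' to 60th percentile) with `n_thresholds` evenly spaced levels -- robust
#' to intensity windowing since it adapts to the frame's own histogram.
#' The lower quantile bounds the smallest resolvable blob: the darkest
#' `q_lo` fraction of pixels must not already exceed the smallest
#' expected coil core (see [blob_params_from_truth()]).
#'
#' @param gauss_sigma Gaussian blur sigma in pixels (default 9).
#' @param threshold_min,threshold_max Sweep limits in image-intensity
#'   units, or `NULL` for the percentile defaults.
#' @param threshold_step Sweep step; `NULL` uses `n_thresholds` evenly
#'   spaced levels instead.
#' @param n_thresholds Number of levels when `threshold_step` is `NULL`.
#' @param threshold_quantiles Quantiles `c(lo, hi)` of the blurred frame
#'   used when the sweep limits are `NULL`.
#' @param min_dist_between_blobs Centroid grouping radius in pixels;
#'   blobs closer than this (within or across thresholds) merge into one
#'   keypoint.
#' @param min_area,max_area Area gate in pixels^2, applied to
#'   per-threshold components and to the final group support area. The
#'   intended use is to set these from the smallest and largest coil the
#'   deployment expects to see.
#' @param min_repeatability Minimum number of distinct thresholds at
#'   which a group must appear (default 2).
#' @return An object of class `"blob_params"`.
#' @export
blob_params <- function(gauss_sigma = 9,
                        threshold_min = NULL, threshold_max = NULL,
                        threshold_step = NULL, n_thresholds = 64L,
                        threshold_quantiles = c(0.01, 0.60),
                        min_dist_between_blobs = 10,
                        min_area = 100, max_area = 10000,
                        min_repeatability = 2L) {
  if (gauss_sigma <= 0) stop("blob_params: gauss_sigma must be > 0")
  if (!is.null(threshold_min) && !is.null(threshold_max) &&
      threshold_min >= threshold_max)
    stop("blob_params: threshold_min must be < threshold_max")
  if (min_area <= 0 || max_area <= 0 || min_area >= max_area)
    stop("blob_params: need 0 < min_area < max_area")
  if (min_dist_between_blobs < 0)
    stop("blob_params: min_dist_between_blobs must be >= 0")
  if (length(threshold_quantiles) != 2 ||
      threshold_quantiles[1] >= threshold_quantiles[2] ||
      any(threshold_quantiles < 0) || any(threshold_quantiles > 1))
    stop("blob_params: threshold_quantiles must be c(lo, hi) in [0, 1]")
  structure(list(gauss_sigma = gauss_sigma,
                 threshold_min = threshold_min, threshold_max = threshold_max,
                 threshold_step = threshold_step,
                 n_thresholds = as.integer(n_thresholds),
                 threshold_quantiles = threshold_quantiles,
                 min_dist_between_blobs = min_dist_between_blobs,
                 min_area = min_area, max_area = max_area,
                 min_repeatability = as.integer(min_repeatability),
                 polarity = "dark"),
            class = "blob_params")
}

#' Separable Gaussian blur with reflect-101 boundary
#'
#' Exact separable convolution with a truncated Gaussian kernel (radius
#' `ceiling(3*sigma)`); out-of-range taps are reflected about the edge
#' pixel (reflect-101), so constant images are exactly preserved and
#' small fixtures blur without artifacts.
#'
#' @param pixels Numeric matrix.
#' @param sigma Gaussian sigma in pixels, > 0.
#' @return Blurred matrix, same size.
#' @export
gaussian_blur <- function(pixels, sigma) {
  stopifnot(is.matrix(pixels), sigma > 0)
  k <- gauss_kernel(sigma)
  blur_operator(nrow(pixels), k) %*% pixels %*% t(blur_operator(ncol(pixels), k))
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# n x n dense operator applying the 1-D kernel along a length-n axis with
# reflect-101 boundary (index i reflects to 2-i below 1, 2n-i above n).
blur_operator <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  A <- matrix(0, n, n)
  for (o in -r:r) {
    j <- seq_len(n) + o
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    j <- pmin(pmax(j, 1L), n)  # guard for kernels wider than the axis
    A[cbind(seq_len(n), j)] <- A[cbind(seq_len(n), j)] + kernel[o + r + 1L]
  }
  A
}

# Core 8-connected labelling on the flattened image: 4-connected labels
# from EBImage::bwlabel, then a union-find merge of diagonally adjacent
# labels using column-major index arithmetic (no matrix copies).
# Returns list(idx = linear indices of foreground pixels, labels = dense
# 1..n component label per foreground pixel, nr, nc).
label8_core <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- EBImage::imageData(EBImage::bwlabel(binary + 0))
  v <- as.vector(lab)
  idx <- which(v > 0)
  if (length(idx) == 0)
    return(list(idx = idx, labels = integer(0), nr = nr, nc = nc))
  a <- as.integer(v[idx])
  nlab <- max(a)
  if (nlab > 1) {
    r <- (idx - 1L) %% nr
    cc <- (idx - 1L) %/% nr
    pairs <- NULL
    for (off in c(nr + 1L, -(nr - 1L))) {   # down-right, down-left diagonals
      ok <- r < nr - 1L & (if (off > 0) cc < nc - 1L else cc > 0L)
      j <- idx[ok] + off
      b <- v[j]
      sel <- b > 0 & b != a[ok]
      if (any(sel))
        pairs <- rbind(pairs, cbind(a[ok][sel], as.integer(b[sel])))
    }
    if (!is.null(pairs) && nrow(pairs) > 0) {
      pairs <- unique(pairs)
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
        i
      }
      for (p in seq_len(nrow(pairs))) {
        x <- find(pairs[p, 1]); y <- find(pairs[p, 2])
        if (x != y) parent[y] <- x
      }
      roots <- vapply(seq_len(nlab), find, integer(1))
      a <- roots[a]
    }
  }
  list(idx = idx, labels = match(a, sort(unique(a))), nr = nr, nc = nc)
}

#' Label connected components with 8-connectivity
#'
#' 4-connected labelling (via `EBImage::bwlabel`) followed by a
#' union-find merge of diagonally adjacent labels, yielding standard
#' 8-connected components with dense labels `1..n`.
#'
#' @param binary Logical or 0/1 numeric matrix.
#' @return Integer matrix of the same size; 0 = background.
#' @export
label_components <- function(binary) {
  stopifnot(is.matrix(binary))
  core <- label8_core(binary)
  out <- matrix(0L, core$nr, core$nc)
  out[core$idx] <- core$labels
  out
}

# Area-gated component centroids for one binary image: per-component area
# and 0-based (row, col) centroid, components outside [min_area, max_area]
# dropped before any centroid work.
component_stats <- function(binary, min_area = 0, max_area = Inf) {
  core <- label8_core(binary)
  if (length(core$idx) == 0)
    return(data.frame(row = numeric(0), col = numeric(0), area = numeric(0)))
  area <- tabulate(core$labels)
  keep <- which(area >= min_area & area <= max_area)
  if (length(keep) == 0)
    return(data.frame(row = numeric(0), col = numeric(0), area = numeric(0)))
  sel <- core$labels %in% keep
  idx <- core$idx[sel]
  l <- match(core$labels[sel], keep)
  r0 <- (idx - 1L) %% core$nr
  c0 <- (idx - 1L) %/% core$nr
  ka <- area[keep]
  data.frame(row = rowsum(r0, l)[, 1] / ka,
             col = rowsum(c0, l)[, 1] / ka,
             area = ka)
}

#' Detect dark blobs by multi-threshold binarization
#'
#' Implements the five-step detection core: (1) Gaussian blur to enhance
#' variance and diminish local peaks; (2) binarize the blurred frame at
#' each threshold in the sweep (dark polarity: pixel < threshold);
#' (3) extract 8-connected components per binary image as candidate blobs
#' with centroid and area, gated to `[min_area, max_area]`; (4) group
#' candidates across thresholds whose centroids lie within
#' `min_dist_between_blobs` of an existing group's (area-weighted) center;
#' (5) keep groups whose mean member area passes the area gate and that
#' appear at `>= min_repeatability` thresholds. Each surviving group
#' becomes a keypoint with center = area-weighted mean centroid, support
#' area = mean member area and radius = `sqrt(support_area / pi)`.
#'
#' @param image Single-channel numeric matrix (typically a prepared,
#'   normalized frame).
#' @param params A [blob_params()].
#' @return Data frame of keypoints sorted by decreasing support area
#'   (ties by row then column): columns `row`, `col` (0-based centroid),
#'   `radius`, `support_area`, `n_thresholds`.
#' @export
detect_blobs <- function(image, params = blob_params()) {
  stopifnot(is.matrix(image), inherits(params, "blob_params"))
  blurred <- gaussian_blur(image, params$gauss_sigma)
  tmin <- params$threshold_min
  tmax <- params$threshold_max
  auto <- is.null(tmin) || is.null(tmax)
  q <- params$threshold_quantiles %||% c(0.01, 0.60)
  if (is.null(tmin)) tmin <- unname(stats::quantile(blurred, q[1]))
  if (is.null(tmax)) tmax <- unname(stats::quantile(blurred, q[2]))
  if (auto && tmax - tmin < 1e-8 * max(1, abs(tmax)))
    return(empty_keypoints())   # (near-)uniform image: nothing to detect
  if (!is.finite(tmin) || !is.finite(tmax) || tmin >= tmax)
    stop("detect_blobs: empty threshold sweep (min >= max)")
  thresholds <- if (is.null(params$threshold_step))
    seq(tmin, tmax, length.out = params$n_thresholds)
  else seq(tmin, tmax, by = params$threshold_step)
  if (length(thresholds) < 1) stop("detect_blobs: empty threshold sweep")

  # running groups: weighted-center sums plus per-member records
  sw <- swr <- swc <- numeric(0)
  members <- list()   # each: list(areas, tids)
  for (ti in seq_along(thresholds)) {
    st <- component_stats(blurred < thresholds[ti],
                          params$min_area, params$max_area)
    for (i in seq_len(nrow(st))) {
      r <- st$row[i]; cc <- st$col[i]; a <- st$area[i]
      j <- 0L
      if (length(sw) > 0) {
        d <- sqrt((swr / sw - r)^2 + (swc / sw - cc)^2)
        jmin <- which.min(d)
        if (d[jmin] <= params$min_dist_between_blobs) j <- jmin
      }
      if (j == 0L) {
        sw <- c(sw, a); swr <- c(swr, a * r); swc <- c(swc, a * cc)
        members[[length(members) + 1L]] <- list(areas = a, tids = ti)
      } else {
        sw[j] <- sw[j] + a; swr[j] <- swr[j] + a * r; swc[j] <- swc[j] + a * cc
        members[[j]]$areas <- c(members[[j]]$areas, a)
        members[[j]]$tids <- c(members[[j]]$tids, ti)
      }
    }
  }
  if (length(members) == 0) return(empty_keypoints())
  support <- vapply(members, function(m) mean(m$areas), numeric(1))
  nthr <- vapply(members, function(m) length(unique(m$tids)), numeric(1))
  keep <- support >= params$min_area & support <= params$max_area &
    nthr >= params$min_repeatability
  if (!any(keep)) return(empty_keypoints())
  out <- data.frame(row = (swr / sw)[keep], col = (swc / sw)[keep],
                    radius = sqrt(support[keep] / pi),
                    support_area = support[keep], n_thresholds = nthr[keep])
  out[order(-out$support_area, out$row, out$col), , drop = FALSE]
}

empty_keypoints <- function() {
  data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
             support_area = numeric(0), n_thresholds = numeric(0))
}

#' Convert blob keypoints to scored detections
#'
#' Each keypoint's circle is circumscribed by a square box
#' (center +/- radius), clipped to the image extent. The blob detector
#' produces no confidence estimate, so every detection carries the
#' constant score 1 (documented limitation; learned backends supply real
#' scores).
#'
#' @param kps Keypoint data frame from [detect_blobs()].
#' @param image_extent `c(width, height)` in pixels.
#' @return Detection data frame: `xmin`, `ymin`, `xmax`, `ymax`, `score`,
#'   `label` (always `"coil"`).
#' @export
keypoints_to_detections <- function(kps, image_extent) {
  if (is.null(kps) || nrow(kps) == 0) return(empty_detections())
  out <- lapply(seq_len(nrow(kps)), function(i) {
    b <- bbox_clip(bbox(kps$col[i] - kps$radius[i], kps$row[i] - kps$radius[i],
                        kps$col[i] + kps$radius[i], kps$row[i] + kps$radius[i]),
                   image_extent)
    data.frame(xmin = b[["xmin"]], ymin = b[["ymin"]],
               xmax = b[["xmax"]], ymax = b[["ymax"]],
               score = 1, label = "coil")
  })
  do.call(rbind, out)
}

#' Empty detection table
#' @return Zero-row detection data frame with the standard columns.
#' @export
empty_detections <- function() {
  data.frame(xmin = numeric(0), ymin = numeric(0), xmax = numeric(0),
             ymax = numeric(0), score = numeric(0), label = character(0))
}

#' Detector backends
#'
#' A detector backend is a pure function `f(pixels) -> detections` (a
#' data frame as returned by [keypoints_to_detections()]), deterministic
#' given its configuration. `backend_blob()` wraps the multi-threshold
#' blob detector; `backend_stub()` ignores the pixels and returns fixed
#' boxes (a test double standing in for a learned model);
#' `backend_empty()` never detects anything. [run_backend()] applies a
#' backend defensively: a backend error is logged as a warning and yields
#' an empty detection table instead of crashing the pipeline.
#'
#' @param params A [blob_params()] for the blob backend.
#' @param boxes Box data frame for the stub backend.
#' @param score Constant score attached by the stub backend.
#' @return A backend function.
#' @export
backend_blob <- function(params = blob_params()) {
  force(params)
  function(pixels) {
    keypoints_to_detections(detect_blobs(pixels, params),
                            image_extent = c(ncol(pixels), nrow(pixels)))
  }
}

#' @rdname backend_blob
#' @export
backend_stub <- function(boxes, score = 0.99) {
  boxes <- as_box_df(boxes)
  det <- if (nrow(boxes) == 0) empty_detections() else
    data.frame(xmin = boxes$xmin, ymin = boxes$ymin,
               xmax = boxes$xmax, ymax = boxes$ymax,
               score = score, label = "coil")
  function(pixels) det
}

#' @rdname backend_blob
#' @export
backend_empty <- function() {
  function(pixels) empty_detections()
}

#' @rdname backend_blob
#' @param backend A backend function.
#' @param pixels Single-channel numeric matrix.
#' @export
run_backend <- function(backend, pixels) {
  tryCatch(backend(pixels), error = function(e) {
    warning(sprintf("detector backend failed (%s); returning no detections",
                    conditionMessage(e)))
    empty_detections()
  })
}
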