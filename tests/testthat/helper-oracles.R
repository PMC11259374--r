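# Independent reference implementations used to cross-check the package.
# These share no code with the implementation paths they verify.

# Exact two-sided Mann-Whitney p by full enumeration of the C(n1+n2, n1)
# placements of sample x among the pooled ranks (valid when there are no
# ties). Two-sided p = 2 * min(P(U <= u), P(U >= u)), capped at 1.
mwu_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- rank(c(x, y))
  u_obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2, function(ix)
    sum(seq_len(n1 + n2)[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(all_u <= u_obs + 1e-9)
  p_ge <- mean(all_u >= u_obs - 1e-9)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# All-point-interpolated AP via the per-recall-level definition:
# AP = (1/npos) * sum over m of max precision at recall >= m/npos.
ap_oracle <- function(dets, gts, thr) {
  npos <- nrow(gts)
  ord <- order(-dets$score)
  matched <- rep(FALSE, npos)
  tp <- integer(0)
  for (i in ord) {
    best <- 0; jbest <- 0
    for (j in seq_len(npos)) {
      if (matched[j] || gts$image_id[j] != dets$image_id[i]) next
      v <- iou(bbox(dets$xmin[i], dets$ymin[i], dets$xmax[i], dets$ymax[i]),
               bbox(gts$xmin[j], gts$ymin[j], gts$xmax[j], gts$ymax[j]))
      if (v > best) { best <- v; jbest <- j }
    }
    if (jbest > 0 && best >= thr) { matched[jbest] <- TRUE; tp <- c(tp, 1L) }
    else tp <- c(tp, 0L)
  }
  rec <- cumsum(tp) / npos
  prec <- cumsum(tp) / seq_along(tp)
  lvl <- vapply(seq_len(npos) / npos, function(r) {
    p <- prec[rec >= r - 1e-12]
    if (length(p) == 0) 0 else max(p)
  }, numeric(1))
  mean(lvl)
}

# 8-connected flood-fill labelling by breadth-first search (slow, small
# images only).
floodfill_label8 <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!binary[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            binary[ii, jj] && lab[ii, jj] == 0) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Literal re-implementation of the multi-threshold blob sweep using the
# flood-fill labeller and explicit loops; mirrors the documented
# semantics step by step, sharing no code with detect_blobs().
blob_oracle <- function(image, params) {
  blurred <- gaussian_blur(image, params$gauss_sigma)
  q <- params$threshold_quantiles %||% c(0.01, 0.60)
  tmin <- params$threshold_min %||% unname(quantile(blurred, q[1]))
  tmax <- params$threshold_max %||% unname(quantile(blurred, q[2]))
  thresholds <- if (is.null(params$threshold_step))
    seq(tmin, tmax, length.out = params$n_thresholds)
  else seq(tmin, tmax, by = params$threshold_step)
  groups <- list()
  for (ti in seq_along(thresholds)) {
    lab <- floodfill_label8(blurred < thresholds[ti])
    for (l in seq_len(max(lab))) {
      px <- which(lab == l, arr.ind = TRUE)
      a <- nrow(px)
      if (a < params$min_area || a > params$max_area) next
      ctr <- c(mean(px[, 1]) - 1, mean(px[, 2]) - 1)
      joined <- FALSE
      if (length(groups) > 0) {
        cent <- t(vapply(groups, function(g) {
          w <- vapply(g, `[[`, numeric(1), "a")
          c(sum(w * vapply(g, `[[`, numeric(1), "r")) / sum(w),
            sum(w * vapply(g, `[[`, numeric(1), "c")) / sum(w))
        }, numeric(2)))
        d <- sqrt((cent[, 1] - ctr[1])^2 + (cent[, 2] - ctr[2])^2)
        k <- which.min(d)
        if (d[k] <= params$min_dist_between_blobs) {
          groups[[k]][[length(groups[[k]]) + 1]] <-
            list(r = ctr[1], c = ctr[2], a = a, t = ti)
          joined <- TRUE
        }
      }
      if (!joined)
        groups[[length(groups) + 1]] <- list(list(r = ctr[1], c = ctr[2],
                                                  a = a, t = ti))
    }
  }
  rows <- list()
  for (g in groups) {
    a <- vapply(g, `[[`, numeric(1), "a")
    supp <- mean(a)
    nthr <- length(unique(vapply(g, `[[`, numeric(1), "t")))
    if (supp < params$min_area || supp > params$max_area ||
        nthr < params$min_repeatability) next
    rows[[length(rows) + 1]] <- data.frame(
      row = sum(a * vapply(g, `[[`, numeric(1), "r")) / sum(a),
      col = sum(a * vapply(g, `[[`, numeric(1), "c")) / sum(a),
      radius = sqrt(supp / pi), support_area = supp, n_thresholds = nthr)
  }
  if (length(rows) == 0)
    return(data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
                      support_area = numeric(0), n_thresholds = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(-out$support_area, out$row, out$col), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic image: dark filled disk(s) on a bright background.
disk_image <- function(n = 64, centers, radii, bg = 1, fg = 0) {
  img <- matrix(bg, n, n)
  for (k in seq_len(nrow(centers))) {
    rr <- matrix(seq_len(n) - 1, n, n)
    cc <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
    img[(rr - centers[k, 1])^2 + (cc - centers[k, 2])^2 <= radii[k]^2] <- fg
  }
  img
}

det_bbox <- function(det, i = 1) {
  bbox(det$xmin[i], det$ymin[i], det$xmax[i], det$ymax[i])
}

df_box <- det_bbox

empty_keypoints_df <- function() {
  data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
             support_area = numeric(0), n_thresholds = numeric(0))
}
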