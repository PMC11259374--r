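#' Intersection over union (Jaccard index) of two boxes
#'
#' `|A intersect B| / |A union B|` with half-open box areas; 0 for
#' disjoint boxes.
#'
#' @param a,b [bbox()] objects.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  stopifnot(inherits(a, "bbox"), inherits(b, "bbox"))
  iw <- min(a[["xmax"]], b[["xmax"]]) - max(a[["xmin"]], b[["xmin"]])
  ih <- min(a[["ymax"]], b[["ymax"]]) - max(a[["ymin"]], b[["ymin"]])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

# IoU between row i of df1 and row j of df2 (box data frames).
iou_rows <- function(df1, i, df2, j) {
  iou(df_bbox(df1, i), df_bbox(df2, j))
}

#' Average precision of scored detections over a dataset
#'
#' Standard single-class VOC-style evaluation. Detections are sorted by
#' decreasing score; each detection greedily matches the not-yet-matched
#' ground-truth box (same image) of highest IoU, provided that IoU is at
#' least `iou_threshold`; otherwise it is a false positive. Each ground
#' truth matches at most once. AP is the area under the precision
#' envelope of the precision-recall curve (all-point interpolation,
#' VOC-2010 convention) or the classic 11-point average when
#' `method = "eleven_point"`.
#'
#' @param dets Detection data frame with columns `image_id`, `xmin`,
#'   `ymin`, `xmax`, `ymax`, `score`.
#' @param gts Ground-truth data frame with columns `image_id`, `xmin`,
#'   `ymin`, `xmax`, `ymax`. Must contain at least one box: AP is
#'   undefined on a dataset with no ground truth (error).
#' @param iou_threshold Matching threshold in `(0, 1]`.
#' @param method `"all_point"` (default) or `"eleven_point"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5,
                              method = c("all_point", "eleven_point")) {
  method <- match.arg(method)
  if (is.null(gts) || nrow(gts) == 0)
    stop("average_precision: no ground-truth boxes; AP is undefined")
  npos <- nrow(gts)
  if (is.null(dets) || nrow(dets) == 0) return(0)
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  gt_matched <- rep(FALSE, npos)
  tp <- numeric(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    cand <- which(gts$image_id == dets$image_id[i] & !gt_matched)
    if (length(cand) > 0) {
      ious <- vapply(cand, function(j) iou_rows(dets, i, gts, j), numeric(1))
      jbest <- which.max(ious)
      if (ious[jbest] >= iou_threshold) {
        tp[i] <- 1
        gt_matched[cand[jbest]] <- TRUE
      }
    }
  }
  rec <- cumsum(tp) / npos
  prec <- cumsum(tp) / seq_along(tp)
  if (method == "eleven_point") {
    mean(vapply(seq(0, 1, 0.1), function(r) {
      p <- prec[rec >= r]
      if (length(p) == 0) 0 else max(p)
    }, numeric(1)))
  } else {
    mprec <- rev(cummax(rev(prec)))
    sum(diff(c(0, rec)) * mprec)
  }
}

#' Evaluate detections at one or more IoU thresholds
#'
#' Computes AP at each threshold (single "coil" class, so the per-class
#' mean AP equals AP), plus per-ground-truth best-match IoU dispersion.
#' `mean_iou`/`stdev_iou` are taken over the best detection IoU of every
#' ground-truth box (0 for boxes with no overlapping detection); the
#' dispersion is therefore across ground-truth instances, which is stated
#' explicitly because "per-fold standard deviation" is ambiguous.
#'
#' @param dets,gts As in [average_precision()].
#' @param thresholds Numeric vector of IoU thresholds; `0.75` gives the
#'   mAP@75 headline metric.
#' @param method AP interpolation, see [average_precision()].
#' @return An object of class `"eval_result"`: `ap_at_threshold` (named
#'   numeric, kept distinct per threshold), `map_score` (mean over
#'   classes at the first threshold), `iou_per_match`, `mean_iou`,
#'   `stdev_iou`.
#' @export
map_at <- function(dets, gts, thresholds = 0.75,
                   method = c("all_point", "eleven_point")) {
  method <- match.arg(method)
  ap <- vapply(thresholds,
               function(t) average_precision(dets, gts, t, method),
               numeric(1))
  names(ap) <- sprintf("ap@%g", thresholds)
  best <- vapply(seq_len(nrow(gts)), function(j) {
    cand <- which(dets$image_id == gts$image_id[j])
    if (length(cand) == 0) return(0)
    max(vapply(cand, function(i) iou_rows(dets, i, gts, j), numeric(1)))
  }, numeric(1))
  structure(list(ap_at_threshold = ap,
                 map_score = unname(ap[1]),
                 iou_per_match = best,
                 mean_iou = mean(best),
                 stdev_iou = stats::sd(best)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result>\n")
  for (nm in names(x$ap_at_threshold))
    cat(sprintf("  %s = %.4f\n", nm, x$ap_at_threshold[[nm]]))
  cat(sprintf("  mean IoU = %.4f (sd %.4f over %d ground-truth boxes)\n",
              x$mean_iou, x$stdev_iou, length(x$iou_per_match)))
  invisible(x)
}

#' Patient-wise (grouped) k-fold split
#'
#' Partitions the unique patients into `k` validation folds of as equal
#' size as the patient count allows (sizes differ by at most one); frames
#' follow their patient, so no patient ever appears in both the training
#' and validation side of a fold.
#'
#' @param patient_ids Vector of per-frame patient identifiers.
#' @param k Number of folds.
#' @param seed Seed for the patient shuffle.
#' @return List of `k` folds, each `list(val_patients, val, train)` where
#'   `val`/`train` are frame indices into `patient_ids`.
#' @examples
#' folds <- groupwise_kfold(rep(1:13, times = 13:1), k = 5, seed = 1)
#' lengths(lapply(folds, `[[`, "val_patients"))  # 3 3 3 2 2
#' @export
groupwise_kfold <- function(patient_ids, k = 5L, seed = 1L) {
  pats <- unique(patient_ids)
  if (length(pats) < k)
    stop("groupwise_kfold: fewer unique patients than folds")
  shuffled <- with_seed(seed, sample(pats))
  sizes <- rep(length(pats) %/% k, k)
  extra <- length(pats) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(f) {
    vp <- shuffled[starts[f]:ends[f]]
    val <- which(patient_ids %in% vp)
    list(val_patients = vp, val = val,
         train = setdiff(seq_along(patient_ids), val))
  })
}

#' Mann-Whitney U test (two-sided)
#'
#' The U statistic for sample `x` counts pairs with `x_i > y_j` plus half
#' the cross-group ties. The p-value is exact (full null enumeration, via
#' the exact distribution) when both samples have at most 10 observations
#' and the pooled sample has no ties; otherwise the tie-corrected normal
#' approximation with continuity correction is used, and the method
#' employed is recorded in the result.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param alpha Significance level for the `reject` flag.
#' @return An object of class `"mwu_result"`: `u_statistic`,
#'   `p_two_sided`, `n1`, `n2`, `method` (`"exact"` or
#'   `"normal_tie_corrected"`), `reject`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, alpha = 0.05) {
  if (length(x) < 1 || length(y) < 1)
    stop("mann_whitney_u: both samples must be non-empty")
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  use_exact <- length(x) <= 10 && length(y) <= 10 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  res <- structure(list(u_statistic = u,
                        p_two_sided = wt$p.value,
                        n1 = length(x), n2 = length(y),
                        method = if (use_exact) "exact"
                                 else "normal_tie_corrected",
                        alpha = alpha,
                        reject = wt$p.value < alpha),
                   class = "mwu_result")
  res
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("<Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s], %s H0 at alpha = %g>\n",
              x$u_statistic, x$n1, x$n2, x$p_two_sided, x$method,
              if (x$reject) "reject" else "retain", x$alpha))
  invisible(x)
}
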