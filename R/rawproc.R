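#' Raw angiography frame with acquisition geometry
#'
#' A raw frame is the detector image before preparation, together with the
#' acquisition geometry needed to prepare it: flip flags, a quarter-turn
#' rotation, the collimator shutter rectangle (given in the *corrected*
#' orientation, as stored by the acquisition system) and the pixel pitch.
#'
#' @param pixels 2-D numeric matrix (rows = image rows).
#' @param flip_horizontal,flip_vertical Orientation flags.
#' @param rotation_quarter_turns Counter-clockwise quarter turns in
#'   `0:3`, applied after the flips by [correct_orientation()].
#' @param collimator_rect A [bbox()] giving the shutter opening in the
#'   corrected orientation, or `NULL` if unknown (auto-detection is then
#'   used by [crop_collimator()]).
#' @param pixel_pitch_mm Physical pixel size (mm), > 0.
#' @return An object of class `"raw_frame"`.
#' @export
raw_frame <- function(pixels, flip_horizontal = FALSE, flip_vertical = FALSE,
                      rotation_quarter_turns = 0L, collimator_rect = NULL,
                      pixel_pitch_mm = 0.2) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  rot <- as.integer(rotation_quarter_turns)
  if (!rot %in% 0:3)
    stop("raw_frame: rotation_quarter_turns must be in 0:3")
  if (pixel_pitch_mm <= 0) stop("raw_frame: pixel_pitch_mm must be > 0")
  if (!is.null(collimator_rect)) {
    stopifnot(inherits(collimator_rect, "bbox"))
    # bounds are checked against the corrected orientation
    d <- if (rot %% 2L == 1L) rev(dim(pixels)) else dim(pixels)
    if (collimator_rect[["xmin"]] < 0 || collimator_rect[["ymin"]] < 0 ||
        collimator_rect[["xmax"]] > d[2] || collimator_rect[["ymax"]] > d[1])
      stop("raw_frame: collimator_rect outside image bounds")
  }
  structure(list(pixels = pixels,
                 flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical),
                 rotation_quarter_turns = rot,
                 collimator_rect = collimator_rect,
                 pixel_pitch_mm = pixel_pitch_mm),
            class = "raw_frame")
}

#' @export
print.raw_frame <- function(x, ...) {
  cat(sprintf("<raw_frame %dx%d px, pitch %g mm, flipH=%s flipV=%s rot=%d>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch_mm,
              x$flip_horizontal, x$flip_vertical, x$rotation_quarter_turns))
  invisible(x)
}

# Counter-clockwise rotation by k quarter turns.
rot90_matrix <- function(m, k = 1L) {
  k <- as.integer(k) %% 4L
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

flip_matrix <- function(m, horizontal = FALSE, vertical = FALSE) {
  if (horizontal) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (vertical) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

#' Correct frame orientation (flip, then rotate)
#'
#' Applies the horizontal/vertical flips first and the counter-clockwise
#' quarter-turn rotation second, then resets the flags. The collimator
#' rectangle is already expressed in the corrected orientation and is
#' passed through unchanged.
#'
#' @param frame A [raw_frame()].
#' @return The corrected [raw_frame()] with all flags reset.
#' @export
correct_orientation <- function(frame) {
  stopifnot(inherits(frame, "raw_frame"))
  px <- flip_matrix(frame$pixels, frame$flip_horizontal, frame$flip_vertical)
  px <- rot90_matrix(px, frame$rotation_quarter_turns)
  raw_frame(px, collimator_rect = frame$collimator_rect,
            pixel_pitch_mm = frame$pixel_pitch_mm)
}

#' Crop a frame to its collimator opening
#'
#' Removes the shuttered border using the stored collimator rectangle.
#' When the rectangle is unknown (`NULL`), the opening is auto-detected as
#' the tight hull of pixels above the exact-zero shutter border (the
#' phantom renders ideal shutters as zeros) -- a fallback for frames
#' without stored geometry.
#'
#' @param frame A [raw_frame()] in corrected orientation.
#' @return A [raw_frame()] containing only the opening; its
#'   `collimator_rect` spans the full new extent and the crop offset
#'   (original coordinates of the new origin) is stored in fields
#'   `crop_offset_x` / `crop_offset_y`.
#' @export
crop_collimator <- function(frame) {
  stopifnot(inherits(frame, "raw_frame"))
  px <- frame$pixels
  rect <- frame$collimator_rect
  if (is.null(rect)) {
    nzr <- which(rowSums(px != 0) > 0)
    nzc <- which(colSums(px != 0) > 0)
    if (length(nzr) == 0 || length(nzc) == 0)
      stop("crop_collimator: frame is entirely shuttered (all zeros)")
    rect <- bbox(min(nzc) - 1, min(nzr) - 1, max(nzc), max(nzr))
  }
  xmin <- round(rect[["xmin"]]); ymin <- round(rect[["ymin"]])
  xmax <- round(rect[["xmax"]]); ymax <- round(rect[["ymax"]])
  if (xmax - xmin < 1 || ymax - ymin < 1)
    stop("crop_collimator: degenerate collimator rectangle")
  sub <- px[(ymin + 1):ymax, (xmin + 1):xmax, drop = FALSE]
  out <- raw_frame(sub,
                   collimator_rect = bbox(0, 0, ncol(sub), nrow(sub)),
                   pixel_pitch_mm = frame$pixel_pitch_mm)
  out$crop_offset_x <- xmin
  out$crop_offset_y <- ymin
  out
}

#' Standard-scaler normalization (zero mean, unit variance)
#'
#' Uses the population standard deviation. A constant image is degenerate
#' and maps to all zeros with a warning, keeping the chain deterministic.
#'
#' @param pixels Numeric matrix or vector with at least 2 elements.
#' @return The normalized array, same shape.
#' @examples
#' normalize_standard(c(0, 2))  # -1, 1
#' @export
normalize_standard <- function(pixels) {
  if (length(pixels) < 2) stop("normalize_standard: need at least 2 pixels")
  mu <- mean(pixels)
  sdev <- sqrt(mean((pixels - mu)^2))
  if (sdev == 0) {
    warning("normalize_standard: constant image, returning zeros")
    return(pixels * 0)
  }
  (pixels - mu) / sdev
}

#' Resize a frame to a fixed resolution, transforming boxes consistently
#'
#' Anisotropic bilinear resampling to `target = c(H, W)` (no letterboxing):
#' rows are scaled by `H/nrow`, columns by `W/ncol`. Boxes are scaled by
#' the same factors and rounded outward (floor on minima, ceiling on
#' maxima) so no ground-truth pixel is lost.
#'
#' @param pixels Numeric matrix.
#' @param boxes Optional box data frame (`xmin`, `ymin`, `xmax`, `ymax`,
#'   extra columns preserved) in the input pixel grid.
#' @param target Output size `c(height, width)`, default `c(512, 512)`.
#' @return List with `pixels` (resized matrix), `boxes` (transformed) and
#'   `transform` -- the affine record `list(sx, sy, ox, oy)` mapping input
#'   coordinates to output coordinates as `x' = (x - ox) * sx`.
#' @export
resize_with_boxes <- function(pixels, boxes = NULL, target = c(512L, 512L)) {
  stopifnot(is.matrix(pixels))
  if (any(target <= 0)) stop("resize_with_boxes: target must be positive")
  if (nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("resize_with_boxes: zero-sized input")
  sy <- target[1] / nrow(pixels)
  sx <- target[2] / ncol(pixels)
  resized <- if (sx == 1 && sy == 1) pixels else {
    r <- EBImage::resize(pixels, w = target[1], h = target[2],
                         filter = "bilinear")
    matrix(as.numeric(r), target[1], target[2])
  }
  tr <- list(sx = sx, sy = sy, ox = 0, oy = 0)
  list(pixels = resized, boxes = transform_boxes(boxes, tr), transform = tr)
}

#' Apply an affine frame transform to boxes (outward rounding)
#'
#' @param boxes Box data frame or `NULL`.
#' @param transform `list(sx, sy, ox, oy)`: `x' = (x - ox) * sx`,
#'   `y' = (y - oy) * sy`.
#' @return Transformed boxes (minima floored, maxima ceiled), or `NULL`.
#' @export
transform_boxes <- function(boxes, transform) {
  if (is.null(boxes) || nrow(boxes) == 0) return(boxes)
  out <- boxes
  out$xmin <- floor((boxes$xmin - transform$ox) * transform$sx)
  out$xmax <- ceiling((boxes$xmax - transform$ox) * transform$sx)
  out$ymin <- floor((boxes$ymin - transform$oy) * transform$sy)
  out$ymax <- ceiling((boxes$ymax - transform$oy) * transform$sy)
  out
}

#' Invert an affine frame transform
#' @param transform `list(sx, sy, ox, oy)`.
#' @return The inverse transform, such that applying both is the identity
#'   up to rounding.
#' @export
invert_transform <- function(transform) {
  list(sx = 1 / transform$sx, sy = 1 / transform$sy,
       ox = -transform$ox * transform$sx, oy = -transform$oy * transform$sy)
}

#' Full frame-preparation chain
#'
#' Orientation correction, collimator crop, fixed-resolution resize, then
#' standard-scaler normalization (normalizing last keeps the prepared
#' frame exactly zero-mean/unit-variance; resampling would otherwise
#' perturb the moments). Ground-truth boxes, when given in the corrected
#' uncropped pixel grid, are carried through crop shift and resize scale
#' with outward rounding.
#'
#' @param frame A [raw_frame()].
#' @param boxes Optional box data frame in the corrected, uncropped grid.
#' @param target Output resolution `c(H, W)`.
#' @return An object of class `"prepared_frame"`: `pixels` (normalized
#'   matrix), `boxes`, `transform` (composed affine record), `target_size`
#'   and `pixel_pitch_mm` (per-axis, named `x`/`y`, reflecting the resize).
#' @export
prepare_frame <- function(frame, boxes = NULL, target = c(512L, 512L)) {
  corrected <- correct_orientation(frame)
  cropped <- crop_collimator(corrected)
  shift <- list(sx = 1, sy = 1, ox = cropped$crop_offset_x,
                oy = cropped$crop_offset_y)
  boxes_c <- transform_boxes(boxes, shift)
  rs <- resize_with_boxes(cropped$pixels, boxes_c, target)
  tr <- list(sx = rs$transform$sx, sy = rs$transform$sy,
             ox = cropped$crop_offset_x, oy = cropped$crop_offset_y)
  structure(list(pixels = normalize_standard(rs$pixels),
                 boxes = rs$boxes,
                 transform = tr,
                 target_size = as.integer(target),
                 pixel_pitch_mm = c(x = frame$pixel_pitch_mm / tr$sx,
                                    y = frame$pixel_pitch_mm / tr$sy)),
            class = "prepared_frame")
}
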