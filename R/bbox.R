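#' Axis-aligned bounding box
#'
#' Boxes are 0-based and half-open: a box covers pixel columns
#' `[xmin, xmax)` and rows `[ymin, ymax)`, with `x` indexing columns and
#' `y` indexing rows. This convention is used throughout the package,
#' including the Pascal-VOC XML writer.
#'
#' @param xmin,ymin,xmax,ymax Box edges (reals); `xmin < xmax`, `ymin < ymax`.
#' @return A named numeric vector of class `"bbox"`.
#' @examples
#' b <- bbox(0, 0, 10, 20)
#' bbox_area(b)  # 200
#' @export
bbox <- function(xmin, ymin, xmax, ymax) {
  v <- c(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  if (any(!is.finite(v)))
    stop("bbox: non-finite coordinate")
  if (v["xmin"] >= v["xmax"] || v["ymin"] >= v["ymax"])
    stop("bbox: degenerate box (need xmin < xmax and ymin < ymax)")
  structure(v, class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox [%g, %g) x [%g, %g), area %g px^2>\n",
              x[["xmin"]], x[["xmax"]], x[["ymin"]], x[["ymax"]], bbox_area(x)))
  invisible(x)
}

#' Box area in pixel^2 (half-open convention)
#' @param box A [bbox()].
#' @return Numeric area.
#' @export
bbox_area <- function(box) {
  unname((box[["xmax"]] - box[["xmin"]]) * (box[["ymax"]] - box[["ymin"]]))
}

#' Clip a box to an image extent
#'
#' @param box A [bbox()].
#' @param extent Image extent as `c(width, height)` in pixels.
#' @return The clipped [bbox()]; errors if the clipped box would be empty.
#' @export
bbox_clip <- function(box, extent) {
  xmin <- max(box[["xmin"]], 0); ymin <- max(box[["ymin"]], 0)
  xmax <- min(box[["xmax"]], extent[1]); ymax <- min(box[["ymax"]], extent[2])
  if (xmin >= xmax || ymin >= ymax)
    stop("bbox_clip: box lies entirely outside the extent")
  bbox(xmin, ymin, xmax, ymax)
}

#' Tight hull of a set of boxes
#'
#' @param boxes A data frame with columns `xmin`, `ymin`, `xmax`, `ymax`
#'   (one row per box), or a list of [bbox()] objects.
#' @return A [bbox()] covering all input boxes, or `NULL` for empty input.
#' @export
bbox_hull <- function(boxes) {
  boxes <- as_box_df(boxes)
  if (nrow(boxes) == 0) return(NULL)
  bbox(min(boxes$xmin), min(boxes$ymin), max(boxes$xmax), max(boxes$ymax))
}

# Coerce bbox / list-of-bbox / data.frame to a canonical box data.frame.
as_box_df <- function(boxes) {
  if (is.null(boxes)) return(empty_box_df())
  if (inherits(boxes, "bbox")) boxes <- list(boxes)
  if (is.data.frame(boxes)) {
    stopifnot(all(c("xmin", "ymin", "xmax", "ymax") %in% names(boxes)))
    return(boxes)
  }
  if (is.list(boxes)) {
    if (length(boxes) == 0) return(empty_box_df())
    return(do.call(rbind, lapply(boxes, function(b)
      data.frame(xmin = b[["xmin"]], ymin = b[["ymin"]],
                 xmax = b[["xmax"]], ymax = b[["ymax"]]))))
  }
  stop("cannot interpret 'boxes' as bounding boxes")
}

empty_box_df <- function() {
  data.frame(xmin = numeric(0), ymin = numeric(0),
             xmax = numeric(0), ymax = numeric(0))
}

# Row i of a box data.frame as a bbox.
df_bbox <- function(df, i) {
  bbox(df$xmin[i], df$ymin[i], df$xmax[i], df$ymax[i])
}
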