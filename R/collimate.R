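#' Union box of accepted detections
#'
#' Tight hull of all detections with score at or above `min_score`; the
#' aggregate a single rectangular collimator must cover when several
#' coils are present.
#'
#' @param dets Detection data frame (`xmin`..`ymax`, `score`).
#' @param min_score Minimum confidence to accept a detection.
#' @return A [bbox()], or `NULL` if no detection passes.
#' @export
union_box <- function(dets, min_score = 0) {
  if (is.null(dets) || nrow(dets) == 0) return(NULL)
  keep <- dets$score >= min_score
  if (!any(keep)) return(NULL)
  bbox_hull(dets[keep, , drop = FALSE])
}

#' Upscale a box about its center
#'
#' Multiplies width and height by `scale_factor` about the box center and
#' clips the result to the image extent. The safety margin an expert adds
#' around a detected coil before collimating.
#'
#' @param box A [bbox()].
#' @param scale_factor Multiplicative factor, >= 1.
#' @param image_extent `c(width, height)` in pixels.
#' @return The upscaled, clipped [bbox()].
#' @examples
#' upscale_box(bbox(10, 10, 30, 30), 2, c(100, 100))  # (0,0,40,40)
#' @export
upscale_box <- function(box, scale_factor, image_extent) {
  stopifnot(inherits(box, "bbox"))
  if (scale_factor < 1) stop("upscale_box: scale_factor must be >= 1")
  cx <- (box[["xmin"]] + box[["xmax"]]) / 2
  cy <- (box[["ymin"]] + box[["ymax"]]) / 2
  hw <- (box[["xmax"]] - box[["xmin"]]) * scale_factor / 2
  hh <- (box[["ymax"]] - box[["ymin"]]) * scale_factor / 2
  bbox_clip(bbox(cx - hw, cy - hh, cx + hw, cy + hh), image_extent)
}

#' Planned collimator aperture
#'
#' @param box A [bbox()] in detector pixel coordinates.
#' @param pixel_pitch_mm Pixel pitch (mm); scalar, or named `c(x=, y=)`.
#' @param scale_factor The upscale factor that produced the box.
#' @param mode `"auto"` (planned from detections) or `"manual"`
#'   (fallback, e.g. full field when nothing was detected).
#' @return An object of class `"aperture_spec"` with the physical opening
#'   area in m^2 (`area_m2 = width * height * pitch_x * pitch_y / 1e6`).
#' @export
aperture_spec <- function(box, pixel_pitch_mm, scale_factor = 1,
                          mode = c("auto", "manual")) {
  stopifnot(inherits(box, "bbox"))
  mode <- match.arg(mode)
  px <- if (length(pixel_pitch_mm) == 2) pixel_pitch_mm[["x"]] else pixel_pitch_mm
  py <- if (length(pixel_pitch_mm) == 2) pixel_pitch_mm[["y"]] else pixel_pitch_mm
  area_m2 <- (box[["xmax"]] - box[["xmin"]]) * px *
    (box[["ymax"]] - box[["ymin"]]) * py / 1e6
  structure(list(box = box, area_m2 = area_m2,
                 scale_factor = scale_factor, mode = mode),
            class = "aperture_spec")
}

#' @export
print.aperture_spec <- function(x, ...) {
  cat(sprintf("<aperture %s [%g, %g) x [%g, %g) px, %.6g m^2, scale %g>\n",
              x$mode, x$box[["xmin"]], x$box[["xmax"]],
              x$box[["ymin"]], x$box[["ymax"]], x$area_m2, x$scale_factor))
  invisible(x)
}

#' Plan a collimator aperture from detections
#'
#' Union of accepted detections, upscaled by the expert safety factor and
#' clipped to the field. When no detection passes, the full field is
#' returned flagged as `"manual"` mode -- collimation stays with the
#' operator.
#'
#' @param dets Detection data frame.
#' @param image_extent `c(width, height)` of the frame in pixels.
#' @param pixel_pitch_mm Pixel pitch (mm), scalar or `c(x=, y=)`.
#' @param scale_factor Expert upscale factor (default 1.5; a free
#'   operational parameter, not a calibrated value).
#' @param min_score Minimum detection confidence.
#' @return An [aperture_spec()].
#' @export
plan_aperture <- function(dets, image_extent, pixel_pitch_mm,
                          scale_factor = 1.5, min_score = 0) {
  ub <- union_box(dets, min_score)
  if (is.null(ub)) {
    return(aperture_spec(bbox(0, 0, image_extent[1], image_extent[2]),
                         pixel_pitch_mm, scale_factor = 1, mode = "manual"))
  }
  aperture_spec(upscale_box(ub, scale_factor, image_extent),
                pixel_pitch_mm, scale_factor = scale_factor, mode = "auto")
}
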