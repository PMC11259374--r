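#' Read and write single-channel frame TIFFs
#'
#' Frames are stored as single-channel 16-bit unsigned TIFFs with values
#' in `[0, 1]` (the package's detector-signal convention: higher value =
#' more signal, coils dark).
#'
#' @param pixels Numeric matrix in `[0, 1]` (values are clamped).
#' @param path Output file path.
#' @return `write_frame_tiff()`: the path, invisibly;
#'   `read_frame_tiff()`: the pixel matrix.
#' @export
write_frame_tiff <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  tiff::writeTIFF(pmin(pmax(pixels, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px
}

#' Write and read Pascal-VOC-style XML annotations
#'
#' One `<object>` element per box, name `"coil"`, with `<bndbox>`
#' coordinates `xmin`/`ymin`/`xmax`/`ymax`. Coordinates are 0-based and
#' half-open (`xmax`/`ymax` exclusive), as everywhere in this package;
#' this deviates from classic VOC's 1-based inclusive pixels and is
#' recorded in a `<coordinate_convention>` element of each file.
#'
#' @param path XML file path.
#' @param filename Image file name recorded in the annotation.
#' @param width,height Image size in pixels.
#' @param boxes Box data frame (`xmin`, `ymin`, `xmax`, `ymax`, optional
#'   `label`).
#' @return `write_voc_xml()`: the path, invisibly; `read_voc_xml()`: a
#'   list with `filename`, `width`, `height` and `boxes`.
#' @export
write_voc_xml <- function(path, filename, width, height, boxes) {
  boxes <- as_box_df(boxes)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  xml2::xml_add_child(doc, "coordinate_convention", "0-based, half-open")
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(width))
  xml2::xml_add_child(size, "height", as.character(height))
  xml2::xml_add_child(size, "depth", "1")
  for (i in seq_len(nrow(boxes))) {
    obj <- xml2::xml_add_child(doc, "object")
    lbl <- if ("label" %in% names(boxes)) boxes$label[i] else "coil"
    xml2::xml_add_child(obj, "name", lbl)
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(boxes$xmin[i]))
    xml2::xml_add_child(bb, "ymin", format(boxes$ymin[i]))
    xml2::xml_add_child(bb, "xmax", format(boxes$xmax[i]))
    xml2::xml_add_child(bb, "ymax", format(boxes$ymax[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_voc_xml
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  num <- function(node, tag)
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, tag)))
  boxes <- if (length(objs) == 0)
    cbind(empty_box_df(), data.frame(label = character(0)))
  else do.call(rbind, lapply(objs, function(o)
    data.frame(xmin = num(o, ".//xmin"), ymin = num(o, ".//ymin"),
               xmax = num(o, ".//xmax"), ymax = num(o, ".//ymax"),
               label = xml2::xml_text(xml2::xml_find_first(o, ".//name")))))
  list(filename = xml2::xml_text(xml2::xml_find_first(doc, ".//filename")),
       width = num(doc, ".//size/width"),
       height = num(doc, ".//size/height"),
       boxes = boxes)
}

#' Frame geometry sidecar (YAML)
#'
#' Stores the acquisition geometry of a raw frame (flip flags, rotation,
#' collimator rectangle, pixel pitch) next to its TIFF so user-supplied
#' frames can enter the pipeline.
#'
#' @param path YAML file path.
#' @param frame A [raw_frame()].
#' @return `write_geometry_yaml()`: the path, invisibly;
#'   `read_geometry_yaml()`: the geometry as a list (`collimator_rect`
#'   as a [bbox()] or `NULL`).
#' @export
write_geometry_yaml <- function(path, frame) {
  stopifnot(inherits(frame, "raw_frame"))
  g <- list(flip_horizontal = frame$flip_horizontal,
            flip_vertical = frame$flip_vertical,
            rotation_quarter_turns = frame$rotation_quarter_turns,
            pixel_pitch_mm = frame$pixel_pitch_mm,
            collimator_rect = if (is.null(frame$collimator_rect)) NULL else
              as.list(unclass(frame$collimator_rect)))
  yaml::write_yaml(g, path)
  invisible(path)
}

#' @rdname write_geometry_yaml
#' @export
read_geometry_yaml <- function(path) {
  g <- yaml::read_yaml(path)
  if (!is.null(g$collimator_rect))
    g$collimator_rect <- bbox(g$collimator_rect$xmin, g$collimator_rect$ymin,
                              g$collimator_rect$xmax, g$collimator_rect$ymax)
  g
}

#' Read a frame plus sidecar geometry as a raw frame
#'
#' @param tiff_path Frame TIFF path; the sidecar defaults to the same
#'   path with extension `.geom.yaml`.
#' @param geometry_path Optional explicit sidecar path.
#' @return A [raw_frame()].
#' @export
read_raw_frame <- function(tiff_path,
                           geometry_path = sub("\\.tiff?$", ".geom.yaml",
                                               tiff_path)) {
  px <- read_frame_tiff(tiff_path)
  g <- if (file.exists(geometry_path)) read_geometry_yaml(geometry_path)
  else list()
  raw_frame(px,
            flip_horizontal = isTRUE(g$flip_horizontal),
            flip_vertical = isTRUE(g$flip_vertical),
            rotation_quarter_turns = g$rotation_quarter_turns %||% 0L,
            collimator_rect = g$collimator_rect,
            pixel_pitch_mm = g$pixel_pitch_mm %||% 0.2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detections as JSON lines
#'
#' One JSON object per line: `image_id`, `xmin`, `ymin`, `xmax`, `ymax`,
#' `score`, `label`.
#'
#' @param dets Detection data frame (with `image_id` column).
#' @param path Output path.
#' @return `write_detections_jsonl()`: the path, invisibly;
#'   `read_detections_jsonl()`: the detection data frame.
#' @export
write_detections_jsonl <- function(dets, path) {
  lines <- vapply(seq_len(nrow(dets)), function(i)
    as.character(jsonlite::toJSON(as.list(dets[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_detections_jsonl
#' @export
read_detections_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(cbind(data.frame(image_id = character(0)), empty_detections()))
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}

#' Write a planned aperture to JSON
#'
#' @param aperture An [aperture_spec()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_aperture_json <- function(aperture, path) {
  stopifnot(inherits(aperture, "aperture_spec"))
  jsonlite::write_json(list(xmin = aperture$box[["xmin"]],
                            ymin = aperture$box[["ymin"]],
                            xmax = aperture$box[["xmax"]],
                            ymax = aperture$box[["ymax"]],
                            area_m2 = aperture$area_m2,
                            scale_factor = aperture$scale_factor,
                            mode = aperture$mode),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
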