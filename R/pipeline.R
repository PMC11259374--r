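#' Default pipeline configuration
#'
#' A run is reproducible from the configuration plus its seed alone. The
#' configuration is a plain list and serializes cleanly to YAML.
#'
#' @param seed Master seed.
#' @param n_frames Number of phantom frames to generate.
#' @param patients Number of synthetic patients.
#' @param k_folds Folds for the patient-wise split.
#' @param phantom A [phantom_spec()] used as the base for every frame.
#' @param blob A [blob_params()] for the detector; `NULL` derives the
#'   area gate from the dataset's own ground-truth boxes (smallest and
#'   largest coil), the recommended deployment procedure.
#' @param scale_factor Collimation upscale factor.
#' @param aerc An [aerc_config()].
#' @param iou_thresholds Evaluation thresholds (default `c(0.75, 0.5)`).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_frames = 20L, patients = 5L, k_folds = 5L,
                       phantom = phantom_spec(), blob = NULL,
                       scale_factor = 1.5, aerc = aerc_config(),
                       iou_thresholds = c(0.75, 0.5)) {
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 patients = as.integer(patients), k_folds = as.integer(k_folds),
                 phantom = phantom, blob = blob, scale_factor = scale_factor,
                 aerc = aerc, iou_thresholds = iou_thresholds),
            class = "run_config")
}

#' Derive a blob-detector area gate from ground-truth boxes
#'
#' Mirrors the deployment rule that the smallest and largest expected
#' coil bound the admissible blob area, expressed in *blurred-blob*
#' units: for a coil of half-side `r` the detector sees a basin whose
#' area ranges from a deep core (below `pi r^2`) up to roughly
#' `pi (r + sigma)^2` once the Gaussian blur has spread it. The gate is
#' therefore `[0.25 * pi * min(r)^2, 1.5 * pi * (max(r) + sigma)^2]`.
#'
#' The lower sweep quantile is also tied to the smallest expected coil:
#' anchoring the sweep at the 1st intensity percentile cannot resolve a
#' coil whose deep core holds fewer pixels than 1% of the frame, so the
#' quantile is lowered to the core's area fraction
#' `0.25 * pi * min(r)^2 / image_npx` when that is smaller.
#'
#' @param gt_boxes Box data frame of ground-truth coils.
#' @param base A [blob_params()] providing the remaining parameters
#'   (including the `gauss_sigma` used for the inflation term).
#' @param image_npx Pixel count of the frames the detector will see
#'   (default the standard 512 x 512 prepared resolution).
#' @return A [blob_params()] with the derived `min_area`/`max_area` and
#'   lower sweep quantile.
#' @export
blob_params_from_truth <- function(gt_boxes, base = blob_params(),
                                   image_npx = 512^2) {
  gt_boxes <- as_box_df(gt_boxes)
  if (nrow(gt_boxes) == 0) return(base)
  r <- ((gt_boxes$xmax - gt_boxes$xmin) + (gt_boxes$ymax - gt_boxes$ymin)) / 4
  base$min_area <- 0.25 * pi * min(r)^2
  base$max_area <- 1.5 * pi * (max(r) + base$gauss_sigma)^2
  base$threshold_quantiles[1] <- max(1e-4, min(base$threshold_quantiles[1],
                                               base$min_area / image_npx))
  base
}

#' Run the full phantom-to-report pipeline
#'
#' generate -> prepare -> detect -> collimate -> dose -> evaluate, writing
#' a deterministic artifact tree under `out_dir`:
#' `frames/` (raw TIFF + VOC XML + geometry + manifest), `prepared/`
#' (prepared TIFFs + transforms), `detections.jsonl`, `apertures/`,
#' `dose_experiment1.csv`, `dose_experiment2.csv`, `evaluation.csv`,
#' `folds.csv`, and `manifest_hashes.csv` (MD5 of every artifact).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory results (`manifest`,
#'   `eval_blob`, `eval_stub`, `exp1`, `exp2`, `folds`, `paths`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  frames_dir <- file.path(out_dir, "frames")
  prepared_dir <- file.path(out_dir, "prepared")
  apert_dir <- file.path(out_dir, "apertures")
  for (d in c(frames_dir, prepared_dir, apert_dir))
    dir.create(d, showWarnings = FALSE)

  # -- generate -------------------------------------------------------------
  specs <- phantom_spec_series(config$n_frames, config$phantom, config$seed)
  manifest <- render_dataset(specs, config$patients, frames_dir,
                             seed = config$seed + 1L)
  scenes <- lapply(specs, render_frame)

  # -- prepare --------------------------------------------------------------
  prepared <- vector("list", length(scenes))
  gts <- list()
  for (i in seq_along(scenes)) {
    pf <- prepare_frame(scenes[[i]]$frame, scenes[[i]]$truth$boxes)
    prepared[[i]] <- pf
    write_frame_tiff((pf$pixels - min(pf$pixels)) /
                       max(diff(range(pf$pixels)), .Machine$double.eps),
                     file.path(prepared_dir, paste0(manifest$frame_id[i], ".tif")))
    jsonlite::write_json(pf$transform,
                         file.path(prepared_dir,
                                   paste0(manifest$frame_id[i], ".transform.json")),
                         auto_unbox = TRUE, digits = NA)
    if (nrow(pf$boxes) > 0)
      gts[[length(gts) + 1L]] <- cbind(
        data.frame(image_id = manifest$frame_id[i]), pf$boxes)
  }
  gts <- if (length(gts)) do.call(rbind, gts) else
    cbind(data.frame(image_id = character(0)), empty_box_df())

  # -- detect ---------------------------------------------------------------
  bp <- config$blob %||% blob_params_from_truth(gts)
  backend <- backend_blob(bp)
  dets <- list()
  for (i in seq_along(prepared)) {
    d <- run_backend(backend, prepared[[i]]$pixels)
    if (nrow(d) > 0)
      dets[[length(dets) + 1L]] <- cbind(
        data.frame(image_id = manifest$frame_id[i]), d)
  }
  dets <- if (length(dets)) do.call(rbind, dets) else
    cbind(data.frame(image_id = character(0)), empty_detections())
  write_detections_jsonl(dets, file.path(out_dir, "detections.jsonl"))

  # -- collimate ------------------------------------------------------------
  for (i in seq_along(prepared)) {
    di <- dets[dets$image_id == manifest$frame_id[i], , drop = FALSE]
    ap <- plan_aperture(di, rev(dim(prepared[[i]]$pixels)),
                        prepared[[i]]$pixel_pitch_mm,
                        scale_factor = config$scale_factor)
    write_aperture_json(ap, file.path(apert_dir,
                                      paste0(manifest$frame_id[i], ".json")))
  }

  # -- dose -----------------------------------------------------------------
  exp1 <- tryCatch(
    suppressWarnings(
      run_experiment1(scenes, function(px) backend(normalize_standard(px)),
                      cfg = config$aerc, scale_factor = config$scale_factor)),
    error = function(e) {
      warning(sprintf("experiment 1 skipped: %s", conditionMessage(e)))
      NULL
    })
  if (!is.null(exp1))
    utils::write.csv(exp1$table, file.path(out_dir, "dose_experiment1.csv"),
                     row.names = FALSE)
  first_with_coil <- which(vapply(scenes, function(s)
    nrow(s$truth$boxes) > 0, logical(1)))[1]
  exp2 <- NULL
  if (!is.na(first_with_coil)) {
    sc <- scenes[[first_with_coil]]
    coil_mask <- Reduce(`|`, sc$truth$coil_masks)
    tight <- aperture_spec(
      upscale_box(bbox_hull(sc$truth$boxes), config$scale_factor,
                  rev(dim(sc$attenuation))),
      sc$frame$pixel_pitch_mm)
    exp2 <- run_experiment2(sc$attenuation, coil_mask, tight,
                            cfg = config$aerc)
    utils::write.csv(exp2$reports, file.path(out_dir, "dose_experiment2.csv"),
                     row.names = FALSE)
  }

  # -- evaluate -------------------------------------------------------------
  eval_blob <- eval_stub <- NULL
  if (nrow(gts) > 0) {  # AP is undefined on a coil-free dataset
    eval_blob <- map_at(dets, gts, config$iou_thresholds)
    stub_dets <- cbind(gts[, "image_id", drop = FALSE],
                       gts[, c("xmin", "ymin", "xmax", "ymax")],
                       score = 0.99, label = "coil")
    eval_stub <- map_at(stub_dets, gts, config$iou_thresholds)
    ev <- data.frame(
      detector = c(rep("blob", length(config$iou_thresholds)),
                   rep("stub_truth", length(config$iou_thresholds))),
      iou_threshold = rep(config$iou_thresholds, 2),
      ap = c(eval_blob$ap_at_threshold, eval_stub$ap_at_threshold),
      mean_iou = c(rep(eval_blob$mean_iou, length(config$iou_thresholds)),
                   rep(eval_stub$mean_iou, length(config$iou_thresholds))))
  } else {
    ev <- data.frame(detector = character(0), iou_threshold = numeric(0),
                     ap = numeric(0), mean_iou = numeric(0))
  }
  utils::write.csv(ev, file.path(out_dir, "evaluation.csv"), row.names = FALSE)

  folds <- groupwise_kfold(manifest$patient_id, k = min(config$k_folds,
                                                        config$patients),
                           seed = config$seed + 2L)
  folds_df <- do.call(rbind, lapply(seq_along(folds), function(f)
    data.frame(fold = f,
               val_patients = paste(sort(folds[[f]]$val_patients),
                                    collapse = ";"),
               n_val_frames = length(folds[[f]]$val))))
  utils::write.csv(folds_df, file.path(out_dir, "folds.csv"), row.names = FALSE)

  # -- manifest hashes ------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest_hashes.csv"))
  hashes <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files)))
  hashes <- hashes[order(hashes$file), ]
  utils::write.csv(hashes, file.path(out_dir, "manifest_hashes.csv"),
                   row.names = FALSE)

  invisible(list(manifest = manifest, eval_blob = eval_blob,
                 eval_stub = eval_stub, exp1 = exp1, exp2 = exp2,
                 folds = folds, paths = list(out_dir = out_dir)))
}
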