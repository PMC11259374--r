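#' Synthetic angiography phantom specification
#'
#' Describes one synthetic cerebral-angiography frame: a skull-like
#' low-frequency attenuation background, one or more dense curled-wire
#' embolization coils (the strongest absorbers in the scene, hence the
#' darkest structures), thin catheter/guidewire distractors, rectangular
#' collimator shutters rendered as exact zeros, Poisson detector noise and
#' a gamma intensity windowing.
#'
#' Intensity convention (used everywhere in the package): higher stored
#' value = more detector signal. Coils are dark. The unit-output detector
#' signal is `exp(-L)` where `L` is the line-integral attenuation map.
#'
#' The attenuation defaults are free parameters of the phantom, chosen to
#' give a platinum-like, nearly opaque coil (`exp(-4)` ~ 2% transmission)
#' over a soft-tissue/bone background with 30--75% transmission; they are
#' not calibrated against any clinical system.
#'
#' @param image_height_px,image_width_px Frame size in pixels.
#' @param pixel_pitch_mm Physical size of one detector pixel (mm).
#' @param n_coils Number of coils to place (>= 0).
#' @param coil_radius_px_range Two-vector `c(lo, hi)`: coil outer radius
#'   is drawn uniformly from this range (pixels).
#' @param wire_thickness_px Rendered wire thickness (pixels).
#' @param coil_attenuation Line-integral attenuation added per coil-wire
#'   pixel; the coil transmission is `exp(-coil_attenuation)`.
#' @param coil_mode `"spiral"` for a dense Archimedean spiral with angular
#'   jitter (typical packed coil), `"disk"` for a filled disk (idealized,
#'   fully packed coil mass), or `"irregular"` for a sparse
#'   self-intersecting random walk (framing-coil-like, encloses mostly
#'   background and is the blob detector's known hard case).
#' @param background_attenuation_scale Multiplier on the skull background
#'   attenuation (0 disables the background).
#' @param n_distractors Number of catheter/guidewire splines.
#' @param distractor_attenuation Attenuation per distractor pixel; should
#'   be well below `coil_attenuation`.
#' @param collimator_margin_px Collimator shutter margin per side (pixels);
#'   shuttered pixels are exact zeros.
#' @param noise_poisson_scale Photons per unit signal for Poisson noise
#'   (0 disables noise).
#' @param windowing_gamma Gamma applied to the clamped signal after noise;
#'   1 is neutral, values away from 1 emulate an improperly windowed frame.
#' @param randomize_orientation If `TRUE`, the stored pixels carry random
#'   flip/rotation flags (ground truth stays in the corrected orientation).
#' @param seed Integer seed; rendering is deterministic given the spec.
#' @return An object of class `"phantom_spec"`.
#' @seealso [render_frame()], [render_dataset()]
#' @export
phantom_spec <- function(image_height_px = 640L,
                         image_width_px = 640L,
                         pixel_pitch_mm = 0.2,
                         n_coils = 1L,
                         coil_radius_px_range = c(18, 45),
                         wire_thickness_px = 3,
                         coil_attenuation = 4,
                         coil_mode = c("spiral", "disk", "irregular"),
                         background_attenuation_scale = 1,
                         n_distractors = 2L,
                         distractor_attenuation = 0.6,
                         collimator_margin_px = 32L,
                         noise_poisson_scale = 2000,
                         windowing_gamma = 1,
                         randomize_orientation = FALSE,
                         seed = 1L) {
  coil_mode <- match.arg(coil_mode)
  spec <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_pitch_mm = pixel_pitch_mm,
    n_coils = as.integer(n_coils),
    coil_radius_px_range = as.numeric(coil_radius_px_range),
    wire_thickness_px = wire_thickness_px,
    coil_attenuation = coil_attenuation,
    coil_mode = coil_mode,
    background_attenuation_scale = background_attenuation_scale,
    n_distractors = as.integer(n_distractors),
    distractor_attenuation = distractor_attenuation,
    collimator_margin_px = as.integer(collimator_margin_px),
    noise_poisson_scale = noise_poisson_scale,
    windowing_gamma = windowing_gamma,
    randomize_orientation = isTRUE(randomize_orientation),
    seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$image_height_px < 32 || s$image_width_px < 32)
    stop("phantom_spec: image must be at least 32x32")
  if (s$pixel_pitch_mm <= 0) stop("phantom_spec: pixel_pitch_mm must be > 0")
  if (s$n_coils < 0 || s$n_distractors < 0)
    stop("phantom_spec: counts must be >= 0")
  r <- s$coil_radius_px_range
  if (length(r) != 2 || r[1] > r[2])
    stop("phantom_spec: coil_radius_px_range must be c(lo, hi) with lo <= hi")
  if (r[2] >= min(s$image_height_px, s$image_width_px) / 2)
    stop("phantom_spec: coil radius too large for the image")
  if (s$wire_thickness_px <= 0) stop("phantom_spec: wire_thickness_px must be > 0")
  if (s$coil_attenuation <= 0) stop("phantom_spec: coil_attenuation must be > 0")
  if (s$background_attenuation_scale < 0)
    stop("phantom_spec: background_attenuation_scale must be >= 0")
  if (s$collimator_margin_px < 0)
    stop("phantom_spec: collimator_margin_px must be >= 0")
  m <- s$collimator_margin_px
  if (s$image_height_px - 2 * m <= 0 || s$image_width_px - 2 * m <= 0)
    stop("phantom_spec: collimator margins leave no open field")
  if (s$noise_poisson_scale < 0)
    stop("phantom_spec: noise_poisson_scale must be >= 0")
  if (s$windowing_gamma <= 0) stop("phantom_spec: windowing_gamma must be > 0")
  invisible(s)
}

# Run code under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- rasterization helpers ------------------------------------------------

# Stamp a polyline (matrix of 0-based real (row, col) sample points) onto an
# H x W logical mask with a round brush of the given diameter.
stamp_polyline <- function(H, W, pts, thickness) {
  rad <- max(thickness / 2, 0.5)
  ri <- ceiling(rad)
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 1e-9, , drop = FALSE]
  if (nrow(off) == 0) off <- data.frame(dr = 0, dc = 0)
  r0 <- round(pts[, 1]); c0 <- round(pts[, 2])
  rr <- rep(r0, each = nrow(off)) + rep(off$dr, times = length(r0))
  cc <- rep(c0, each = nrow(off)) + rep(off$dc, times = length(r0))
  keep <- rr >= 0 & rr < H & cc >= 0 & cc < W
  mask <- matrix(FALSE, H, W)
  mask[cbind(rr[keep] + 1, cc[keep] + 1)] <- TRUE
  mask
}

# Tightly packed, jittered Archimedean spiral: rings spaced ~1.5 wire
# thicknesses, so the rendered coil is a nearly solid absorber (a packed
# embolization coil reads as a solid dark mass on radiographs) and a
# sigma~9 blur fuses it into a single dark blob.
coil_points_spiral <- function(center_rc, radius, thickness) {
  turns <- max(2, round(radius / (1.5 * thickness)))
  theta_max <- 2 * pi * turns
  arc <- pi * radius * turns               # approximate total arc length
  n <- max(200L, ceiling(2 * arc))
  theta <- seq(0, theta_max, length.out = n)
  # smooth radial jitter from a coarse random profile
  knots <- pmax(8L, turns * 4L)
  prof <- stats::spline(seq(0, theta_max, length.out = knots),
                        stats::rnorm(knots, 0, 0.05), xout = theta)$y
  r <- radius * (0.12 + 0.88 * theta / theta_max) * (1 + prof)
  r <- pmin(pmax(r, 0), radius)
  cbind(center_rc[1] + r * sin(theta), center_rc[2] + r * cos(theta))
}

# Sparse self-intersecting random walk confined to a disk; emulates a
# loosely packed framing coil that encloses mostly background.
coil_points_irregular <- function(center_rc, radius, thickness) {
  n <- max(200L, ceiling(7 * radius))
  pts <- matrix(0, n, 2)
  pos <- center_rc + stats::runif(2, -radius / 3, radius / 3)
  ang <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n)) {
    ang <- ang + stats::rnorm(1, 0, 0.3)
    step <- c(sin(ang), cos(ang)) * 1.5
    cand <- pos + step
    if (sqrt(sum((cand - center_rc)^2)) > radius * 0.95) {
      # steer back toward the center
      ang <- atan2(center_rc[1] - pos[1], center_rc[2] - pos[2]) +
        stats::rnorm(1, 0, 0.4)
      cand <- pos + c(sin(ang), cos(ang)) * 1.5
    }
    pos <- cand
    pts[i, ] <- pos
  }
  pts
}

# Filled disk of the given radius (idealized fully packed coil mass).
disk_mask <- function(H, W, center_rc, radius) {
  rr <- matrix(seq_len(H) - 1, H, W)
  cc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  (rr - center_rc[1])^2 + (cc - center_rc[2])^2 <= radius^2
}

# Catheter/guidewire: a smooth spline across the open field.
distractor_points <- function(H, W, margin) {
  lo_r <- margin; hi_r <- H - margin - 1
  lo_c <- margin; hi_c <- W - margin - 1
  vertical <- stats::runif(1) < 0.5
  if (vertical) {
    r <- c(lo_r, stats::runif(2, lo_r, hi_r), hi_r)
    c <- stats::runif(4, lo_c, hi_c)
  } else {
    c <- c(lo_c, stats::runif(2, lo_c, hi_c), hi_c)
    r <- stats::runif(4, lo_r, hi_r)
  }
  t0 <- seq(0, 1, length.out = 4)
  tt <- seq(0, 1, length.out = 4 * max(H, W))
  cbind(stats::spline(t0, r, xout = tt)$y, stats::spline(t0, c, xout = tt)$y)
}

# Skull-like background: soft-edged ellipse plus a low-frequency field.
background_attenuation <- function(H, W, scale) {
  if (scale <= 0) return(matrix(0, H, W))
  rr <- matrix(seq_len(H) - 1, H, W)
  cc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  cy <- (H - 1) / 2 + stats::runif(1, -0.05, 0.05) * H
  cx <- (W - 1) / 2 + stats::runif(1, -0.05, 0.05) * W
  ay <- 0.38 * H * stats::runif(1, 0.9, 1.1)
  ax <- 0.42 * W * stats::runif(1, 0.9, 1.1)
  q <- ((rr - cy) / ay)^2 + ((cc - cx) / ax)^2
  ellipse <- 0.5 * (1 + tanh((1 - q) / 0.15))
  field <- matrix(0, H, W)
  for (k in 1:3) {
    fy <- stats::runif(1, 0.5, 2) * pi / H
    fx <- stats::runif(1, 0.5, 2) * pi / W
    ph <- stats::runif(2, 0, 2 * pi)
    field <- field + cos(rr * fy + ph[1]) * cos(cc * fx + ph[2])
  }
  field <- field / 3
  scale * (0.2 + 0.6 * ellipse + 0.15 * (field + 1) / 2)
}

# Tight 0-based half-open box around the nonzero pixels of a mask.
mask_tight_box <- function(mask) {
  nz <- which(mask, arr.ind = TRUE)
  if (nrow(nz) == 0) return(NULL)
  bbox(min(nz[, 2]) - 1, min(nz[, 1]) - 1, max(nz[, 2]), max(nz[, 1]))
}

# ---- rendering ------------------------------------------------------------

#' Render one synthetic angiography frame with ground truth
#'
#' Builds an attenuation map `L` (background + coil wires + distractors),
#' converts it to unit-output detector signal `exp(-L)`, applies Poisson
#' noise and gamma windowing, and zeroes the collimator margins. Coils are
#' the strongest absorbers and hence the darkest structures in the frame.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `"phantom_scene"` with elements
#'   \describe{
#'     \item{frame}{[raw_frame()]: pixels in `[0,1]` plus acquisition
#'       geometry (flip/rotation flags, collimator rectangle, pixel pitch).}
#'     \item{truth}{ground truth: `boxes` (data frame, one tight box per
#'       coil), `coil_masks` (list of logical matrices in the corrected
#'       orientation) and `patient_id`.}
#'     \item{attenuation}{the noiseless line-integral attenuation map `L`
#'       (corrected orientation), used by the dose simulator.}
#'   }
#' @examples
#' sc <- render_frame(phantom_spec(n_coils = 1, seed = 7))
#' sc$truth$boxes
#' @export
render_frame <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, render_frame_impl(spec))
}

render_frame_impl <- function(spec) {
  H <- spec$image_height_px; W <- spec$image_width_px
  m <- spec$collimator_margin_px
  L <- background_attenuation(H, W, spec$background_attenuation_scale)

  pad <- spec$wire_thickness_px + 3
  centers <- matrix(numeric(0), 0, 2); radii <- numeric(0)
  coil_masks <- vector("list", spec$n_coils)
  for (i in seq_len(spec$n_coils)) {
    placed <- FALSE
    for (try in seq_len(40L)) {
      rad <- stats::runif(1, spec$coil_radius_px_range[1],
                          spec$coil_radius_px_range[2])
      lo_r <- m + rad + pad; hi_r <- H - 1 - m - rad - pad
      lo_c <- m + rad + pad; hi_c <- W - 1 - m - rad - pad
      if (hi_r <= lo_r || hi_c <= lo_c)
        stop(sprintf("phantom: coil %d does not fit inside the open field", i))
      ctr <- c(stats::runif(1, lo_r, hi_r), stats::runif(1, lo_c, hi_c))
      sep <- if (nrow(centers) == 0) TRUE else
        all(sqrt(rowSums(sweep(centers, 2, ctr)^2)) >
              radii + rad + 2 * spec$wire_thickness_px + 4)
      if (sep) { placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf("phantom: could not place coil %d without overlap", i))
    mask <- if (spec$coil_mode == "disk") disk_mask(H, W, ctr, rad) else {
      pts <- switch(spec$coil_mode,
                    spiral = coil_points_spiral(ctr, rad, spec$wire_thickness_px),
                    irregular = coil_points_irregular(ctr, rad, spec$wire_thickness_px))
      stamp_polyline(H, W, pts, spec$wire_thickness_px)
    }
    coil_masks[[i]] <- mask
    centers <- rbind(centers, ctr); radii <- c(radii, rad)
    L <- L + spec$coil_attenuation * mask
  }

  for (d in seq_len(spec$n_distractors)) {
    pts <- distractor_points(H, W, m)
    L <- L + spec$distractor_attenuation *
      stamp_polyline(H, W, pts, spec$wire_thickness_px)
  }

  S <- exp(-L)
  if (spec$noise_poisson_scale > 0) {
    S <- matrix(stats::rpois(length(S), S * spec$noise_poisson_scale) /
                  spec$noise_poisson_scale, H, W)
  }
  S <- pmin(pmax(S, 0), 1)^spec$windowing_gamma
  if (m > 0) {
    open <- matrix(FALSE, H, W)
    open[(m + 1):(H - m), (m + 1):(W - m)] <- TRUE
    S[!open] <- 0
  }
  rect <- if (m > 0) bbox(m, m, W - m, H - m) else bbox(0, 0, W, H)

  boxes <- do.call(rbind, lapply(coil_masks, function(mk) {
    b <- mask_tight_box(mk)
    data.frame(xmin = b[["xmin"]], ymin = b[["ymin"]],
               xmax = b[["xmax"]], ymax = b[["ymax"]], label = "coil")
  }))
  if (is.null(boxes))
    boxes <- cbind(empty_box_df(), data.frame(label = character(0)))

  fh <- fv <- FALSE; rot <- 0L
  if (spec$randomize_orientation) {
    fh <- stats::runif(1) < 0.5; fv <- stats::runif(1) < 0.5
    rot <- sample(0:3, 1)
    # store pixels so that flip-then-rotate recovers the canonical frame
    S <- flip_matrix(rot90_matrix(S, (4L - rot) %% 4L), fh, fv)
  }

  frame <- raw_frame(S, flip_horizontal = fh, flip_vertical = fv,
                     rotation_quarter_turns = rot, collimator_rect = rect,
                     pixel_pitch_mm = spec$pixel_pitch_mm)
  structure(list(frame = frame,
                 truth = list(boxes = boxes, coil_masks = coil_masks,
                              patient_id = NA_integer_),
                 attenuation = L,
                 spec = spec),
            class = "phantom_scene")
}

#' Derive a series of frame specifications from a base spec
#'
#' Gives each frame its own sub-seed (derived deterministically from
#' `seed`) while keeping all other study conditions fixed.
#'
#' @param n Number of frames.
#' @param base A [phantom_spec()] supplying all non-seed parameters.
#' @param seed Master seed for the series.
#' @return A list of `n` phantom specs.
#' @export
phantom_spec_series <- function(n, base = phantom_spec(), seed = 1L) {
  subseeds <- with_seed(seed, sample.int(2^30, n))
  lapply(seq_len(n), function(i) {
    s <- unclass(base)
    s$seed <- as.integer(subseeds[i])
    structure(s, class = "phantom_spec")
  })
}

#' Render a dataset of phantom frames to disk (TIFF + Pascal-VOC XML)
#'
#' Writes one 16-bit single-channel TIFF and one VOC-style XML annotation
#' per frame, assigns frames to patients with a long-tailed skew (every
#' patient receives at least one frame, interventional-style patients
#' receive many), and returns the manifest, which is also written as
#' `manifest.csv`.
#'
#' @param specs List of [phantom_spec()] objects (see
#'   [phantom_spec_series()]).
#' @param patients Number of patients (>= 1) to distribute frames over.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the patient assignment.
#' @return Invisibly, the manifest data frame with columns `frame_id`,
#'   `tiff`, `xml`, `patient_id`, `n_coils`, `seed`.
#' @export
render_dataset <- function(specs, patients, out_dir, seed = 1L) {
  stopifnot(patients >= 1, length(specs) >= 1)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop(sprintf("render_dataset: cannot create '%s'", out_dir))
  n <- length(specs)
  patient_id <- with_seed(seed, {
    ids <- integer(n)
    base <- rep_len(seq_len(patients), min(patients, n))
    ids[seq_along(base)] <- sample(base)
    if (n > patients) {
      w <- exp(-0.35 * (seq_len(patients) - 1))
      ids[(patients + 1):n] <- sample.int(patients, n - patients,
                                          replace = TRUE, prob = w)
    }
    ids
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- render_frame(specs[[i]])
    fid <- sprintf("frame_%04d", i)
    tiff_path <- file.path(out_dir, paste0(fid, ".tif"))
    xml_path <- file.path(out_dir, paste0(fid, ".xml"))
    write_frame_tiff(sc$frame$pixels, tiff_path)
    write_voc_xml(xml_path, filename = basename(tiff_path),
                  width = ncol(sc$frame$pixels), height = nrow(sc$frame$pixels),
                  boxes = sc$truth$boxes)
    write_geometry_yaml(file.path(out_dir, paste0(fid, ".geom.yaml")), sc$frame)
    rows[[i]] <- data.frame(frame_id = fid, tiff = basename(tiff_path),
                            xml = basename(xml_path), patient_id = patient_id[i],
                            n_coils = nrow(sc$truth$boxes),
                            seed = specs[[i]]$seed)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
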