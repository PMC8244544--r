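#' Specification of one synthetic stoma
#'
#' A stoma is drawn as a bright elliptical guard-cell outline with a dark
#' elliptical aperture inside it. The centre never moves: real stomata are
#' effectively immovable under the microscope and only vary in opening size,
#' which is the assumption the tracker relies on. The aperture's semi-axes are
#' rescaled isotropically over time so that the rasterized area follows the
#' programmed kinetics, and are capped so the aperture stays strictly inside
#' the guard outline.
#'
#' @param center `(x, y)` pixel coordinates of the stoma centre (0-based,
#'   x rightward, y downward).
#' @param orientation major-axis angle in degrees, counter-clockwise.
#' @param guard_axes semi-axes `(a_g, b_g)` in px of the guard-cell outline.
#' @param aperture_axes initial aperture semi-axes `(a0, b0)` in px; must be
#'   strictly inside `guard_axes`.
#' @param kinetics a [kinetics_spec()].
#' @return an object of class `stoma_spec`.
#' @export
stoma_spec <- function(center, orientation = 0, guard_axes = c(26, 16),
                       aperture_axes = c(14, 7),
                       kinetics = kinetics_spec("constant")) {
  stopifnot(length(center) == 2, length(guard_axes) == 2,
            length(aperture_axes) == 2, all(guard_axes > 0),
            all(aperture_axes > 0), inherits(kinetics, "kinetics_spec"))
  if (any(aperture_axes >= guard_axes)) {
    stop("aperture axes must be strictly smaller than guard axes")
  }
  structure(list(center = as.numeric(center),
                 orientation = as.numeric(orientation),
                 guard_axes = as.numeric(guard_axes),
                 aperture_axes = as.numeric(aperture_axes),
                 kinetics = kinetics),
            class = "stoma_spec")
}

#' Aperture semi-axes of a stoma at time t
#'
#' Isotropic rescaling of the initial axes so that `pi * a(t) * b(t)` equals
#' the kinetics area, capped at 95% of the guard axes.
#'
#' @param stoma a [stoma_spec()].
#' @param t time in seconds (scalar).
#' @return numeric `(a, b)` semi-axes in px (possibly zero).
#' @export
aperture_axes_at <- function(stoma, t) {
  a0 <- stoma$aperture_axes[1]
  b0 <- stoma$aperture_axes[2]
  area0 <- pi * a0 * b0
  area_t <- aperture_area(stoma$kinetics, area0, t)
  s <- sqrt(area_t / area0)
  s_max <- 0.95 * min(stoma$guard_axes / stoma$aperture_axes)
  s <- min(s, s_max)
  c(a0, b0) * s
}

#' Specification of a synthetic microscope scene
#'
#' Describes a video of stationary stomata on a textured leaf background with
#' sensor noise and slow illumination drift. Identical specs (same seed)
#' render bit-identically.
#'
#' @param width,height frame size in px; defaults match the 640 x 480
#'   microscope recordings the pipeline targets.
#' @param fps frames per second (default 20, the recording frame rate);
#'   fractional values are allowed for sparse long-duration renders.
#' @param duration video length in seconds.
#' @param stomata list of [stoma_spec()] objects.
#' @param noise_sigma per-pixel Gaussian sensor noise, intensity units on the
#'   `[0, 1]` scale.
#' @param illumination_drift fractional brightness ramp per minute (e.g. 0.02
#'   brightens the frame by 2% per minute).
#' @param seed integer RNG seed controlling texture and noise.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width = 640, height = 480, fps = 20, duration = 10,
                       stomata = list(), noise_sigma = 0.02,
                       illumination_drift = 0.02, seed = 1L) {
  stopifnot(width > 0, height > 0, fps > 0, duration > 0, noise_sigma >= 0)
  stopifnot(all(vapply(stomata, inherits, logical(1), "stoma_spec")))
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, duration = duration, stomata = stomata,
                 noise_sigma = noise_sigma,
                 illumination_drift = illumination_drift,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
format.scene_spec <- function(x, ...) {
  sprintf("<scene_spec %dx%d @ %g fps, %g s, %d stomata, seed %d>",
          x$width, x$height, x$fps, x$duration, length(x$stomata), x$seed)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

n_frames <- function(scene) as.integer(round(scene$fps * scene$duration))

# run expr with a locally-derived RNG state, restoring the caller's state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# band-limited texture standing in for epidermal cell relief: blurred white
# noise, fixed per scene (it does not change between frames)
scene_background <- function(scene) {
  with_local_seed(scene$seed, {
    noise <- matrix(runif(scene$height * scene$width),
                    nrow = scene$height, ncol = scene$width)
    sm <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(noise)),
                                              sigma = 3)))
    sm <- (sm - mean(sm)) / max(stats::sd(sm), 1e-12)
    0.55 + 0.05 * sm
  })
}

# pixel-centre inclusion test for a rotated ellipse; returns a logical matrix
ellipse_mask <- function(width, height, center, axes, orientation_deg) {
  if (min(axes) <= 0) {
    return(matrix(FALSE, nrow = height, ncol = width))
  }
  x <- matrix(rep(0:(width - 1), each = height), nrow = height)
  y <- matrix(rep(0:(height - 1), times = width), nrow = height)
  dx <- x - center[1]
  dy <- y - center[2]
  th <- orientation_deg * pi / 180
  u <- (dx * cos(th) + dy * sin(th)) / axes[1]
  v <- (-dx * sin(th) + dy * cos(th)) / axes[2]
  u * u + v * v <= 1
}

#' Render one frame of a synthetic scene
#'
#' Produces the intensity image (textured background, bright guard-cell
#' outlines, dark apertures, sensor noise, illumination drift) and the exact
#' ground-truth aperture mask. Masks are rasterized by centre-of-pixel
#' inclusion so that ground truth stays integer-valued.
#'
#' @param scene a [scene_spec()].
#' @param t time in seconds, `0 <= t <= duration`.
#' @return list with `image` (height x width matrix in `[0, 1]`) and `mask`
#'   (height x width integer matrix, 0 = background, 1 = aperture).
#' @examples
#' sc <- scene_spec(width = 96, height = 64, duration = 1, fps = 5,
#'                  stomata = list(stoma_spec(center = c(48, 32))))
#' fr <- render_frame(sc, 0)
#' sum(fr$mask)   # rasterized aperture area in px
#' @export
render_frame <- function(scene, t) {
  stopifnot(inherits(scene, "scene_spec"))
  if (t < 0 || t > scene$duration) {
    stop("t outside [0, duration]")
  }
  img <- scene_background(scene)
  mask <- matrix(0L, nrow = scene$height, ncol = scene$width)
  for (st in scene$stomata) {
    guard <- ellipse_mask(scene$width, scene$height, st$center,
                          st$guard_axes, st$orientation)
    inner <- ellipse_mask(scene$width, scene$height, st$center,
                          0.82 * st$guard_axes, st$orientation)
    ring <- guard & !inner
    img[ring] <- pmin(img[ring] + 0.22, 1)     # bright guard-cell rim
    img[inner] <- img[inner] * 0.85            # slightly shaded pore field
    ap <- ellipse_mask(scene$width, scene$height, st$center,
                       aperture_axes_at(st, t), st$orientation)
    img[ap] <- 0.12                            # dark open aperture
    mask[ap] <- 1L
  }
  k <- as.integer(round(t * scene$fps))
  img <- img * (1 + scene$illumination_drift * t / 60)
  if (scene$noise_sigma > 0) {
    img <- img + with_local_seed(
      (as.numeric(scene$seed) * 7919 + k) %% 2147483647,
      matrix(rnorm(length(img), sd = scene$noise_sigma),
             nrow = nrow(img)))
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Analytic and rasterized ground-truth SOA table for a scene
#'
#' One row per (frame, stoma): the analytic kinetics area `pi * a(t) * b(t)`
#' and the rasterized pixel count actually present in the ground-truth mask.
#'
#' @param scene a [scene_spec()].
#' @return data.frame with columns `frame_index`, `time_s`, `stoma_id`,
#'   `soa_analytic_px2`, `soa_raster_px`.
#' @export
scene_ground_truth <- function(scene) {
  nf <- n_frames(scene)
  ns <- length(scene$stomata)
  rows <- vector("list", nf)
  for (k in seq_len(nf)) {
    t <- (k - 1) / scene$fps
    analytic <- numeric(ns)
    raster <- integer(ns)
    for (s in seq_len(ns)) {
      st <- scene$stomata[[s]]
      ax <- aperture_axes_at(st, t)
      analytic[s] <- pi * ax[1] * ax[2]
      raster[s] <- sum(ellipse_mask(scene$width, scene$height, st$center,
                                    ax, st$orientation))
    }
    rows[[k]] <- data.frame(frame_index = k - 1L, time_s = t,
                            stoma_id = seq_len(ns), soa_analytic_px2 = analytic,
                            soa_raster_px = raster)
  }
  do.call(rbind, rows)
}

#' Render a full synthetic video with ground truth
#'
#' Writes the frames (lossless image-sequence directory or uncompressed AVI),
#' the per-frame ground-truth masks (plus a x255 visual variant), and the SOA
#' ground-truth table.
#'
#' @param scene a [scene_spec()].
#' @param out_dir output directory, created if missing.
#' @param format `"dir"` for a lossless PNG image sequence (canonical),
#'   `"avi"` for an uncompressed AVI container.
#' @param write_masks write per-frame ground-truth masks under `masks/` and
#'   `masks_visual/`.
#' @return invisibly, a list with `video` (path), `ground_truth` (path of the
#'   SOA CSV), `n_frames`, and the ground-truth data.frame.
#' @export
generate_video <- function(scene, out_dir, format = c("dir", "avi"),
                           write_masks = TRUE) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  nf <- n_frames(scene)
  frames <- vector("list", nf)
  if (write_masks) {
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks_visual"), showWarnings = FALSE)
  }
  for (k in seq_len(nf)) {
    fr <- render_frame(scene, (k - 1) / scene$fps)
    frames[[k]] <- fr$image
    if (write_masks) {
      write_mask(fr$mask,
                 file.path(out_dir, "masks", sprintf("mask_%05d.png", k - 1)))
      write_mask(fr$mask,
                 file.path(out_dir, "masks_visual",
                           sprintf("mask_%05d.png", k - 1)),
                 visual = TRUE)
    }
  }
  fs <- frame_sequence(frames, fps = scene$fps)
  video_path <- if (format == "avi") {
    p <- file.path(out_dir, "video.avi")
    write_video(fs, p)
    p
  } else {
    p <- file.path(out_dir, "frames")
    write_video(fs, p)
    p
  }
  gt <- scene_ground_truth(scene)
  gt_path <- file.path(out_dir, "ground_truth_soa.csv")
  write.csv(gt, gt_path, row.names = FALSE)
  invisible(list(video = video_path, ground_truth = gt_path,
                 n_frames = nf, table = gt))
}

#' Preset chilling-stress closure scene
#'
#' Three stomata with logistic closure kinetics at staggered rates and
#' midpoints, emulating the patchy closure seen under chilling: faster closers
#' (larger `k`) reach their fastest-closing moment earlier (smaller `t0`), and
#' all apertures are essentially closed within the 10-minute window.
#'
#' @param width,height frame size in px.
#' @param fps sampling rate of the render; the default 0.1 gives one frame
#'   every 10 s over the 600 s episode.
#' @param seed scene RNG seed.
#' @return a [scene_spec()] of duration 600 s.
#' @export
scene_chilling_demo <- function(width = 192, height = 144, fps = 0.1,
                                seed = 7L) {
  mk <- function(cx, cy, k, t0, ap = c(14, 7)) {
    stoma_spec(center = c(cx, cy), orientation = 15 * cx %% 60,
               guard_axes = c(26, 16), aperture_axes = ap,
               kinetics = kinetics_spec("logistic_closure", A_end = 0,
                                        k = k, t0 = t0))
  }
  scene_spec(width = width, height = height, fps = fps, duration = 600,
             stomata = list(mk(45, 40, k = 0.08, t0 = 120),
                            mk(130, 50, k = 0.05, t0 = 210),
                            mk(85, 105, k = 0.03, t0 = 300)),
             seed = seed)
}

#' Generate a ground-truthed crop dataset for segmentation training
#'
#' Renders `n` independent single-stoma crops (image + aperture mask) with
#' randomized stoma geometry, orientation and opening fraction, each from its
#' own seeded mini scene. A fifth of the crops show an effectively closed
#' stoma (sub-pixel aperture, empty mask) so the segmenter sees the closure
#' endpoint it must recognize in stress time courses. Used to train and
#' benchmark the segmentation network without real annotated data.
#'
#' @param n number of crops.
#' @param size square crop side in px.
#' @param seed integer seed; crop `i` derives its own sub-seed from it.
#' @param closed_frac fraction of crops rendered with a closed aperture.
#' @return list of `n` elements, each `list(image =, mask =)`.
#' @export
synth_crop_dataset <- function(n, size = 64, seed = 1L, closed_frac = 0.2) {
  lapply(seq_len(n), function(i) {
    par <- with_local_seed((as.numeric(seed) * 131071 + i) %% 2147483647, {
      list(cx = runif(1, 0.35, 0.65) * size,
           cy = runif(1, 0.35, 0.65) * size,
           th = runif(1, 0, 180),
           ag = runif(1, 0.28, 0.40) * size,
           ratio = runif(1, 0.45, 0.7),
           open_frac = runif(1, 0.15, 0.75),
           closed = runif(1) < closed_frac,
           sub_seed = sample.int(2147483646L, 1))
    })
    guard <- c(par$ag, par$ag * par$ratio)
    ap <- if (par$closed) c(0.3, 0.15) else guard * sqrt(par$open_frac) * 0.9
    sc <- scene_spec(width = size, height = size, fps = 1, duration = 1,
                     stomata = list(stoma_spec(center = c(par$cx, par$cy),
                                               orientation = par$th,
                                               guard_axes = guard,
                                               aperture_axes = ap)),
                     seed = par$sub_seed)
    render_frame(sc, 0)
  })
}
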