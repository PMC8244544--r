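#' Time-ordered frame sequence
#'
#' Container for video frames as grayscale intensity matrices in `[0, 1]`,
#' plus timing metadata. Pixel coordinates are 0-based with `(0, 0)` at the
#' top-left, x rightward and y downward; boxes are half-open
#' `[x, x + w) x [y, y + h)`.
#'
#' @param frames list of numeric matrices, all the same size.
#' @param fps frames per second of the underlying recording.
#' @param t0 time offset of the first frame in seconds.
#' @param times optional explicit per-frame times (overrides the uniform
#'   grid), strictly increasing.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps = 20, t0 = 0, times = NULL) {
  stopifnot(is.list(frames), length(frames) > 0, fps > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have identical dimensions")
  }
  if (is.null(times)) {
    times <- t0 + (seq_along(frames) - 1) / fps
  }
  stopifnot(length(times) == length(frames), all(diff(times) > 0))
  structure(list(frames = frames, fps = fps, t0 = t0, times = times),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence: %d frames of %dx%d, fps %g, t in [%g, %g] s>\n",
              length(x$frames), d[2], d[1], x$fps, min(x$times), max(x$times)))
  invisible(x)
}

#' Read a video, sampling every `interval`-th frame
#'
#' Accepts either an uncompressed AVI file or a lossless image-sequence
#' directory (PNG frames named in lexical order plus a `sequence.yaml`
#' sidecar carrying the fps). Sampling keeps frame 0 and every `interval`-th
#' frame after it; sampled times are `frame_index / fps`.
#'
#' @param path AVI file or image-sequence directory.
#' @param interval sampling stride in frames, `>= 1`.
#' @param fps fallback frames-per-second when the source carries none.
#' @return a [frame_sequence()] of the sampled frames.
#' @export
read_video <- function(path, interval = 1L, fps = 20) {
  interval <- as.integer(interval)
  stopifnot(interval >= 1L)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) stop("empty video: no PNG frames in ", path)
    meta <- file.path(path, "sequence.yaml")
    if (file.exists(meta)) {
      fps <- yaml::read_yaml(meta)$fps
    }
    idx <- seq(1L, length(files), by = interval)
    frames <- lapply(files[idx], read_gray_png)
  } else if (file.exists(path)) {
    av <- read_avi(path)
    fps <- av$fps
    idx <- seq(1L, length(av$frames), by = interval)
    frames <- av$frames[idx]
  } else {
    stop("video not found: ", path)
  }
  frame_sequence(frames, fps = fps, times = (idx - 1) / fps)
}

#' Write a frame sequence as a video
#'
#' A path ending in `.avi` produces an uncompressed AVI; any other path is
#' treated as an image-sequence directory (8-bit PNG frames plus a
#' `sequence.yaml` fps sidecar). The directory dialect is lossless.
#'
#' @param fs a [frame_sequence()].
#' @param path output AVI file or directory.
#' @return invisibly, `path`.
#' @export
write_video <- function(fs, path) {
  stopifnot(inherits(fs, "frame_sequence"))
  if (grepl("\\.avi$", path, ignore.case = TRUE)) {
    write_avi(fs$frames, fs$fps, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(fs$frames)) {
      png::writePNG(pmin(pmax(fs$frames[[k]], 0), 1),
                    file.path(path, sprintf("frame_%05d.png", k - 1L)))
    }
    yaml::write_yaml(list(fps = fs$fps), file.path(path, "sequence.yaml"))
  }
  invisible(path)
}

read_gray_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px
}

#' Read / write 2-class segmentation masks
#'
#' Masks are 8-bit single-channel PNGs holding class indices, 0 = background
#' and 1 = stomatal aperture. Because index 1 is visually indistinguishable
#' from 0, a "visual" variant scales values by 255 for inspection.
#'
#' @param path PNG file path.
#' @return integer matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path) {
  px <- read_gray_png(path)
  m <- matrix(as.integer(round(px * 255)), nrow = nrow(px))
  if (all(m %in% c(0L, 255L)) && any(m == 255L)) {
    m <- m %/% 255L                      # visual variant folds back to {0,1}
  }
  if (!all(m %in% c(0L, 1L))) {
    stop("mask contains values outside {0, 1}")
  }
  m
}

#' @rdname read_mask
#' @param mask integer matrix with values in `{0, 1}`.
#' @param visual write the x255 visualization variant instead of raw indices.
#' @export
write_mask <- function(mask, path, visual = FALSE) {
  if (!all(mask %in% c(0L, 1L))) {
    stop("mask contains values outside {0, 1}")
  }
  scale <- if (visual) 255 else 1
  png::writePNG(matrix(mask * scale / 255, nrow = nrow(mask)), path)
  invisible(path)
}

#' Write / read SOA result tables
#'
#' The pipeline's tabular output: one row per sampled frame per tracked
#' stoma, CSV with header `time_s, stoma_id, soa_px`.
#'
#' @param table data.frame with columns `time_s`, `stoma_id`, `soa_px`.
#' @param path CSV file path.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("refusing to write an empty result table")
  need <- c("time_s", "stoma_id", "soa_px")
  if (!all(need %in% names(table))) {
    stop("result table must have columns: ", paste(need, collapse = ", "))
  }
  write.csv(table[, union(need, names(table))], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.csv(path)
}

#' Read a gas-exchange log
#'
#' Expects a CSV with header `time_s, Pn, Ci, Gs, Tr` (seconds; instrument
#' units: umol m-2 s-1 for Pn/Tr, umol mol-1 for Ci, mol m-2 s-1 for Gs).
#' Portable photosynthesis systems log on a uniform 30-s grid; gaps are
#' tolerated. Exports from such instruments should be reduced to these five
#' columns before loading.
#'
#' @param path CSV file path.
#' @return data.frame with the five columns, ordered by time.
#' @export
read_gas_exchange <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "Pn", "Ci", "Gs", "Tr")
  if (!all(need %in% names(df))) {
    stop("gas-exchange table must have columns: ", paste(need, collapse = ", "))
  }
  df[order(df$time_s), need]
}
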