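#' Kernelized correlation filter (KCF) tracking
#'
#' Raw-pixel KCF: ridge regression over all cyclic shifts of a padded,
#' cosine-windowed grayscale template, solved in the frequency domain with a
#' Gaussian kernel. The response-map peak between frames localizes the
#' target. Stomata are stationary and only vary in opening size, so this
#' classical tracker needs no training data and its behaviour is fully
#' checkable against a dense cross-correlation oracle.
#'
#' @name kcf
NULL

#' Bounding box
#'
#' @param x,y top-left corner in pixels (0-based).
#' @param w,h width and height in pixels, `> 0`.
#' @return an object of class `bounding_box`.
#' @export
bounding_box <- function(x, y, w, h) {
  stopifnot(w > 0, h > 0)
  structure(list(x = as.integer(round(x)), y = as.integer(round(y)),
                 w = as.integer(round(w)), h = as.integer(round(h))),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<box x=%d y=%d w=%d h=%d>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

#' KCF hyperparameters
#'
#' @param padding window padding factor around the target box.
#' @param sigma Gaussian kernel bandwidth (relative to the unit-normalized
#'   patch inner products).
#' @param lambda ridge regularization.
#' @param eta model interpolation factor per update.
#' @param output_sigma_factor bandwidth of the Gaussian regression target as
#'   a fraction of the target size.
#' @return named list of hyperparameters.
#' @export
kcf_params <- function(padding = 1.5, sigma = 0.2, lambda = 1e-4,
                       eta = 0.075, output_sigma_factor = 0.1) {
  list(padding = padding, sigma = sigma, lambda = lambda, eta = eta,
       output_sigma_factor = output_sigma_factor)
}

hann2 <- function(nr, nc) {
  hr <- if (nr == 1) 1 else 0.5 * (1 - cos(2 * pi * (0:(nr - 1)) / (nr - 1)))
  hc <- if (nc == 1) 1 else 0.5 * (1 - cos(2 * pi * (0:(nc - 1)) / (nc - 1)))
  outer(hr, hc)
}

# Gaussian regression target with its peak at index (1,1), wrapped
gaussian_labels <- function(nr, nc, sigma) {
  di <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dj <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  exp(-0.5 * outer(di^2, dj^2, "+") / sigma^2)
}

# extract a window centred on (cx, cy) with edge replication
extract_patch <- function(frame, cx, cy, win_w, win_h) {
  xs <- floor(cx - win_w / 2) + seq_len(win_w)   # 0-based pixel columns
  ys <- floor(cy - win_h / 2) + seq_len(win_h)
  xs <- pmin(pmax(xs, 1L), ncol(frame))
  ys <- pmin(pmax(ys, 1L), nrow(frame))
  frame[ys, xs, drop = FALSE]
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Gaussian kernel auto/cross-correlation of two windowed patches, evaluated
# at all cyclic shifts via frequency-domain products
gaussian_correlation <- function(x1, x2, sigma) {
  n <- length(x1)
  c12 <- Re(ifft2(fft2(x1) * Conj(fft2(x2))))
  d <- (sum(x1^2) + sum(x2^2) - 2 * c12) / n
  d[d < 0] <- 0
  exp(-d / sigma^2)
}

# standardize the patch (zero mean, unit variance) before windowing: the
# Gaussian kernel bandwidth sigma is relative to standardized inner products,
# which keeps the kernel spectrum well away from the -lambda pole of the
# ridge solution regardless of the scene's contrast
preprocess_patch <- function(patch, window) {
  (patch - mean(patch)) / (stats::sd(patch) + 1e-8) * window
}

#' Initialize a KCF tracker on a frame
#'
#' Trains the correlation filter on the padded window around `box`: the dual
#' ridge-regression coefficients are fit against a centred Gaussian response
#' over all cyclic shifts of the patch.
#'
#' @param frame grayscale intensity matrix.
#' @param box a [bounding_box()] fully inside the frame.
#' @param params hyperparameters from [kcf_params()].
#' @return a `kcf_state` object.
#' @export
init_tracker <- function(frame, box, params = kcf_params()) {
  stopifnot(inherits(box, "bounding_box"))
  if (box$w * box$h == 0) stop("degenerate box")
  if (box$x < 0 || box$y < 0 || box$x + box$w > ncol(frame) ||
      box$y + box$h > nrow(frame)) {
    stop("box outside frame")
  }
  win_w <- floor(box$w * (1 + params$padding))
  win_h <- floor(box$h * (1 + params$padding))
  cx <- box$x + box$w / 2
  cy <- box$y + box$h / 2
  window <- hann2(win_h, win_w)
  out_sigma <- sqrt(box$w * box$h) * params$output_sigma_factor
  yf <- fft2(gaussian_labels(win_h, win_w, out_sigma))
  x <- preprocess_patch(extract_patch(frame, cx, cy, win_w, win_h), window)
  k <- gaussian_correlation(x, x, params$sigma)
  alphaf <- yf / (fft2(k) + params$lambda)
  structure(list(params = params, w = box$w, h = box$h,
                 win_w = win_w, win_h = win_h, cx = cx, cy = cy,
                 window = window, yf = yf, model_x = x,
                 model_alphaf = alphaf,
                 frame_dim = dim(frame)),
            class = "kcf_state")
}

# response-map argmax with ties broken by smallest row-major index
argmax_rowmajor <- function(m) {
  mx <- max(m)
  hits <- which(m == mx, arr.ind = TRUE)
  ord <- order((hits[, 1] - 1L) * ncol(m) + hits[, 2])
  hits[ord[1], ]
}

#' Advance a KCF tracker by one frame
#'
#' Evaluates the correlation response of the stored filter on the new frame's
#' window, moves the box to the integer response peak, and interpolates the
#' appearance model and filter towards the new patch by `eta`. Box size is
#' fixed at its initialization value.
#'
#' @param state a `kcf_state` from [init_tracker()].
#' @param frame grayscale matrix of the same size as the initializing frame.
#' @return list with `box` (the new [bounding_box()]), `state` (updated),
#'   `response` (peak response value), and `clamped` (TRUE if the box had to
#'   be clamped to stay inside the frame).
#' @export
update_tracker <- function(state, frame) {
  if (!inherits(state, "kcf_state")) stop("tracker state not initialized")
  if (!all(dim(frame) == state$frame_dim)) {
    stop("frame dimensions differ from the initializing frame")
  }
  p <- state$params
  z <- preprocess_patch(
    extract_patch(frame, state$cx, state$cy, state$win_w, state$win_h),
    state$window)
  kzx <- gaussian_correlation(z, state$model_x, p$sigma)
  resp <- Re(ifft2(fft2(kzx) * state$model_alphaf))
  pk <- argmax_rowmajor(resp)
  dy <- pk[1] - 1L
  dx <- pk[2] - 1L
  if (dy > state$win_h / 2) dy <- dy - state$win_h
  if (dx > state$win_w / 2) dx <- dx - state$win_w
  cx <- state$cx + dx
  cy <- state$cy + dy
  # keep the box inside the frame (frame_dim = c(nrow, ncol))
  cx2 <- min(max(cx, state$w / 2), state$frame_dim[2] - state$w / 2)
  cy2 <- min(max(cy, state$h / 2), state$frame_dim[1] - state$h / 2)
  clamped <- (cx2 != cx) || (cy2 != cy)
  state$cx <- cx2
  state$cy <- cy2
  xnew <- preprocess_patch(
    extract_patch(frame, state$cx, state$cy, state$win_w, state$win_h),
    state$window)
  knew <- gaussian_correlation(xnew, xnew, p$sigma)
  alphaf_new <- state$yf / (fft2(knew) + p$lambda)
  state$model_x <- (1 - p$eta) * state$model_x + p$eta * xnew
  state$model_alphaf <- (1 - p$eta) * state$model_alphaf + p$eta * alphaf_new
  box <- bounding_box(state$cx - state$w / 2, state$cy - state$h / 2,
                      state$w, state$h)
  list(box = box, state = state, response = max(resp), clamped = clamped)
}

crop_box <- function(frame, box) {
  frame[(box$y + 1):(box$y + box$h), (box$x + 1):(box$x + box$w),
        drop = FALSE]
}

#' Track multiple stomata and collect per-stoma crop stacks
#'
#' Runs one independent KCF tracker per initial box across all frames of a
#' sequence and crops the tracked window from every frame.
#'
#' @param fs a [frame_sequence()].
#' @param boxes list of [bounding_box()] drawn on the first frame.
#' @param params shared [kcf_params()].
#' @return list with `crops` (per-stoma list of crop matrices), `boxes`
#'   (per-stoma list of per-frame boxes), `times`, and `flagged` (n_frames x
#'   n_stomata logical: TRUE where the tracker had to be clamped at the frame
#'   border).
#' @export
track_and_crop <- function(fs, boxes, params = kcf_params()) {
  stopifnot(inherits(fs, "frame_sequence"))
  if (length(fs$frames) == 0) stop("empty frame sequence")
  if (length(boxes) < 1) stop("at least one box is required")
  nf <- length(fs$frames)
  ns <- length(boxes)
  crops <- rep(list(vector("list", nf)), ns)
  out_boxes <- rep(list(vector("list", nf)), ns)
  flagged <- matrix(FALSE, nrow = nf, ncol = ns)
  for (s in seq_len(ns)) {
    st <- init_tracker(fs$frames[[1]], boxes[[s]], params)
    out_boxes[[s]][[1]] <- boxes[[s]]
    crops[[s]][[1]] <- crop_box(fs$frames[[1]], boxes[[s]])
    if (nf > 1) {
      for (k in 2:nf) {
        up <- update_tracker(st, fs$frames[[k]])
        st <- up$state
        out_boxes[[s]][[k]] <- up$box
        crops[[s]][[k]] <- crop_box(fs$frames[[k]], up$box)
        flagged[k, s] <- up$clamped
      }
    }
  }
  list(crops = crops, boxes = out_boxes, times = fs$times, flagged = flagged)
}
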