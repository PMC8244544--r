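#' Stochastic image/mask augmentation policy
#'
#' The training-set expansion policy: random rotation up to +/-25 degrees
#' applied with probability 0.80, left-right flip with probability 0.50, and
#' scaling down to 0.85x with probability 0.30 — each an independent draw,
#' applied identically to the image and its mask.
#'
#' @param rotate_max_deg maximum rotation magnitude, degrees.
#' @param rotate_prob probability a pair is rotated.
#' @param hflip_prob probability a pair is flipped left-right.
#' @param scale_factor shrink factor applied when scaling triggers.
#' @param scale_prob probability a pair is scaled.
#' @param seed integer seed for [expand_dataset()].
#' @return an object of class `augment_policy`.
#' @export
augment_policy <- function(rotate_max_deg = 25, rotate_prob = 0.80,
                           hflip_prob = 0.50, scale_factor = 0.85,
                           scale_prob = 0.30, seed = 1L) {
  stopifnot(rotate_max_deg >= 0,
            rotate_prob >= 0, rotate_prob <= 1,
            hflip_prob >= 0, hflip_prob <= 1,
            scale_factor > 0, scale_factor <= 1,
            scale_prob >= 0, scale_prob <= 1)
  structure(list(rotate_max_deg = rotate_max_deg, rotate_prob = rotate_prob,
                 hflip_prob = hflip_prob, scale_factor = scale_factor,
                 scale_prob = scale_prob, seed = as.integer(seed)),
            class = "augment_policy")
}

# reflect an out-of-range 0-based index back into [0, n-1] (mirror with edge
# duplication, period 2n)
reflect_idx <- function(i, n) {
  j <- i %% (2L * n)
  j <- ifelse(j < 0, j + 2L * n, j)
  ifelse(j >= n, 2L * n - 1L - j, j)
}

# inverse-map affine sampler about the image centre. interp "bilinear" with
# reflection fill for intensities, "nearest" with zero fill for masks (keeps
# masks strictly 2-valued).
affine_sample <- function(m, angle_deg, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  h <- nrow(m); w <- ncol(m)
  th <- angle_deg * pi / 180
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  xo <- matrix(rep(0:(w - 1), each = h), nrow = h) - cx
  yo <- matrix(rep(0:(h - 1), times = w), nrow = h) - cy
  # rotate destination grid back into the source frame
  xs <- cos(th) * xo + sin(th) * yo + cx
  ys <- -sin(th) * xo + cos(th) * yo + cy
  if (interp == "nearest") {
    xi <- round(xs); yi <- round(ys)
    inside <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    out <- matrix(0, nrow = h, ncol = w)
    out[inside] <- m[cbind(yi[inside] + 1L, xi[inside] + 1L)]
    matrix(as.integer(out), nrow = h)
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    at <- function(yy, xx) {
      m[cbind(reflect_idx(as.integer(yy), h) + 1L,
              reflect_idx(as.integer(xx), w) + 1L)]
    }
    v <- (1 - fy) * (1 - fx) * at(y0, x0) +
      (1 - fy) * fx * at(y0, x0 + 1) +
      fy * (1 - fx) * at(y0 + 1, x0) +
      fy * fx * at(y0 + 1, x0 + 1)
    matrix(v, nrow = h)
  }
}

# shrink to factor f, then pad back to the original size, centred; images pad
# by reflection, masks by zero
shrink_pad <- function(m, f, interp) {
  h <- nrow(m); w <- ncol(m)
  h2 <- max(1L, as.integer(round(h * f)))
  w2 <- max(1L, as.integer(round(w * f)))
  small <- if (interp == "nearest") {
    matrix(as.integer(resize_nearest(m, h2, w2)), nrow = h2)
  } else {
    resize_bilinear(m, h2, w2)
  }
  oy <- (h - h2) %/% 2L
  ox <- (w - w2) %/% 2L
  if (interp == "nearest") {
    out <- matrix(0L, nrow = h, ncol = w)
    out[oy + seq_len(h2), ox + seq_len(w2)] <- small
  } else {
    ys <- reflect_idx((0:(h - 1)) - oy, h2) + 1L
    xs <- reflect_idx((0:(w - 1)) - ox, w2) + 1L
    out <- small[ys, xs, drop = FALSE]
    out[oy + seq_len(h2), ox + seq_len(w2)] <- small
  }
  out
}

#' Apply one stochastic augmentation draw to an image/mask pair
#'
#' Draw order is rotate, flip, scale, each an independent Bernoulli draw from
#' the current RNG stream. The same geometric transform is applied to both
#' members: bilinear interpolation with reflection fill for the image,
#' nearest-neighbour with zero fill for the mask, so the mask stays strictly
#' 2-valued.
#'
#' @param image intensity matrix.
#' @param mask integer matrix in `{0, 1}`, same size as `image`.
#' @param policy an [augment_policy()].
#' @return list with `image`, `mask`, and `ops` (the realized draws:
#'   `rotated`, `angle`, `flipped`, `scaled`).
#' @export
augment_pair <- function(image, mask, policy = augment_policy()) {
  stopifnot(inherits(policy, "augment_policy"))
  if (!all(dim(image) == dim(mask))) stop("image/mask size mismatch")
  ops <- list(rotated = FALSE, angle = 0, flipped = FALSE, scaled = FALSE)
  if (runif(1) < policy$rotate_prob) {
    ops$rotated <- TRUE
    ops$angle <- runif(1, -policy$rotate_max_deg, policy$rotate_max_deg)
    image <- affine_sample(image, ops$angle, "bilinear")
    mask <- affine_sample(mask, ops$angle, "nearest")
  }
  if (runif(1) < policy$hflip_prob) {
    ops$flipped <- TRUE
    image <- image[, ncol(image):1, drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (runif(1) < policy$scale_prob) {
    ops$scaled <- TRUE
    image <- shrink_pad(image, policy$scale_factor, "bilinear")
    mask <- shrink_pad(mask, policy$scale_factor, "nearest")
  }
  list(image = image, mask = mask, ops = ops)
}

#' Expand a training set with augmented copies
#'
#' Draws `n_new` source pairs with replacement and pushes each through one
#' augmentation draw; the originals are returned untouched alongside the
#' additions. Fully reproducible from `policy$seed`.
#'
#' @param pairs list of `list(image =, mask =)` pairs.
#' @param policy an [augment_policy()].
#' @param n_new number of augmented pairs to add.
#' @return list of `length(pairs) + n_new` pairs (originals first).
#' @export
expand_dataset <- function(pairs, policy = augment_policy(), n_new = 0L) {
  stopifnot(n_new >= 0)
  if (length(pairs) == 0 && n_new > 0) {
    stop("cannot augment an empty source set")
  }
  if (n_new == 0) return(pairs)
  extra <- with_local_seed(policy$seed, {
    src <- sample.int(length(pairs), n_new, replace = TRUE)
    lapply(src, function(i) {
      a <- augment_pair(pairs[[i]]$image, pairs[[i]]$mask, policy)
      list(image = a$image, mask = a$mask)
    })
  })
  c(pairs, extra)
}
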