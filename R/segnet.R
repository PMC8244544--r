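#' Segmentation network configuration
#'
#' Configuration of the aperture-segmentation network: a UNet-style
#' encoder-decoder whose encoder is a stack of depthwise separable
#' convolutions (the MobileNet building block) and whose four skip features
#' f1-f4 each pass through a squeeze-and-excitation (SE) channel-attention
#' block before decoder concatenation.
#'
#' @param input_size `(H, W)` the network operates on; both divisible by 16
#'   (four 2x downsamplings). Crops are resized to this before inference;
#'   default 416 x 416.
#' @param n_classes number of classes (2: background, aperture).
#' @param width_multiplier fraction of the full channel widths
#'   (32/64/128/256); 0.25 keeps CPU training in minutes.
#' @param se_reduction SE bottleneck reduction ratio r.
#' @param in_channels input channels (1 for grayscale microscopy).
#' @param batch_size minibatch size (default 5).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs training epochs.
#' @param seed RNG seed for initialization and data order.
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(input_size = c(416L, 416L), n_classes = 2L,
                       width_multiplier = 1, se_reduction = 16L,
                       in_channels = 1L, batch_size = 5L,
                       learning_rate = 0.001, epochs = 100L, seed = 1L) {
  input_size <- as.integer(rep(input_size, length.out = 2))
  if (any(input_size %% 16L != 0L)) {
    stop("input_size must be divisible by 16")
  }
  stopifnot(n_classes >= 2, width_multiplier > 0, se_reduction >= 1,
            in_channels >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(input_size = input_size, n_classes = as.integer(n_classes),
                 width_multiplier = width_multiplier,
                 se_reduction = as.integer(se_reduction),
                 in_channels = as.integer(in_channels),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "seg_config")
}

seg_widths <- function(config) {
  pmax(4L, as.integer(round(c(32, 64, 128, 256) * config$width_multiplier)))
}

he_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

he_dw <- function(kh, kw, c) {
  array(rnorm(kh * kw * c, sd = sqrt(2 / (kh * kw))), dim = c(kh, kw, c))
}

he_dense <- function(nout, nin) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout)
}

se_hidden <- function(c, r) max(1L, as.integer(round(c / r)))

#' Create a randomly initialized segmentation model
#'
#' All layers use He initialization; biases start at zero.
#'
#' @param config a [seg_config()].
#' @return an object of class `seg_model` (parameters + config).
#' @export
seg_model_new <- function(config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  ch <- seg_widths(config)
  r <- config$se_reduction
  p <- list()
  with_local_seed(config$seed, {
    add_conv <- function(name, cin, cout, k = 3L) {
      p[[paste0(name, ".W")]] <<- he_conv(k, k, cin, cout)
      p[[paste0(name, ".b")]] <<- numeric(cout)
    }
    add_ds <- function(name, cin, cout) {
      p[[paste0(name, ".dw.W")]] <<- he_dw(3L, 3L, cin)
      p[[paste0(name, ".dw.b")]] <<- numeric(cin)
      p[[paste0(name, ".pw.W")]] <<- he_conv(1L, 1L, cin, cout)
      p[[paste0(name, ".pw.b")]] <<- numeric(cout)
    }
    add_se <- function(name, c) {
      hdim <- se_hidden(c, r)
      p[[paste0(name, ".W1")]] <<- he_dense(hdim, c)
      p[[paste0(name, ".b1")]] <<- numeric(hdim)
      p[[paste0(name, ".W2")]] <<- he_dense(c, hdim)
      p[[paste0(name, ".b2")]] <<- numeric(c)
    }
    add_conv("enc0", config$in_channels, ch[1])
    add_ds("enc1", ch[1], ch[1])
    add_ds("enc2a", ch[1], ch[2]); add_ds("enc2b", ch[2], ch[2])
    add_ds("enc3a", ch[2], ch[3]); add_ds("enc3b", ch[3], ch[3])
    add_ds("enc4a", ch[3], ch[4]); add_ds("enc4b", ch[4], ch[4])
    for (i in 1:4) add_se(paste0("se", i), ch[i])
    add_conv("dec3a", ch[4], ch[3]); add_conv("dec3b", 2L * ch[3], ch[3])
    add_conv("dec2a", ch[3], ch[2]); add_conv("dec2b", 2L * ch[2], ch[2])
    add_conv("dec1a", ch[2], ch[1]); add_conv("dec1b", 2L * ch[1], ch[1])
    add_conv("dec0", ch[1], ch[1])
    add_conv("head", ch[1], config$n_classes, k = 1L)
  })
  structure(list(params = p, config = config), class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<seg_model: %d parameters, widths %s, input %dx%d>\n",
              np, paste(seg_widths(x$config), collapse = "/"),
              x$config$input_size[1], x$config$input_size[2]))
  invisible(x)
}

# wires the encoder/decoder graph on a tape; returns the logits node id
seg_graph <- function(tp, gacc, x_id, params) {
  ds <- function(id, name, stride = 1L) {
    id <- l_dwconv(tp, gacc, id, params, paste0(name, ".dw"), stride, 1L)
    l_conv(tp, gacc, id, params, paste0(name, ".pw"), 1L, 0L)
  }
  a0 <- l_relu(tp, l_conv(tp, gacc, x_id, params, "enc0", 2L, 1L))
  f1 <- l_relu(tp, ds(a0, "enc1"))
  f2 <- l_relu(tp, ds(l_relu(tp, ds(f1, "enc2a", 2L)), "enc2b"))
  f3 <- l_relu(tp, ds(l_relu(tp, ds(f2, "enc3a", 2L)), "enc3b"))
  f4 <- l_relu(tp, ds(l_relu(tp, ds(f3, "enc4a", 2L)), "enc4b"))
  s1 <- l_se(tp, gacc, f1, params, "se1")
  s2 <- l_se(tp, gacc, f2, params, "se2")
  s3 <- l_se(tp, gacc, f3, params, "se3")
  s4 <- l_se(tp, gacc, f4, params, "se4")
  d3 <- l_relu(tp, l_conv(tp, gacc, l_up2(tp, s4), params, "dec3a", 1L, 1L))
  d3 <- l_relu(tp, l_conv(tp, gacc, l_concat(tp, d3, s3), params, "dec3b",
                          1L, 1L))
  d2 <- l_relu(tp, l_conv(tp, gacc, l_up2(tp, d3), params, "dec2a", 1L, 1L))
  d2 <- l_relu(tp, l_conv(tp, gacc, l_concat(tp, d2, s2), params, "dec2b",
                          1L, 1L))
  d1 <- l_relu(tp, l_conv(tp, gacc, l_up2(tp, d2), params, "dec1a", 1L, 1L))
  d1 <- l_relu(tp, l_conv(tp, gacc, l_concat(tp, d1, s1), params, "dec1b",
                          1L, 1L))
  d0 <- l_relu(tp, l_conv(tp, gacc, l_up2(tp, d1), params, "dec0", 1L, 1L))
  l_conv(tp, gacc, d0, params, "head", 1L, 0L)
}

check_input_shape <- function(x, config = NULL) {
  x <- as_c3(x)
  d <- dim(x)
  if (any(d[1:2] %% 16L != 0L)) {
    stop("input spatial size must be divisible by 16, got ",
         d[1], "x", d[2])
  }
  if (!is.null(config) && d[3] != config$in_channels) {
    if (config$in_channels == 1L) {
      x <- array(rowMeans(matrix(x, ncol = d[3])), dim = c(d[1:2], 1L))
    } else {
      stop("input has ", d[3], " channels, model expects ",
           config$in_channels)
    }
  }
  x
}

#' Forward pass: per-pixel class probabilities
#'
#' @param model a `seg_model`.
#' @param x input image: H x W matrix or H x W x C array, intensities in
#'   `[0, 1]`, H and W divisible by 16.
#' @return H x W x n_classes array of per-pixel class probabilities (each
#'   pixel sums to 1).
#' @export
seg_forward <- function(model, x) {
  x <- check_input_shape(x, model$config)
  tp <- tape_new()
  gacc <- new.env(parent = emptyenv())
  logits <- seg_graph(tp, gacc, tp_push(tp, x), model$params)
  softmax_channels(tp$vals[[logits]])
}

# loss and parameter gradients for one sample
seg_loss_grad <- function(model, x, labels) {
  x <- check_input_shape(x, model$config)
  tp <- tape_new()
  gacc <- new.env(parent = emptyenv())
  x_id <- tp_push(tp, x)
  logits_id <- seg_graph(tp, gacc, x_id, model$params)
  ce <- softmax_ce(tp$vals[[logits_id]], labels)
  tape_backward(tp, logits_id, ce$grad)
  list(loss = ce$loss, grads = as.list(gacc))
}

#' Parameter counts of separable vs standard convolution
#'
#' A k x k standard convolution from `c_in` to `c_out` channels costs
#' `k^2 c_in c_out` weights; the separable factorization costs
#' `k^2 c_in + c_in c_out`, a ratio of exactly `1/c_out + 1/k^2`.
#'
#' @param k spatial kernel size.
#' @param c_in,c_out channel counts.
#' @return list with `separable`, `standard`, `ratio`.
#' @export
separable_param_counts <- function(k, c_in, c_out) {
  sep <- k * k * c_in + c_in * c_out
  std <- k * k * c_in * c_out
  list(separable = sep, standard = std, ratio = sep / std)
}

#' Depthwise separable convolution (functional form)
#'
#' Per-channel spatial filtering (one k x k kernel per input channel)
#' followed by 1 x 1 pointwise mixing across channels. Exposed directly so
#' the factorization can be validated against brute-force convolution.
#'
#' @param x H x W x C input array.
#' @param depth_kernels k x k x C array, one kernel per input channel.
#' @param point_kernels 1 x 1 x C x C_out array (or C x C_out matrix) of
#'   pointwise weights.
#' @param stride,pad stride and zero padding of the depthwise stage.
#' @return H' x W' x C_out array.
#' @export
depthwise_separable_conv <- function(x, depth_kernels, point_kernels,
                                     stride = 1L, pad = 1L) {
  x <- as_c3(x)
  cin <- dim(x)[3]
  if (dim(depth_kernels)[3] != cin) {
    stop("need one depth kernel per input channel")
  }
  if (is.matrix(point_kernels)) {
    point_kernels <- array(point_kernels,
                           dim = c(1L, 1L, dim(point_kernels)))
  }
  if (dim(point_kernels)[1] != 1L || dim(point_kernels)[2] != 1L ||
      dim(point_kernels)[3] != cin) {
    stop("pointwise kernels must be 1x1 with one slice per input channel")
  }
  cout <- dim(point_kernels)[4]
  mid <- dwconv2d_fwd(x, depth_kernels, numeric(cin), stride, pad)
  conv2d_fwd(mid, array(point_kernels, dim = c(1L, 1L, cin * cout)),
             numeric(cout), cin, cout, 1L, 0L)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

validate_pair <- function(pair, config) {
  img <- check_input_shape(pair$image, config)
  m <- pair$mask
  if (!all(m %in% 0:(config$n_classes - 1L))) {
    stop("mask contains values outside the class index range")
  }
  if (!all(dim(m) == dim(img)[1:2])) stop("image/mask size mismatch")
  list(image = img, mask = m)
}

#' Train the segmentation network
#'
#' Adam optimization of per-pixel categorical cross-entropy, matching the
#' published training recipe (batch size 5, learning rate 0.001, He
#' initialization). With `val_frac > 0` a held-out split drives early
#' stopping: training stops after `patience` epochs without validation-loss
#' improvement and the best parameters are restored.
#'
#' @param model a `seg_model` from [seg_model_new()].
#' @param dataset list of `list(image =, mask =)` pairs; masks are integer
#'   class-index matrices.
#' @param epochs overrides `model$config$epochs` when given.
#' @param val_frac fraction of the dataset held out for early stopping.
#' @param patience early-stopping patience in epochs.
#' @param verbose print per-epoch losses.
#' @return the trained `seg_model`, with a `loss_log` data.frame attached
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_segnet <- function(model, dataset, epochs = NULL, val_frac = 0,
                         patience = 10L, verbose = FALSE) {
  stopifnot(inherits(model, "seg_model"))
  if (length(dataset) == 0) stop("empty training dataset")
  cfg <- model$config
  dataset <- lapply(dataset, validate_pair, config = cfg)
  if (is.null(epochs)) epochs <- cfg$epochs
  n_val <- floor(length(dataset) * val_frac)
  log_rows <- vector("list", epochs)
  with_local_seed(cfg$seed + 1L, {
    idx <- sample(length(dataset))
    val <- if (n_val > 0) dataset[idx[seq_len(n_val)]] else list()
    trn <- dataset[idx[(n_val + 1):length(idx)]]
    opt <- adam_new(model$params)
    best_val <- Inf
    best_params <- NULL
    stall <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(length(trn))
      ep_loss <- 0
      b <- 1L
      while (b <= length(ord)) {
        bidx <- ord[b:min(b + cfg$batch_size - 1L, length(ord))]
        gsum <- NULL
        for (i in bidx) {
          r <- seg_loss_grad(model, trn[[i]]$image, trn[[i]]$mask)
          ep_loss <- ep_loss + r$loss
          gsum <- if (is.null(gsum)) r$grads else {
            for (nm in names(r$grads)) {
              gsum[[nm]] <- gsum[[nm]] + r$grads[[nm]]
            }
            gsum
          }
        }
        gmean <- lapply(gsum, function(g) g / length(bidx))
        st <- adam_step(model$params, gmean, opt, cfg$learning_rate)
        model$params <- st$params
        opt <- st$state
        b <- b + cfg$batch_size
      }
      train_loss <- ep_loss / length(trn)
      val_loss <- NA_real_
      if (n_val > 0) {
        val_loss <- mean(vapply(val, function(p) {
          softmax_ce(seg_logits(model, p$image), p$mask)$loss
        }, numeric(1)))
        if (val_loss < best_val - 1e-6) {
          best_val <- val_loss
          best_params <- model$params
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      log_rows[[ep]] <- data.frame(epoch = ep, train_loss = train_loss,
                                   val_loss = val_loss)
      if (verbose) {
        cat(sprintf("epoch %3d  train %.4f  val %s\n", ep, train_loss,
                    ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
      }
      if (n_val > 0 && stall >= patience) break
    }
    if (!is.null(best_params)) model$params <- best_params
  })
  model$loss_log <- do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                    logical(1))])
  model
}

#' Train a reference model on generator crops
#'
#' Convenience recipe for a fully synthetic aperture segmenter: renders
#' `n_crops` ground-truthed single-stoma crops, lifts each pair to the
#' network's working resolution through the same resize path used at
#' inference (bilinear for images, nearest-neighbour for masks), and trains.
#' Supervising at the network resolution rather than the crop's native
#' resolution matters: the finest encoder features sit at half the input
#' resolution, so working at an upsampled input puts the decision grid at (or
#' below) native pixel pitch and sharpens aperture-boundary localization —
#' the accuracy that small, closing apertures need.
#'
#' @param n_crops number of training crops to render.
#' @param crop_size native crop side in px.
#' @param input_size network input size (both dims divisible by 16).
#' @param width_multiplier,epochs,seed passed to [seg_config()].
#' @return a trained `seg_model`.
#' @export
train_synthetic_segnet <- function(n_crops = 150, crop_size = 64,
                                   input_size = c(128, 128),
                                   width_multiplier = 0.25, epochs = 45,
                                   seed = 1L) {
  crops <- synth_crop_dataset(n_crops, size = crop_size, seed = seed)
  input_size <- as.integer(rep(input_size, length.out = 2))
  pairs <- lapply(crops, function(p) {
    if (all(dim(p$image) == input_size)) return(p)
    list(image = resize_bilinear(p$image, input_size[1], input_size[2]),
         mask = matrix(as.integer(resize_nearest(p$mask, input_size[1],
                                                 input_size[2])),
                       input_size[1]))
  })
  cfg <- seg_config(input_size = input_size,
                    width_multiplier = width_multiplier, epochs = epochs,
                    seed = seed)
  train_segnet(seg_model_new(cfg), pairs)
}

seg_logits <- function(model, x) {
  x <- check_input_shape(x, model$config)
  tp <- tape_new()
  gacc <- new.env(parent = emptyenv())
  id <- seg_graph(tp, gacc, tp_push(tp, x), model$params)
  tp$vals[[id]]
}

resize_bilinear <- function(m, h, w) {
  t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m)), w = w, h = h,
                                       filter = "bilinear")))
}

resize_nearest <- function(m, h, w) {
  t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m)), w = w, h = h,
                                       filter = "none")))
}

#' Predict an aperture mask for an arbitrary-size crop
#'
#' Preprocessing scales intensities to `[0, 1]` and bilinearly resizes the
#' crop to the configured network input size; the per-pixel argmax (ties
#' broken towards background) is then resized back to the crop's native size
#' with nearest-neighbour sampling so aperture areas are counted at native
#' resolution.
#'
#' @param model a trained `seg_model`.
#' @param image crop matrix (grayscale) or H x W x C array; any size.
#' @return integer mask matrix of the crop's native size, values `{0, 1}`.
#' @export
predict_mask <- function(model, image) {
  if (!is.matrix(image)) {
    image <- check_input_shape(image, model$config)[, , 1]
  }
  if (max(image) > 1) image <- image / 255
  native <- dim(image)
  sz <- model$config$input_size
  xin <- if (all(native == sz)) image else resize_bilinear(image, sz[1], sz[2])
  prob <- seg_forward(model, xin)
  mask <- matrix(0L, nrow = sz[1], ncol = sz[2])
  mask[prob[, , 2] > prob[, , 1]] <- 1L   # ties go to background
  if (!all(native == sz)) {
    mask <- matrix(as.integer(resize_nearest(mask, native[1], native[2])),
                   nrow = native[1])
  }
  mask
}

#' Save / load a segmentation model checkpoint
#'
#' The checkpoint is a single serialized weights file; a YAML sidecar
#' (`<path>.yaml`) records the architecture configuration for inspection.
#'
#' @param model a `seg_model`.
#' @param path checkpoint file path.
#' @export
save_segnet <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(list(params = model$params, config = unclass(model$config)), path)
  yaml::write_yaml(unclass(model$config), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  if (!file.exists(path)) stop("model checkpoint not found: ", path)
  obj <- readRDS(path)
  structure(list(params = obj$params,
                 config = structure(obj$config, class = "seg_config")),
            class = "seg_model")
}
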