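# Shared fixtures built in code. Expensive artifacts (trained models) are
# memoized per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small stationary two-stoma scene used by tracking tests
tracking_scene <- function(noise_sigma = 0.02, seed = 5L) {
  scene_spec(width = 160, height = 120, fps = 20, duration = 10,
             noise_sigma = noise_sigma, seed = seed,
             stomata = list(stoma_spec(center = c(60, 50)),
                            stoma_spec(center = c(110, 80))))
}

render_frames <- function(scene, n) {
  lapply((seq_len(n) - 1) / scene$fps, function(t) render_frame(scene, t)$image)
}

# shift frame content by integer (dx, dy), filling uncovered borders with 0.5
shift_frame <- function(f, dx, dy) {
  h <- nrow(f); w <- ncol(f)
  out <- matrix(0.5, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- f[src_r[ok_r], src_c[ok_c]]
  out
}

# quick low-quality model for pipeline bookkeeping tests (seconds to train)
quick_model <- function() {
  memo("quick_model", {
    pairs <- synth_crop_dataset(3, size = 64, seed = 42)
    cfg <- seg_config(input_size = c(64, 64), width_multiplier = 0.25,
                      epochs = 6, seed = 1)
    train_segnet(seg_model_new(cfg), pairs)
  })
}

# the 50-crop benchmark model: width 0.25, native 64-px input
benchmark_model <- function() {
  memo("benchmark_model", {
    pairs <- synth_crop_dataset(50, size = 64, seed = 101)
    cfg <- seg_config(input_size = c(64, 64), width_multiplier = 0.25,
                      epochs = 25, seed = 1)
    train_segnet(seg_model_new(cfg), pairs)
  })
}

# the reference pipeline model: supervised at 128 input for sub-native-pixel
# aperture boundaries (see ?train_synthetic_segnet)
reference_model <- function() {
  memo("reference_model", {
    train_synthetic_segnet(n_crops = 150, crop_size = 64,
                           input_size = c(128, 128), epochs = 45, seed = 1)
  })
}

heldout_crops <- function() synth_crop_dataset(20, size = 64, seed = 202)

# brute-force spatial convolution oracle (triple nested loops, zero padding)
conv_oracle <- function(x, w4, b, stride = 1L, pad = 1L) {
  kh <- dim(w4)[1]; kw <- dim(w4)[2]; cin <- dim(w4)[3]; cout <- dim(w4)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (W + 2 * pad - kw) %/% stride + 1L
  out <- array(0, dim = c(Ho, Wo, cout))
  for (co in seq_len(cout)) {
    for (io in seq_len(Ho)) {
      for (jo in seq_len(Wo)) {
        acc <- b[co]
        for (ci in seq_len(cin)) {
          for (ki in seq_len(kh)) {
            for (kj in seq_len(kw)) {
              ii <- (io - 1L) * stride - pad + ki
              jj <- (jo - 1L) * stride - pad + kj
              if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
                acc <- acc + x[ii, jj, ci] * w4[ki, kj, ci, co]
              }
            }
          }
        }
        out[io, jo, co] <- acc
      }
    }
  }
  out
}

# per-pixel ellipse-inclusion oracle (independent double loop)
ellipse_oracle_count <- function(width, height, center, axes, theta_deg) {
  th <- theta_deg * pi / 180
  count <- 0L
  for (yy in 0:(height - 1)) {
    for (xx in 0:(width - 1)) {
      dx <- xx - center[1]; dy <- yy - center[2]
      u <- (dx * cos(th) + dy * sin(th)) / axes[1]
      v <- (-dx * sin(th) + dy * cos(th)) / axes[2]
      if (u * u + v * v <= 1) count <- count + 1L
    }
  }
  count
}

# per-pixel confusion/metrics oracle (explicit enumeration)
metrics_oracle <- function(truth, pred) {
  n <- matrix(0L, 2, 2)
  for (i in seq_along(truth)) {
    n[truth[i] + 1L, pred[i] + 1L] <- n[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  pa <- (n[1, 1] + n[2, 2]) / sum(n)
  cpa <- c(n[1, 1] / sum(n[1, ]), n[2, 2] / sum(n[2, ]))
  iou <- c(n[1, 1] / (sum(n[1, ]) + sum(n[, 1]) - n[1, 1]),
           n[2, 2] / (sum(n[2, ]) + sum(n[, 2]) - n[2, 2]))
  list(n = n, pa = pa, cpa = cpa, mpa = mean(cpa, na.rm = TRUE),
       iou = iou, miou = mean(iou, na.rm = TRUE))
}

aperture_iou <- function(truth, pred) {
  compute_metrics(confusion(truth, pred))$iou[2]
}
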