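test_that("tracker initialization validates its inputs", {
  f <- matrix(runif(100 * 120), 100, 120)
  expect_error(init_tracker(f, bounding_box(110, 10, 20, 20)),
               "outside frame")
  expect_error(bounding_box(10, 10, 0, 5))
  st <- init_tracker(f, bounding_box(40, 30, 30, 24))
  expect_true(all(is.finite(Mod(st$model_alphaf))))
  expect_error(update_tracker(list(), f), "not initialized")
  expect_error(update_tracker(st, matrix(0, 10, 10)), "dimensions")
})

test_that("identical init calls give identical states; self-response peaks at zero shift", {
  sc <- tracking_scene()
  f0 <- render_frame(sc, 0)$image
  box <- bounding_box(30, 30, 60, 40)
  s1 <- init_tracker(f0, box)
  s2 <- init_tracker(f0, box)
  expect_identical(s1, s2)
  up <- update_tracker(s1, f0)
  expect_equal(up$box$x, box$x)
  expect_equal(up$box$y, box$y)
})

test_that("flat-patch dual coefficients are finite and match the explicit ridge oracle", {
  ns <- asNamespace("stomatrack")
  p <- kcf_params()
  # 4x4 patch: build the ridge solution by explicit cyclic-shift enumeration
  check_against_oracle <- function(patch) {
    win <- ns$hann2(4, 4)
    x <- ns$preprocess_patch(patch, win)
    y <- ns$gaussian_labels(4, 4, 0.5)
    # kernel matrix over all 16 cyclic shifts (row-major shift enumeration)
    shifts <- expand.grid(di = 0:3, dj = 0:3)
    shifted <- lapply(seq_len(16), function(i) {
      di <- shifts$di[i]; dj <- shifts$dj[i]
      x[(c(0:3 - di) %% 4) + 1, (c(0:3 - dj) %% 4) + 1]
    })
    K <- matrix(0, 16, 16)
    for (i in 1:16) for (j in 1:16) {
      d <- sum((shifted[[i]] - shifted[[j]])^2) / 16
      K[i, j] <- exp(-d / p$sigma^2)
    }
    yv <- vapply(seq_len(16),
                 function(i) y[shifts$di[i] + 1, shifts$dj[i] + 1],
                 numeric(1))
    alpha_oracle <- solve(K + p$lambda * diag(16), yv)
    # frequency-domain solution mapped back to the spatial domain
    kxx <- ns$gaussian_correlation(x, x, p$sigma)
    alphaf <- ns$fft2(y) / (ns$fft2(kxx) + p$lambda)
    alpha_fd <- Re(ns$ifft2(alphaf))
    alpha_fd_vec <- vapply(seq_len(16),
                           function(i) alpha_fd[shifts$di[i] + 1,
                                                shifts$dj[i] + 1],
                           numeric(1))
    expect_true(all(is.finite(alpha_oracle)))
    expect_true(all(is.finite(alpha_fd_vec)))
    expect_equal(alpha_fd_vec, alpha_oracle, tolerance = 1e-8)
  }
  check_against_oracle(matrix(0.5, 4, 4))              # flat patch
  set.seed(3)
  check_against_oracle(matrix(runif(16), 4, 4))        # generic patch
})

test_that("integer translations are recovered exactly within the padding margin", {
  sc <- scene_spec(width = 160, height = 120, fps = 20, duration = 10,
                   noise_sigma = 0.02,
                   stomata = list(stoma_spec(center = c(80, 60))))
  f0 <- render_frame(sc, 0)$image
  box <- bounding_box(60, 45, 40, 30)
  for (sh in list(c(3, 2), c(-4, 5), c(7, -6), c(12, 9), c(0, 0))) {
    up <- update_tracker(init_tracker(f0, box),
                         shift_frame(f0, sh[1], sh[2]))
    expect_equal(c(up$box$x - box$x, up$box$y - box$y), sh)
    # dense cross-correlation oracle over all integer shifts of the raw patch
    ns <- asNamespace("stomatrack")
    patch0 <- ns$extract_patch(f0, 80, 60, 100, 75)
    patch1 <- ns$extract_patch(shift_frame(f0, sh[1], sh[2]), 80, 60, 100, 75)
    a <- patch0 - mean(patch0)
    b <- patch1 - mean(patch1)
    cc <- Re(ns$ifft2(ns$fft2(b) * Conj(ns$fft2(a))))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    dy <- pk[1] - 1; dx <- pk[2] - 1
    if (dy > 75 / 2) dy <- dy - 75
    if (dx > 100 / 2) dx <- dx - 100
    expect_equal(unname(c(dx, dy)), sh)
  }
})

test_that("stationary stomata are tracked with <= 1 px drift across noise levels", {
  for (noise in c(0, 0.02, 0.05)) {
    sc <- tracking_scene(noise_sigma = noise)
    fs <- frame_sequence(render_frames(sc, 60), fps = 20)
    tr <- track_and_crop(fs, list(bounding_box(30, 30, 60, 40),
                                  bounding_box(85, 60, 50, 40)))
    for (s in 1:2) {
      xs <- vapply(tr$boxes[[s]], function(b) b$x, integer(1))
      ys <- vapply(tr$boxes[[s]], function(b) b$y, integer(1))
      expect_lte(max(abs(xs - xs[1])), 1)
      expect_lte(max(abs(ys - ys[1])), 1)
    }
  }
})

test_that("a pure-noise frame scores far below the self-match response", {
  sc <- tracking_scene()
  f0 <- render_frame(sc, 0)$image
  box <- bounding_box(30, 30, 60, 40)
  self <- update_tracker(init_tracker(f0, box), f0)$response
  set.seed(8)
  noise <- update_tracker(init_tracker(f0, box),
                          matrix(runif(120 * 160), 120, 160))$response
  expect_lt(noise, 0.5 * self)
})

test_that("track_and_crop bookkeeping, identity crop and fixed-box oracle", {
  sc <- tracking_scene()
  fs <- frame_sequence(render_frames(sc, 10), fps = 20)
  boxes <- list(bounding_box(30, 30, 50, 36), bounding_box(85, 60, 40, 30),
                bounding_box(10, 10, 30, 30))
  tr <- track_and_crop(fs, boxes)
  expect_length(tr$crops, 3)
  for (s in 1:3) {
    expect_length(tr$crops[[s]], 10)
    expect_true(all(vapply(tr$crops[[s]], function(cr) {
      all(dim(cr) == c(boxes[[s]]$h, boxes[[s]]$w))
    }, logical(1))))
    # stationary scene: tracked crop equals the fixed-box crop (<= 1 px shift)
    for (k in c(5, 10)) {
      b <- tr$boxes[[s]][[k]]
      expect_lte(abs(b$x - boxes[[s]]$x), 1)
      expect_lte(abs(b$y - boxes[[s]]$y), 1)
    }
  }
  # one box covering the whole frame: crops are the frames themselves
  whole <- track_and_crop(fs, list(bounding_box(0, 0, 160, 120)))
  expect_identical(whole$crops[[1]][[7]], fs$frames[[7]])
  expect_error(track_and_crop(fs, list()), "at least one box")
  # determinism
  tr2 <- track_and_crop(fs, boxes)
  expect_identical(tr$boxes, tr2$boxes)
})
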