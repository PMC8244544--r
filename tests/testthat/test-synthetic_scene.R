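test_that("kinetics models obey their contracts", {
  kin_c <- kinetics_spec("constant")
  expect_equal(aperture_area(kin_c, 500, c(0, 10, 100)), rep(500, 3))

  kin_l <- kinetics_spec("linear", slope = -5)
  expect_equal(aperture_area(kin_l, 100, c(0, 10)), c(100, 50))
  expect_equal(aperture_area(kin_l, 100, 1000), 0)  # clamped at zero

  kin_g <- kinetics_spec("logistic_closure", A_end = 0, k = 0.05, t0 = 120)
  a <- aperture_area(kin_g, 600, seq(0, 600, by = 10))
  expect_true(all(diff(a) < 0))                      # monotone closure
  expect_lt(aperture_area(kin_g, 600, 600), 0.01 * 600)
  expect_true(all(a >= 0))
})

test_that("empty scene renders an all-zero mask", {
  sc <- scene_spec(width = 40, height = 30, duration = 1, fps = 5)
  fr <- render_frame(sc, 0)
  expect_equal(sum(fr$mask), 0)
  expect_equal(dim(fr$image), c(30, 40))
})

test_that("rasterized aperture matches the per-pixel ellipse oracle", {
  cases <- list(list(axes = c(20, 10), th = 0),
                list(axes = c(12, 6), th = 35),
                list(axes = c(8, 4), th = 110))
  for (cs in cases) {
    sc <- scene_spec(width = 96, height = 72, duration = 1, fps = 5,
                     stomata = list(stoma_spec(center = c(48, 36),
                                               orientation = cs$th,
                                               guard_axes = cs$axes * 1.3,
                                               aperture_axes = cs$axes)))
    got <- sum(render_frame(sc, 0)$mask)
    oracle <- ellipse_oracle_count(96, 72, c(48, 36), cs$axes, cs$th)
    expect_identical(got, oracle)
    analytic <- pi * cs$axes[1] * cs$axes[2]
    expect_lt(abs(got - analytic) / analytic, 0.02)  # 2% for axes >= 4 px
  }
})

test_that("rendering is deterministic and masks are 2-valued", {
  sc <- scene_spec(width = 64, height = 48, duration = 2, fps = 5,
                   stomata = list(stoma_spec(center = c(32, 24))), seed = 11)
  a <- render_frame(sc, 0.4)
  b <- render_frame(sc, 0.4)
  expect_identical(a, b)
  expect_true(all(a$mask %in% c(0L, 1L)))
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("stoma centres are stationary while the aperture shrinks", {
  st <- stoma_spec(center = c(40, 30), aperture_axes = c(12, 6),
                   guard_axes = c(20, 12),
                   kinetics = kinetics_spec("logistic_closure", A_end = 0,
                                            k = 0.05, t0 = 30))
  sc <- scene_spec(width = 80, height = 60, duration = 60, fps = 1,
                   stomata = list(st), noise_sigma = 0)
  centroid <- function(mask) {
    idx <- which(mask == 1L, arr.ind = TRUE)
    c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)   # (x, y), 0-based
  }
  m0 <- render_frame(sc, 0)$mask
  m1 <- render_frame(sc, 25)$mask
  expect_gt(sum(m0), sum(m1))                        # closing
  expect_lt(max(abs(centroid(m0) - c(40, 30))), 1)
  expect_lt(max(abs(centroid(m1) - c(40, 30))), 1)
  # aperture always strictly inside the guard outline
  ax25 <- aperture_axes_at(st, 25)
  expect_true(all(ax25 < st$guard_axes))
})

test_that("generate_video writes frames, masks and a consistent SOA table", {
  sc <- scene_spec(width = 48, height = 36, duration = 2, fps = 5,
                   stomata = list(stoma_spec(center = c(24, 18),
                                             guard_axes = c(13, 8),
                                             aperture_axes = c(8, 4))),
                   seed = 3)
  out <- withr::local_tempdir()
  res <- generate_video(sc, out)
  expect_equal(res$n_frames, 10L)                   # round(fps * duration)
  gt <- read.csv(res$ground_truth)
  expect_equal(nrow(gt), 10L * 1L)                  # frames x stomata
  expect_named(gt, c("frame_index", "time_s", "stoma_id",
                     "soa_analytic_px2", "soa_raster_px"))
  # raster ground truth equals what the frames actually contain
  m0 <- read_mask(file.path(out, "masks", "mask_00000.png"))
  expect_identical(sum(m0), as.integer(gt$soa_raster_px[1]))
  # visual masks are the x255 variant of the raw ones
  vis <- png::readPNG(file.path(out, "masks_visual", "mask_00000.png"))
  expect_setequal(unique(as.integer(round(vis * 255))), c(0L, 255L))
  # logistic closure demo: rasterized SOA at the end <= 1% of start
  gt2 <- scene_ground_truth(scene_chilling_demo(fps = 1 / 60))
  last <- gt2[gt2$time_s == max(gt2$time_s), ]
  first <- gt2[gt2$time_s == 0, ]
  expect_true(all(last$soa_raster_px <= 0.01 * first$soa_raster_px + 1))
})

test_that("crop dataset is reproducible and includes closed stomata", {
  a <- synth_crop_dataset(12, size = 32, seed = 9)
  b <- synth_crop_dataset(12, size = 32, seed = 9)
  expect_identical(a, b)
  fg <- vapply(a, function(p) sum(p$mask), numeric(1))
  expect_true(any(fg == 0))     # closed examples present
  expect_true(any(fg > 20))     # open examples present
})
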