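test_that("compute_soa counts aperture pixels at native resolution", {
  zeros <- rep(list(matrix(0L, 10, 10)), 4)
  s <- compute_soa(zeros, times = 0:3)
  expect_equal(s$soa, rep(0, 4))
  full <- list(matrix(1L, 416, 416))
  expect_equal(compute_soa(full, 0)$soa, 173056)
  expect_error(compute_soa(zeros, times = 0:4), "one mask per time")
  expect_error(compute_soa(list(matrix(3L, 2, 2)), 0), "outside")
})

test_that("SOA on generator masks equals the raster ground truth integer-exactly", {
  sc <- scene_spec(width = 64, height = 48, fps = 1, duration = 6,
                   stomata = list(stoma_spec(center = c(32, 24),
                                             guard_axes = c(18, 11),
                                             aperture_axes = c(12, 6),
                                             kinetics = kinetics_spec(
                                               "linear", slope = -40))),
                   seed = 2)
  gt <- scene_ground_truth(sc)
  masks <- lapply(0:5, function(t) render_frame(sc, t)$mask)
  s <- compute_soa(masks, 0:5)
  expect_identical(as.integer(s$soa), as.integer(gt$soa_raster_px))
})

test_that("rate curves recover constant, linear and logistic behaviour", {
  const <- soa_series(1, 0:9, rep(500, 10))
  expect_equal(rate_curve(const, smooth_window = 1)$rate, rep(0, 10))
  lin <- soa_series(1, 0:20, 1000 - 5 * (0:20))
  r <- rate_curve(lin, smooth_window = 1)
  expect_equal(r$rate[2:20], rep(-5, 19))
  r5 <- rate_curve(lin, smooth_window = 5)   # smoothing keeps a linear trend
  expect_equal(r5$rate[4:18], rep(-5, 15))
  expect_error(rate_curve(soa_series(1, 0, 5)), "at least 2")
  # logistic closure: fastest-closing time within one sample of t0
  kin <- kinetics_spec("logistic_closure", A_end = 0, k = 0.05, t0 = 120)
  t <- seq(0, 300, by = 10)
  s <- soa_series(1, t, aperture_area(kin, 600, t))
  expect_lte(abs(min_rate_time(rate_curve(s, smooth_window = 1)) - 120), 10)
})

test_that("summaries across stomata match a direct averaging oracle", {
  one <- soa_series(1, 0:5, c(5, 4, 3, 2, 1, 0))
  sm1 <- summarize_series(list(one))
  expect_equal(sm1$mean, one$soa)
  two <- summarize_series(list(soa_series(1, 0:3, rep(0, 4)),
                               soa_series(2, 0:3, rep(2, 4))))
  expect_equal(two$mean, rep(1, 4))
  set.seed(21)
  many <- lapply(1:15, function(i) soa_series(i, 0:9, runif(10, 0, 600)))
  sm <- summarize_series(many)
  for (k in 1:10) {
    vals <- vapply(many, function(s) s$soa[k], numeric(1))
    expect_equal(sm$mean[k], mean(vals))
    expect_equal(sm$median[k], median(vals))
    expect_equal(sm$q25[k], quantile(vals, 0.25, names = FALSE))
  }
  expect_error(summarize_series(list()), "empty")
})

test_that("correlations: affine invariance, closed form, and the independence null", {
  t <- seq(0, 1170, by = 30)
  set.seed(33)
  soa <- soa_series("mean", t, 600 * exp(-t / 400) + rnorm(length(t), 0, 5))
  gas <- data.frame(time_s = t,
                    Pn = 2 + 0.01 * soa$soa,       # positive affine -> r = 1
                    Ci = 5 - 0.02 * soa$soa,       # negative affine -> r = -1
                    Gs = 0.3 + 0.001 * soa$soa,
                    Tr = 1 + 0.004 * soa$soa)
  res <- correlate_soa_gas(soa, gas)
  expect_equal(res$r[res$parameter == "Pn"], 1, tolerance = 1e-10)
  expect_equal(res$r[res$parameter == "Ci"], -1, tolerance = 1e-10)
  expect_equal(res$n, rep(length(t), 4))
  # textbook 5-point check against the explicit Pearson formula
  x <- c(1, 2, 4, 5, 8); y <- c(2, 3, 5, 4, 9)
  r_formula <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  s5 <- soa_series(1, x, y)
  g5 <- data.frame(time_s = x, Pn = x, Ci = x, Gs = x, Tr = x)
  expect_equal(correlate_soa_gas(s5, g5)$r[1],
               sum((y - mean(y)) * (x - mean(x))) /
                 sqrt(sum((y - mean(y))^2) * sum((x - mean(x))^2)),
               tolerance = 1e-12)
  expect_equal(r_formula, cor(x, y), tolerance = 1e-12)
  # independent noise, n = 80: |r| below the 99% null bound
  set.seed(55)
  tt <- seq(0, 79 * 30, by = 30)
  noise_soa <- soa_series("mean", tt, abs(rnorm(80, 300, 50)))
  noise_gas <- data.frame(time_s = tt, Pn = rnorm(80), Ci = rnorm(80),
                          Gs = rnorm(80), Tr = rnorm(80))
  rn <- correlate_soa_gas(noise_soa, noise_gas)
  expect_true(all(abs(rn$r) < 0.3))
  # degenerate inputs
  expect_error(correlate_soa_gas(soa_series(1, c(0, 30), c(1, 2)),
                                 gas), "fewer than 3")
  flat_gas <- data.frame(time_s = t, Pn = 1, Ci = 1, Gs = 1, Tr = 1)
  ws <- capture_warnings(rz <- correlate_soa_gas(soa, flat_gas))
  expect_true(all(grepl("zero-variance", ws)))
  expect_true(all(is.na(rz$r)))
})
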