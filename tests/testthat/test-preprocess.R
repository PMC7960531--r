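test_that("cropping keeps exactly the fingerprint window", {
  s <- raman_spectrum(seq(400, 2000, by = 2), rnorm(801))
  cr <- crop_spectrum(s, 600, 1800)
  expect_gte(min(cr$wavenumbers), 600)
  expect_lte(max(cr$wavenumbers), 1800)
  expect_equal(length(cr$wavenumbers), sum(s$wavenumbers >= 600 & s$wavenumbers <= 1800))

  identity <- crop_spectrum(s, min(s$wavenumbers), max(s$wavenumbers))
  expect_identical(identity$intensities, s$intensities)

  high <- raman_spectrum(seq(2000, 3000, by = 5), rnorm(201))
  expect_error(crop_spectrum(high, 600, 1800), "does not overlap")
})

test_that("whittaker baseline reproduces flat and polynomial null spaces", {
  y <- rep(3.7, 60)
  expect_lt(max(abs(whittaker_background(y) - 3.7)), 1e-8)

  ramp <- seq(0, 5, length.out = 80)
  z <- whittaker_background(ramp, lambda = 1e5, diff_order = 2)
  expect_lt(max(abs(z - ramp)), 1e-6)

  expect_error(whittaker_background(rnorm(50), lambda = 0), "positive")
})

test_that("banded whittaker solve matches a dense reference solve", {
  w <- seq_len(50)
  y <- 0.01 * w^2 + 5 * exp(-0.5 * ((w - 25) / 3)^2)
  lambda <- 1e5
  z <- whittaker_background(y, lambda = lambda, p = 0.01, iters = 10,
                            diff_order = 2)
  z_ref <- dense_whittaker_oracle(y, lambda, 0.01, 10, 2)
  expect_lt(max(abs(z - z_ref)), 1e-6)
})

test_that("whittaker baseline is shift-equivariant", {
  set.seed(11)
  y <- cumsum(rnorm(100)) + 10
  z1 <- whittaker_background(y)
  z2 <- whittaker_background(y + 42)
  expect_lt(max(abs((z2 - 42) - z1)), 1e-6)
})

test_that("background subtraction flattens peak-free regions", {
  w <- seq(400, 2000, by = 2)
  baseline <- 5 + 3 * (w / 1000) + 2 * (w / 1000)^2
  peak <- 10 * exp(-0.5 * ((w - 1200) / 10)^2)
  s <- raman_spectrum(w, baseline + peak)
  out <- subtract_background(s)
  expect_length(out$intensities, length(w))
  peak_free <- abs(w - 1200) > 100
  expect_lt(mean(abs(out$intensities[peak_free])), 0.05 * 10)
  # peak magnitude survives subtraction
  expect_gt(max(out$intensities), 8)

  flat <- raman_spectrum(w, rep(2, length(w)))
  expect_lt(max(abs(subtract_background(flat)$intensities)), 1e-6)
})

test_that("normalization modes satisfy their definitions and scale invariance", {
  w <- seq(600, 1800, by = 2)
  set.seed(4)
  y <- abs(rnorm(length(w))) + 1
  s <- raman_spectrum(w, y)
  a <- normalize_spectrum(s, "area")
  integral <- sum(diff(w) * (head(a$intensities, -1) + tail(a$intensities, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-9)

  s3 <- raman_spectrum(w, 3 * y)
  expect_equal(normalize_spectrum(s3, "area")$intensities, a$intensities,
               tolerance = 1e-12)
  expect_equal(max(normalize_spectrum(s, "max")$intensities), 1)
  expect_equal(sqrt(sum(normalize_spectrum(s, "vector")$intensities^2)), 1,
               tolerance = 1e-12)

  # hand-computed trapezoid on a 5-point spectrum: axis 0,1,2,3,4 and
  # y = 1,2,3,2,1 -> area = 1.5 + 2.5 + 2.5 + 1.5 = 8
  hand <- raman_spectrum(0:4, c(1, 2, 3, 2, 1))
  expect_equal(normalize_spectrum(hand, "area")$intensities,
               c(1, 2, 3, 2, 1) / 8)

  zero <- raman_spectrum(0:4, rep(0, 5))
  expect_error(normalize_spectrum(zero, "area"), "cannot normalize")
})

test_that("savitzky-golay reproduces polynomials and the moving-average identity", {
  expect_equal(savitzky_golay(rep(2, 20)), rep(2, 20))
  ramp <- seq(1, 10, length.out = 25)
  sg <- savitzky_golay(ramp, order = 1, frame = 7)
  expect_equal(sg[4:22], ramp[4:22], tolerance = 1e-10)

  set.seed(9)
  y <- rnorm(31)
  sg <- savitzky_golay(y, order = 1, frame = 7)
  moving_avg <- as.numeric(stats::filter(y, rep(1 / 7, 7), sides = 2))
  expect_equal(sg[4:28], moving_avg[4:28], tolerance = 1e-10)

  # an interpolating window reproduces any input exactly
  expect_equal(savitzky_golay(y, order = 6, frame = 7), y, tolerance = 1e-6)

  expect_error(savitzky_golay(y, frame = 6), "odd")
  expect_error(savitzky_golay(y, order = 7, frame = 7), "exceed")
})

test_that("the full chain crops, normalizes and is scale-invariant", {
  spec <- default_class_specs(noise_sd = 0.2)$muscle
  s <- generate_spectrum(spec, seed = 5)
  cfg <- preprocess_config()
  out <- preprocess(s, cfg)
  expect_gte(min(out$wavenumbers), 600)
  expect_lte(max(out$wavenumbers), 1800)
  expect_identical(preprocess(out, cfg)$wavenumbers, out$wavenumbers)

  # area is exactly 1 after the normalization step (before SG smoothing)
  pre_sg <- normalize_spectrum(subtract_background(crop_spectrum(s), cfg), "area")
  integral <- sum(diff(pre_sg$wavenumbers) *
                  (head(pre_sg$intensities, -1) + tail(pre_sg$intensities, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-9)

  scaled <- raman_spectrum(s$wavenumbers, 3 * s$intensities)
  expect_equal(preprocess(scaled, cfg)$intensities, out$intensities,
               tolerance = 1e-9)
})
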