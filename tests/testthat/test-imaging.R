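test_that("rendered band height matches the commanded diameter exactly", {
  # 4 mm at 0.01 mm/px = 400 px, no taper, no noise: every station counts 400
  stk <- render_frames(rep(4.0, 3), mm_per_pixel = 0.01, frame_rate = 30,
                       image_height_px = 420, image_width_px = 20,
                       taper_px = 0, seed = 1)
  m <- binarize(stk$frames[[1]])
  meas <- measure_outer_diameter(m, 0.01)
  expect_equal(meas$station_mm, rep(4.00, 10))
  expect_equal(meas$diameter_mm, 4.00)
})

test_that("rendering is seed-deterministic and records jitter ground truth", {
  a <- render_frames(rep(3.9, 6), mm_per_pixel = 0.01, frame_rate = 30,
                     noise_sd = 0.05, jitter_px = 3, seed = 11)
  b <- render_frames(rep(3.9, 6), mm_per_pixel = 0.01, frame_rate = 30,
                     noise_sd = 0.05, jitter_px = 3, seed = 11)
  expect_identical(a$frames, b$frames)
  expect_equal(dim(a$meta$shifts), c(6, 2))
  expect_true(all(abs(a$meta$shifts) <= 3))
  expect_error(render_frames(10, mm_per_pixel = 0.01, frame_rate = 30,
                             image_height_px = 100), "exceeds")
})

test_that("registration recovers known integer shifts and is idempotent", {
  stk <- render_frames(rep(3.9, 8), mm_per_pixel = 0.01, frame_rate = 30,
                       jitter_px = 4, fiducial = TRUE, seed = 21)
  reg <- register_frames(stk)
  expect_equal(unname(reg$meta$estimated_shifts),
               unname(stk$meta$shifts))
  # idempotence: a second pass finds (almost) nothing to correct
  reg2 <- register_frames(reg)
  expect_true(all(abs(reg2$meta$estimated_shifts) <= 1))
  # zero jitter -> identity shifts
  clean <- register_frames(render_frames(rep(3.9, 4), mm_per_pixel = 0.01,
                                         frame_rate = 30, seed = 2))
  expect_true(all(clean$meta$estimated_shifts == 0))
  one <- register_frames(frame_stack(stk$frames[1], 30, 0.01))
  expect_equal(length(one$frames), 1)
  expect_warning(register_frames(frame_stack(list(matrix(0.5, 10, 10),
                                                  matrix(0.5, 10, 10)),
                                             30, 0.01)),
                 "featureless")
})

test_that("binarization recovers the band under noise and inverted polarity", {
  stk <- render_frames(3.9, mm_per_pixel = 0.01, frame_rate = 30,
                       taper_px = 0, seed = 1)
  truth <- binarize(stk$frames[[1]])
  # noise at 5% of contrast: >= 99% pixel agreement
  noisy <- render_frames(3.9, mm_per_pixel = 0.01, frame_rate = 30,
                         taper_px = 0, noise_sd = 0.05, seed = 8)
  m <- binarize(noisy$frames[[1]])
  expect_gte(mean(m == truth), 0.99)
  inv <- binarize(1 - stk$frames[[1]], invert = TRUE)
  expect_identical(inv, truth)
  expect_error(binarize(matrix(0.5, 5, 5)), "degenerate")
})

test_that("station placement avoids borders; tapered band averages its stations", {
  cols <- station_columns(240, 10)
  expect_equal(length(cols), 10)
  expect_true(all(cols > 1 & cols < 240))
  expect_equal(cols, seq(12, 228, by = 24))
  # strong taper: frame value equals the mean of the 10 station values
  stk <- render_frames(3.5, mm_per_pixel = 0.01, frame_rate = 30,
                       image_height_px = 420, image_width_px = 100,
                       taper_px = 30, seed = 1)
  m <- binarize(stk$frames[[1]])
  meas <- measure_outer_diameter(m, 0.01)
  expect_equal(meas$diameter_mm, mean(meas$station_mm))
  expect_gt(stats::sd(meas$station_mm), 0)   # taper visible across stations
  # empty station column -> measurement error
  empty <- matrix(0L, 50, 40); empty[20:25, 1:10] <- 1L
  expect_error(measure_outer_diameter(empty, 0.01), "empty station")
})

test_that("binarization agrees with an independent Otsu implementation", {
  stk <- render_frames(3.9, mm_per_pixel = 0.01, frame_rate = 30,
                       noise_sd = 0.08, seed = 4)
  f <- stk$frames[[1]]
  f[f < 0] <- 0; f[f > 1] <- 1
  thr_ref <- EBImage::otsu(f, range = c(0, 1), levels = 256)
  ours <- binarize(f)
  ref <- matrix(0L, nrow(f), ncol(f)); ref[f > thr_ref] <- 1L
  # bin-edge conventions differ slightly; the masks must coincide
  expect_gte(mean(ours == ref), 0.995)
})

test_that("the compliance equation matches direct evaluation of the reported regimes", {
  expect_equal(compliance_eq1(3.2, 3.2, 80, 120), 0)
  # worked values from the three regime means
  expect_equal(compliance_eq1(3.215, 3.224, 52.37, 92.01), 0.706,
               tolerance = 1e-3)
  expect_equal(compliance_eq1(3.227, 3.237, 79.67, 120.72), 0.755,
               tolerance = 1e-3)
  expect_equal(compliance_eq1(3.242, 3.253, 110.13, 152.67), 0.798,
               tolerance = 1e-3)
  # scale invariance in the diameters
  expect_equal(compliance_eq1(3.227 * 2, 3.237 * 2, 79.67, 120.72),
               compliance_eq1(3.227, 3.237, 79.67, 120.72))
  expect_error(compliance_eq1(3.2, 3.3, 120, 80), "Pmax")
  expect_error(compliance_eq1(-1, 3.3, 80, 120), "DPmin")
})

test_that("pipeline recovers ground-truth compliance on a noiseless fixture", {
  fx <- compliance_fixture(c_star = 0.755, seed = 5)
  res <- compliance_pipeline(fx$stack, fx$pressure, fx$phantom, fx$regime)
  expect_equal(res$C_mean, 0.755, tolerance = 0.02)
  expect_gte(res$n_cycles, 5)
})

test_that("a rigid phantom measures compliance at the quantization floor", {
  fx <- compliance_fixture(c_star = 0, seed = 6)
  res <- compliance_pipeline(fx$stack, fx$pressure, fx$phantom, fx$regime)
  expect_lt(abs(res$C_mean), 0.02)
})

test_that("a fixture calibrated to the normotensive anchors reproduces them", {
  ph <- phantom_from_anchors(79.67, 3.227, 120.72, 3.237)
  fps <- 30; dur <- 8
  t <- seq(0, dur - 1 / fps, by = 1 / fps)
  p <- (79.67 + 120.72) / 2 - (120.72 - 79.67) / 2 * cos(2 * pi * t)
  d <- diameter_at_pressure(ph, p)
  stk <- render_frames(d$outer, mm_per_pixel = 0.001, frame_rate = fps,
                       seed = 7)
  rate <- 40
  tp <- seq(0, dur - 1 / rate, by = 1 / rate)
  ptrace <- signal_trace((79.67 + 120.72) / 2 -
                           (120.72 - 79.67) / 2 * cos(2 * pi * tp),
                         rate, kind = "pressure")
  res <- compliance_pipeline(stk, ptrace, ph, pressure_regime(79.67, 120.72))
  expect_equal(res$DPmin, 3.227, tolerance = 2e-3)
  expect_equal(res$DPmax, 3.237, tolerance = 2e-3)
  expect_equal(res$Pmin, 79.67, tolerance = 0.01)
  expect_equal(res$Pmax, 120.72, tolerance = 0.01)
})

test_that("frame stacks round-trip through the PNG artifact format", {
  stk <- render_frames(rep(3.8, 3), mm_per_pixel = 0.01, frame_rate = 30,
                       jitter_px = 2, seed = 13)
  dir <- file.path(withr::local_tempdir(), "frames")
  write_frames_png(stk, dir)
  back <- read_frames_png(dir)
  expect_equal(length(back$frames), 3)
  expect_equal(back$frame_rate, 30)
  expect_equal(back$mm_per_pixel, 0.01)
  # PNG is 8-bit; allow one quantization step
  expect_lt(max(abs(back$frames[[2]] - stk$frames[[2]])), 1 / 250)
})
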