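test_that("marker calibration is the known separation over pixel distance", {
  expect_equal(calibrate_film(c(100, 600), 200), 0.4)
  # homogeneous: doubling the known separation doubles the factor
  expect_equal(calibrate_film(c(120, 870), 2 * 300),
               2 * calibrate_film(c(120, 870), 300))
  # markers d px apart with known d * c mm give exactly c mm/px
  set.seed(9)
  for (k in 1:10) {
    d <- runif(1, 50, 900); c0 <- runif(1, 0.05, 1)
    expect_equal(calibrate_film(c(10, 10 + d), d * c0), c0)
  }
  expect_error(calibrate_film(c(50, 50), 100), class = "ctoverrange_calibration")
  expect_error(calibrate_film(c(10, 60), 0), class = "ctoverrange_calibration")
})

test_that("synthetic strip band length matches translation + collimation", {
  # a 254 mm translation with 24 mm collimation exposes a 278 mm band
  p <- scan_protocol(1, 0.5, 24, 3, voi_length = 254 + 24 - 53.85)
  spec <- noise_free_spec(p, seed = 2)
  strip <- simulate_cr_strip(spec, mm_per_pixel = 0.4)
  expect_equal(strip$truth$translation, 254, tolerance = 1e-9)
  expect_equal(strip$truth$band_length_mm, 278, tolerance = 1e-9)
  meas <- exposed_band_length(strip)
  expect_equal(meas$exposed_length, 278, tolerance = 0.01)
  # 695 px at 0.4 mm/px is 27.8 cm
  expect_equal(meas$band_pixels, 695, tolerance = 0.01)
})

test_that("a near-stationary table exposes little more than one beam width", {
  # shrink the embedded over-ranging to 4 mm so a 30 mm VOI yields a 10 mm
  # translation: the band is translation + one full collimation width
  m <- overrange_model(pitch_intercept = 4, pitch_slope = 0,
                       regime_boundary = 4, constant_region_value = 4,
                       linear_region_slope = 0, jump_fraction = 0)
  p <- scan_protocol(1, 0.5, 24, 3, voi_length = 30)
  spec <- simulation_spec(p, model = m, noise_sd = 0, seed = 3)
  strip <- simulate_cr_strip(spec, mm_per_pixel = 0.2, marker_separation = 60)
  expect_equal(strip$truth$translation, 10)
  expect_equal(strip$truth$band_length_mm, 10 + 24)
})

test_that("marker location and calibration round-trip the pixel pitch", {
  p <- abdomen_protocol()
  spec <- simulation_spec(p, noise_sd = 0.01, seed = 17)
  strip <- simulate_cr_strip(spec, mm_per_pixel = 0.4)
  centers <- locate_markers(strip)
  expect_length(centers, 3)
  mmpp <- calibrate_film(centers[1:2], strip$marker_separation)
  expect_equal(mmpp, 0.4, tolerance = 0.005)     # within 0.5%
  # full round-trip: calibrate then measure recovers the physical band
  meas <- exposed_band_length(strip, mm_per_pixel = mmpp)
  expect_equal(meas$exposed_length, strip$truth$band_length_mm,
               tolerance = 0.005)
})

test_that("band measurement survives 50 random geometries within 2 px", {
  set.seed(23)
  for (k in 1:50) {
    p <- random_protocol()
    mmpp <- runif(1, 0.2, 0.6)
    spec <- simulation_spec(p, noise_sd = 0.01, seed = 3000 + k)
    strip <- simulate_cr_strip(spec, mm_per_pixel = mmpp)
    meas <- exposed_band_length(strip)
    expect_lt(abs(meas$band_pixels - strip$truth$band_cols), 2)
  }
})

test_that("band width is invariant to global intensity scaling", {
  p <- abdomen_protocol()
  strip <- simulate_cr_strip(noise_free_spec(p, seed = 5))
  dimmed <- strip
  dimmed$image <- strip$image * 0.31
  expect_equal(exposed_band_length(dimmed)$band_pixels,
               exposed_band_length(strip)$band_pixels)
})

test_that("multi-image averaging reports mean and pixel spread", {
  p <- abdomen_protocol()
  strips <- lapply(1:7, function(s)
    simulate_cr_strip(simulation_spec(p, noise_sd = 0.02, seed = 600 + s)))
  meas <- exposed_band_length(strips)
  expect_equal(meas$n_images, 7L)
  expect_true(is.finite(meas$pixel_sd))
  expect_lt(abs(meas$band_pixels - strips[[1]]$truth$band_cols), 2)
})

test_that("blank images raise a detection error", {
  p <- abdomen_protocol()
  strip <- simulate_cr_strip(noise_free_spec(p, seed = 5))
  strip$image[] <- 0
  expect_error(exposed_band_length(strip), class = "ctoverrange_detection")
})

test_that("film/console reconciliation yields the half-collimation excess", {
  rec <- reconcile_lengths(278, 267, 24)
  expect_equal(rec$excess, 11)
  expect_equal(rec$excess_in_collimation_halves, 11 / 12)
  expect_equal(reconcile_lengths(250, 250, 24)$excess, 0)
  expect_equal(reconcile_lengths(262, 250, 24)$excess_in_collimation_halves, 1)
})
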