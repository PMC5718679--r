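test_that("strict protocol validation mirrors the scanner menus", {
  expect_s3_class(abdomen_protocol(), "scan_protocol")
  expect_error(abdomen_protocol(pitch = 0.52), class = "ctoverrange_invalid_protocol")
  expect_error(abdomen_protocol(rotation_time = 0.6), class = "ctoverrange_invalid_protocol")
  expect_error(abdomen_protocol(collimation = 16), class = "ctoverrange_invalid_protocol")
  expect_error(abdomen_protocol(slice_thickness = 1, collimation = 24),
               class = "ctoverrange_invalid_protocol")
  # permissive mode accepts arbitrary positive values
  expect_s3_class(scan_protocol(0.52, 0.6, 16, 1.2, 100, strict = FALSE),
                  "scan_protocol")
  expect_error(scan_protocol(1, 0, 24, 3, 251, strict = FALSE),
               class = "ctoverrange_invalid_protocol")
  expect_error(scan_protocol(1, 0.5, 24, 3, -5, strict = FALSE),
               class = "ctoverrange_invalid_protocol")
})

test_that("nominal table speed follows the helical relation", {
  expect_equal(nominal_table_speed(abdomen_protocol(pitch = 1)), 48)
  expect_equal(nominal_table_speed(abdomen_protocol(pitch = 1.5)), 72)
  expect_equal(nominal_table_speed(scan_protocol(0, 0.5, 24, 3, 251,
                                                 strict = FALSE)), 0)
  # linear in pitch; doubling the rotation time halves the speed
  for (pitch in c(0.5, 0.85, 1.25)) {
    v1 <- nominal_table_speed(scan_protocol(pitch, 0.5, 24, 3, 251, strict = FALSE))
    v2 <- nominal_table_speed(scan_protocol(2 * pitch, 0.5, 24, 3, 251, strict = FALSE))
    v3 <- nominal_table_speed(scan_protocol(pitch, 1.0, 24, 3, 251, strict = FALSE))
    expect_equal(v2, 2 * v1)
    expect_equal(v3, v1 / 2)
  }
})

test_that("default 24 mm model reproduces the fitted pitch endpoints", {
  m <- siemens_overrange_model(24)
  # fitted so pitch 0.5 -> 43.8 mm and pitch 1.5 -> 63.9 mm; the midpoint
  # follows by linearity: (43.8 + 63.9) / 2 = 53.85 mm
  expect_equal(ground_truth_overrange(m, abdomen_protocol(pitch = 0.5)), 43.8)
  expect_equal(ground_truth_overrange(m, abdomen_protocol(pitch = 1.5)), 63.9)
  expect_equal(ground_truth_overrange(m, abdomen_protocol(pitch = 1.0)), 53.85)
})

test_that("slice-thickness law has a plateau, a jump, and a linear regime", {
  m12 <- siemens_overrange_model(12)
  p <- function(st) abdomen_protocol(collimation = 12, slice_thickness = st)
  # constant region: identical values across the thin-slice plateau
  expect_equal(ground_truth_overrange(m12, p(1)), ground_truth_overrange(m12, p(2)))
  expect_equal(ground_truth_overrange(m12, p(1)), 11.1)
  # 88% jump between the plateau and the first thick-slice entry
  expect_equal(ground_truth_overrange(m12, p(3)) / ground_truth_overrange(m12, p(2)),
               1.88)
  # published endpoint of the thick-slice regime
  expect_equal(ground_truth_overrange(m12, p(10)), 29.7)
  m24 <- siemens_overrange_model(24)
  p24 <- function(st) abdomen_protocol(collimation = 24, slice_thickness = st)
  expect_equal(ground_truth_overrange(m24, p24(5)) / ground_truth_overrange(m24, p24(4)),
               1.77)
  # monotone non-decreasing in slice thickness at fixed collimation
  for (m in list(m12, m24)) {
    coll <- if (identical(m$regime_boundary, 2)) 12 else 24
    grid <- seq(min_slice_thickness(coll), 10, by = 0.25)
    vals <- vapply(grid, function(st)
      ground_truth_overrange(m, scan_protocol(1, 0.5, coll, st, 251,
                                              strict = FALSE)), 0)
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("pitch_slope of zero makes the law pitch-independent", {
  m <- overrange_model(pitch_intercept = 50, pitch_slope = 0,
                       regime_boundary = 4, constant_region_value = 25,
                       linear_region_slope = 1.5, jump_fraction = 0.8)
  vals <- vapply(c(0.5, 1, 1.5), function(pt)
    ground_truth_overrange(m, abdomen_protocol(pitch = pt)), 0)
  expect_equal(diff(range(vals)), 0)
})

test_that("over-ranging law ignores rotation time and VOI length", {
  m <- siemens_overrange_model(24)
  ref <- ground_truth_overrange(m, abdomen_protocol())
  for (rt in c(0.5, 0.75, 1, 1.5))
    for (voi in c(197, 251, 300))
      expect_identical(ground_truth_overrange(
        m, abdomen_protocol(rotation_time = rt, voi_length = voi)), ref)
})

test_that("slice thickness below the scanner minimum is a domain error", {
  m <- siemens_overrange_model(24)
  p <- scan_protocol(1, 0.5, 24, 1, 251, strict = FALSE)
  expect_error(ground_truth_overrange(m, p), class = "ctoverrange_domain")
})

test_that("dosimeter layout validates separation and warns off-nominal", {
  lay <- dosimeter_layout(c(0, 250))
  expect_equal(lay$separation, 250)
  expect_warning(dosimeter_layout(c(0, 97)), class = "ctoverrange_layout_separation")
  expect_silent(dosimeter_layout(c(0, 97), check_separation = FALSE))
  expect_error(dosimeter_layout(c(50, 50)), class = "ctoverrange_invalid_layout")
})
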