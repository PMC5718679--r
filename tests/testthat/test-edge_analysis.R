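test_that("interpolated crossings match the analytic trapezoid oracle", {
  # rise over [1.0, 1.5], fall over [3.0, 3.5]: the continuous 10%
  # crossings are at 1.0 + 0.1 * 0.5 = 1.05 s and 3.0 + 0.9 * 0.5 = 3.45 s
  tr <- analytic_trapezoid(t_rise0 = 1.0, t_fall0 = 3.0, ramp = 0.5)
  e <- detect_edges(tr, 0.10)
  expect_equal(e$t_lead, 1.05, tolerance = 0.005)   # within dt / 2
  expect_equal(e$t_trail, 3.45, tolerance = 0.005)
  # off-grid geometry still lands within half a sample of the oracle
  tr2 <- analytic_trapezoid(t_rise0 = 0.7631, t_fall0 = 2.9113, ramp = 0.213)
  e2 <- detect_edges(tr2, 0.10)
  expect_equal(e2$t_lead, 0.7631 + 0.1 * 0.213, tolerance = 0.005)
  expect_equal(e2$t_trail, 2.9113 + 0.9 * 0.213, tolerance = 0.005)
  expect_equal(e2$threshold_level, 0.1 * e2$peak_value)
})

test_that("rectangular pulses give threshold-independent edges", {
  x <- c(rep(0, 50), rep(1, 100), rep(0, 50))
  tr <- dosimeter_trace(x, 0.01)
  e10 <- detect_edges(tr, 0.10, interpolate = FALSE)
  e50 <- detect_edges(tr, 0.50, interpolate = FALSE)
  expect_identical(e10[c("t_lead", "t_trail")], e50[c("t_lead", "t_trail")])
  # with sub-sample interpolation a vertical edge can only move within the
  # straddling interval
  i10 <- detect_edges(tr, 0.10)
  i50 <- detect_edges(tr, 0.50)
  expect_lt(abs(i10$t_lead - i50$t_lead), 0.01)
  expect_lt(abs(i10$t_trail - i50$t_trail), 0.01)
})

test_that("edge detection is invariant to scaling and time shifts", {
  tr <- analytic_trapezoid(0.9, 2.7, 0.3)
  e <- detect_edges(tr)
  scaled <- dosimeter_trace(tr$readings * 137, tr$sample_period, tr$t0, "table_1")
  es <- detect_edges(scaled)
  expect_equal(es$t_lead, e$t_lead)
  expect_equal(es$t_trail, e$t_trail)
  shifted <- dosimeter_trace(tr$readings, tr$sample_period, tr$t0 + 4.5, "table_1")
  eh <- detect_edges(shifted)
  expect_equal(eh$t_lead, e$t_lead + 4.5)
  expect_equal(eh$t_trail, e$t_trail + 4.5)
})

test_that("consecutive samples exactly at threshold break ties earliest/latest", {
  x <- c(0, 0, 0.1, 0.1, 1, 1, 1, 0.1, 0.1, 0, 0)
  tr <- dosimeter_trace(x, 0.01)
  e <- detect_edges(tr, 0.10)
  # samples 3 and 4 sit exactly at threshold: sample 3 (t = 0.02) leads;
  # samples 8 and 9 ditto: sample 9 (t = 0.08) trails
  expect_equal(e$t_lead, 0.02)
  expect_equal(e$t_trail, 0.08)
})

test_that("degenerate traces raise structured errors", {
  expect_error(detect_edges(dosimeter_trace(rep(0, 10), 0.01)),
               class = "ctoverrange_no_signal")
  expect_error(detect_edges(dosimeter_trace(rep(2, 10), 0.01)),
               class = "ctoverrange_no_signal")
  two_peaks <- dosimeter_trace(c(0, 1, 1, 0, 0, 0, 1, 1, 0), 0.01)
  err <- expect_error(detect_edges(two_peaks),
                      class = "ctoverrange_ambiguous_peak")
  expect_match(conditionMessage(err), "2 disjoint")
  # a 3-sample median filter rejects an isolated spike
  spiky <- dosimeter_trace(c(0, 0, 5, 0, 0, 1, 1, 1, 1, 0, 0), 0.01)
  expect_error(detect_edges(spiky), class = "ctoverrange_ambiguous_peak")
  expect_s3_class(detect_edges(spiky, median_filter = TRUE), "edge_times")
})

test_that("beam-on duration is the trailing minus leading edge", {
  e <- edge_times(0.55, 5.80, threshold_level = 0.1, peak_value = 1)
  expect_equal(beam_on_duration(e), 5.25)
  e2 <- edge_times(2, 2 + 1e-4, 0.1, 1)
  expect_equal(beam_on_duration(e2), 1e-4)
  expect_error(edge_times(3, 3, 0.1, 1), class = "ctoverrange_invalid_edges")
  # a simulated bore plateau reproduces the truth within one sample period
  sim <- simulate_scan(noise_free_spec(abdomen_protocol(), seed = 2))
  expect_equal(beam_on_duration(detect_edges(sim$bore)),
               sim$truth$beam_on_duration, tolerance = 0.01)
})

test_that("table speed follows from separation and edge timing", {
  a <- edge_times(1.85, 2.4, 0.1, 1)
  b <- edge_times(3.85, 4.4, 0.1, 1)
  expect_equal(table_speed_from_traces(a, b, 97), 48.5)
  # pure time translation: both edge modes give separation / shift
  tr <- analytic_trapezoid(1.0, 3.0, 0.4)
  shift <- 1.73
  tr2 <- dosimeter_trace(tr$readings, tr$sample_period, tr$t0 + shift, "table_2")
  ea <- detect_edges(tr); eb <- detect_edges(tr2)
  expect_equal(table_speed_from_traces(ea, eb, 120, "lead"), 120 / shift)
  expect_equal(table_speed_from_traces(ea, eb, 120, "lead_and_trail"),
               120 / shift)
  expect_error(table_speed_from_traces(eb, ea, 120), class = "ctoverrange_ordering")
  expect_error(table_speed_from_traces(ea, eb, 0), class = "ctoverrange_domain")
})

test_that("lead and lead+trail speed estimates agree closely under noise", {
  p <- abdomen_protocol()
  rel <- vapply(1:50, function(seed) {
    sim <- simulate_scan(simulation_spec(p, noise_sd = 0.01, seed = seed))
    e1 <- detect_edges(sim$table_1)
    e2 <- detect_edges(sim$table_2)
    sep <- 0.8 * p$voi_length
    v_lead <- table_speed_from_traces(e1, e2, sep, "lead")
    v_both <- table_speed_from_traces(e1, e2, sep, "lead_and_trail")
    abs(v_both - v_lead) / v_lead
  }, 0)
  expect_true(all(rel <= 0.024))
})
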