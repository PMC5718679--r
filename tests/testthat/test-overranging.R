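test_that("direct estimator recovers the simulated truth (noise-free)", {
  set.seed(101)
  for (k in 1:25) {
    p <- random_protocol()
    spec <- noise_free_spec(p, seed = 1000 + k)
    out <- simulate_and_estimate(spec)
    bound <- out$sim$truth$table_speed * spec$sample_period
    expect_lt(abs(out$est$length - out$sim$truth$overrange_length), bound)
    expect_equal(out$est$total_exposed_length - out$est$voi_length,
                 out$est$length)
    expect_equal(out$est$method, "direct")
  }
})

test_that("exposure and translation conventions differ by one collimation", {
  p <- abdomen_protocol()
  spec <- noise_free_spec(p, seed = 8)
  sim <- simulate_scan(spec)
  exp_conv <- direct_overrange(sim$bore, sim$table_1, sim$table_2,
                               spec$layout, p$voi_length, p$collimation,
                               convention = "exposure")
  trans <- direct_overrange(sim$bore, sim$table_1, sim$table_2,
                            spec$layout, p$voi_length, p$collimation,
                            convention = "translation")
  expect_equal(exp_conv$length - trans$length, p$collimation)
  expect_true(exp_conv$includes_penumbra)
  expect_false(trans$includes_penumbra)
})

test_that("zero over-ranging is flagged degenerate, not raised", {
  p <- abdomen_protocol()
  spec <- noise_free_spec(p, seed = 8)
  out <- simulate_and_estimate(spec)
  degen <- overrange_result(length = out$est$total_exposed_length -
                              out$est$total_exposed_length,
                            total_exposed_length = out$est$total_exposed_length,
                            voi_length = out$est$total_exposed_length)
  expect_equal(degen$length, 0)
  expect_equal(degen$flag, "degenerate")
  expect_true(is.na(out$est$flag))
})

test_that("one-dosimeter mode equals the direct method at the true speed", {
  p <- abdomen_protocol()
  spec <- noise_free_spec(p, seed = 13)
  out <- simulate_and_estimate(spec)
  one <- one_dosimeter_overrange(out$sim$bore,
                                 console_speed = out$est$table_speed,
                                 voi_length = p$voi_length,
                                 collimation = p$collimation)
  expect_equal(one$length, out$est$length, tolerance = 1e-10)
  expect_equal(one$method, "direct_one_dosimeter")
  # a +1% speed bias propagates as 1% of the speed x duration term
  biased <- one_dosimeter_overrange(out$sim$bore,
                                    console_speed = 1.01 * out$est$table_speed,
                                    voi_length = p$voi_length,
                                    collimation = p$collimation)
  expect_equal(biased$length - one$length,
               0.01 * out$est$table_speed * one$beam_on_duration,
               tolerance = 1e-8)
})

test_that("a 254 mm translation at 48.4 mm/s takes 5.25 s", {
  # timing -> distance arithmetic of the one-dosimeter mode
  speed <- 48.4
  duration <- 254 / speed
  expect_equal(round(duration, 2), 5.25)
  tt <- seq(0, duration + 1, by = 0.01)
  up <- pmin(1, pmax(0, (tt - 0.495) / 0.05))
  dn <- pmin(1, pmax(0, ((0.5 + duration + 0.005) - tt) / 0.05))
  bore <- dosimeter_trace(pmin(up, dn), 0.01)
  est <- one_dosimeter_overrange(bore, speed, voi_length = 200,
                                 collimation = 24,
                                 convention = "translation")
  expect_equal(est$total_exposed_length, 254, tolerance = 1e-3)
})

test_that("estimate is invariant to the VOI length chosen", {
  lens <- c(197, 251, 300)
  ests <- vapply(seq_along(lens), function(i) {
    p <- abdomen_protocol(voi_length = lens[i])
    simulate_and_estimate(noise_free_spec(p, seed = 50 + i))$est$length
  }, 0)
  expect_lt(diff(range(ests)), 2 * 48 * 0.01)  # two quantization steps
})

test_that("estimate is invariant to rotation time at fixed pitch", {
  ests <- vapply(c(0.5, 0.75, 1, 1.5), function(rt) {
    p <- abdomen_protocol(rotation_time = rt)
    spec <- simulation_spec(p, noise_sd = 0.01, seed = round(1000 * rt))
    simulate_and_estimate(spec)$est$length
  }, 0)
  expect_true(all(abs(ests - mean(ests)) / mean(ests) <= 0.033))
})

test_that("pitch regression on simulated estimates recovers the model law", {
  m <- siemens_overrange_model(24)
  pitches <- seq(0.5, 1.5, by = 0.1)
  ests <- vapply(seq_along(pitches), function(i) {
    p <- abdomen_protocol(pitch = pitches[i])
    simulate_and_estimate(noise_free_spec(p, seed = 200 + i))$est$length
  }, 0)
  fit <- stats::lm(ests ~ pitches)
  expect_equal(unname(coef(fit)[2]), m$pitch_slope, tolerance = 0.05)
  expect_equal(unname(coef(fit)[1]), m$pitch_intercept, tolerance = 0.05)
})

test_that("inconsistent bore/table geometry is rejected", {
  p <- abdomen_protocol()
  spec <- noise_free_spec(p, seed = 21)
  sim <- simulate_scan(spec)
  # a bore trace much shorter than the table transit cannot belong to the scan
  short_bore <- dosimeter_trace(c(rep(0, 20), rep(1, 30), rep(0, 20)), 0.01,
                                label = "bore")
  expect_error(direct_overrange(short_bore, sim$table_1, sim$table_2,
                                spec$layout, p$voi_length, p$collimation),
               class = "ctoverrange_inconsistent_geometry")
})
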