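# Shared fixtures: all built in code, seeded.

abdomen_protocol <- function(pitch = 1, rotation_time = 0.5, collimation = 24,
                             slice_thickness = 3, voi_length = 251, ...) {
  scan_protocol(pitch, rotation_time, collimation, slice_thickness,
                voi_length, ...)
}

# A random strict-menu protocol whose geometry guarantees that both table
# dosimeters (at 10% / 90% of the VOI) pass fully through the beam.
random_protocol <- function() {
  collimation <- sample(c(12, 24), 1)
  slices <- c(0.75, 1, 1.5, 2, 3, 4, 5, 6, 8, 10)
  slices <- slices[slices >= min_slice_thickness(collimation)]
  scan_protocol(pitch = sample(seq(0.5, 1.5, by = 0.05), 1),
                rotation_time = sample(c(0.5, 0.75, 1, 1.5), 1),
                collimation = collimation,
                slice_thickness = sample(slices, 1),
                voi_length = round(stats::runif(1, 150, 350), 1))
}

noise_free_spec <- function(protocol, seed = 1L, ...) {
  simulation_spec(protocol, noise_sd = 0, seed = seed, ...)
}

# Simulate one scan and estimate its over-ranging with the direct method.
simulate_and_estimate <- function(spec, ...) {
  sim <- simulate_scan(spec)
  est <- direct_overrange(sim$bore, sim$table_1, sim$table_2, spec$layout,
                          voi_length = spec$protocol$voi_length,
                          collimation = spec$protocol$collimation, ...)
  list(sim = sim, est = est)
}

# Sampled trapezoidal pulse with analytically known geometry: linear rise
# over [t_rise0, t_rise0 + ramp], unit plateau, symmetric fall starting at
# t_fall0. The continuous crossing of level `f` is at t_rise0 + f * ramp
# (rising) and t_fall0 + (1 - f) * ramp (falling).
analytic_trapezoid <- function(t_rise0, t_fall0, ramp, dt = 0.01,
                               total = t_fall0 + ramp + 1) {
  tt <- seq(0, total, by = dt)
  up <- pmin(1, pmax(0, (tt - t_rise0) / ramp))
  dn <- pmin(1, pmax(0, (t_fall0 + ramp - tt) / ramp))
  dosimeter_trace(pmin(up, dn), sample_period = dt, t0 = 0, label = "table_1")
}
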