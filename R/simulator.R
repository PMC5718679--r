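# Dosimeter-trace simulator. Stands in for the scanner + fiber-optic
# dosimetry hardware: one stationary bore dosimeter records a plateau for
# the whole beam-on time, two table-mounted dosimeters record trapezoidal
# beam-passage peaks as the table translates them through the fan. A known
# ground-truth over-ranging length is embedded so estimators can be tested
# by parameter recovery; the truth record is returned only by the simulator
# and never consumed by an estimator.

#' Uniformly sampled dose-rate trace of one point dosimeter
#'
#' @param readings Non-negative dose-rate samples (arbitrary consistent
#'   units).
#' @param sample_period Sampling period, s (default 0.010, the temporal
#'   resolution of the fiber-optic system being emulated).
#' @param t0 Time of the first sample, s.
#' @param label One of `"bore"`, `"table_1"`, `"table_2"` (free-form labels
#'   are accepted for derived signals such as film column profiles).
#' @return An object of class `dosimeter_trace` with fields `times`,
#'   `readings`, `sample_period`, `t0`, `label`.
#' @export
dosimeter_trace <- function(readings, sample_period = 0.010, t0 = 0,
                            label = "bore") {
  if (!is.numeric(readings) || length(readings) < 2L)
    stop_ct("invalid_trace", "readings must be a numeric vector of length >= 2")
  if (any(!is.finite(readings)))
    stop_ct("invalid_trace", "readings contain non-finite values")
  if (any(readings < 0))
    stop_ct("invalid_trace", "readings must be non-negative")
  if (!is_number(sample_period) || sample_period <= 0)
    stop_ct("invalid_trace", "sample_period must be a positive number (s)")
  structure(list(times = t0 + sample_period * (seq_along(readings) - 1L),
                 readings = as.numeric(readings),
                 sample_period = sample_period, t0 = t0,
                 label = as.character(label)[1]),
            class = "dosimeter_trace")
}

#' @export
print.dosimeter_trace <- function(x, ...) {
  cat(sprintf("<dosimeter_trace> %s: %d samples @ %g ms, t0 = %.3f s, peak %.4g\n",
              x$label, length(x$readings), 1000 * x$sample_period, x$t0,
              max(x$readings)))
  invisible(x)
}

#' @export
plot.dosimeter_trace <- function(x, ...,
                                 xlab = "time (s)", ylab = "reading (a.u.)") {
  graphics::plot(x$times, x$readings, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# A valid scan trace must actually contain signal: at least one sample
# strictly above 10% of its own maximum (trivially true unless flat/zero).
validate_scan_trace <- function(trace) {
  m <- max(trace$readings)
  if (m <= 0 || !any(trace$readings > 0.1 * m))
    stop_ct("no_signal", "trace '%s' carries no usable signal", trace$label)
  invisible(trace)
}

#' Simulation specification
#'
#' Gathers everything the trace simulator needs: the scan protocol, the
#' dosimeter layout, the ground-truth over-ranging model, and the nuisance
#' parameters of the hardware emulation.
#'
#' @param protocol A [scan_protocol()].
#' @param layout A [dosimeter_layout()]; default places the two table
#'   dosimeters at 10% and 90% of the VOI length.
#' @param model An [overrange_model()]; default [siemens_overrange_model()]
#'   for the protocol's collimation.
#' @param noise_sd Relative (multiplicative Gaussian) noise per sample;
#'   default 0.01.
#' @param ramp_time Table acceleration/deceleration time, s; default 0 (the
#'   acceleration regions of the real scanner are negligible).
#' @param gantry_ripple Relative amplitude of rotation-frequency modulation
#'   of the free-in-air response, in [0, 0.05]; default 0.
#' @param seed Integer seed driving all randomness of one simulated scan.
#' @param sample_period Dosimeter sampling period, s.
#' @param penumbra Width of the linear beam penumbra, mm; default 10% of the
#'   collimation.
#' @param dosimeter_size Longitudinal extent of each scintillator, mm,
#'   modelled as a boxcar blur of the beam profile; default 0.5. Set 0 for a
#'   true point detector.
#' @param edge_rise_time Tube turn-on/turn-off transition, s, modelled as a
#'   linear ramp anchored so that the 10%-of-plateau crossing marks the
#'   nominal beam-on boundary; default 0.05.
#' @param lead_in Quiet time before beam-on in the traces, s.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(protocol, layout = NULL, model = NULL,
                            noise_sd = 0.01, ramp_time = 0, gantry_ripple = 0,
                            seed = 1L, sample_period = 0.010,
                            penumbra = NULL, dosimeter_size = 0.5,
                            edge_rise_time = 0.05, lead_in = 0.5) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (is.null(layout))
    layout <- dosimeter_layout(c(0.1, 0.9) * protocol$voi_length,
                               check_separation = FALSE)
  stopifnot(inherits(layout, "dosimeter_layout"))
  if (is.null(model)) model <- siemens_overrange_model(protocol$collimation)
  stopifnot(inherits(model, "overrange_model"))
  if (!is_number(noise_sd) || noise_sd < 0)
    stop_ct("invalid_spec", "noise_sd must be >= 0")
  if (!is_number(ramp_time) || ramp_time < 0)
    stop_ct("invalid_spec", "ramp_time must be >= 0")
  if (!is_number(gantry_ripple) || gantry_ripple < 0 || gantry_ripple > 0.05)
    stop_ct("invalid_spec",
            "gantry_ripple must lie in [0, 0.05] (free-in-air response varies < 5%% per revolution)")
  if (is.null(penumbra)) penumbra <- 0.1 * protocol$collimation
  structure(list(protocol = protocol, layout = layout, model = model,
                 noise_sd = noise_sd, ramp_time = ramp_time,
                 gantry_ripple = gantry_ripple, seed = as.integer(seed),
                 sample_period = sample_period, penumbra = penumbra,
                 dosimeter_size = dosimeter_size,
                 edge_rise_time = edge_rise_time, lead_in = lead_in),
            class = "simulation_spec")
}

# Trapezoidal longitudinal beam profile: unit plateau of FWHM = collimation,
# linear penumbra of width `pen` on each side.
beam_profile <- function(z, collimation, pen) {
  if (pen <= 0) return(as.numeric(abs(z) <= collimation / 2))
  pmin(1, pmax(0, ((collimation + pen) / 2 - abs(z)) / pen))
}

# Beam profile blurred by the finite scintillator size (boxcar average,
# Simpson's rule over 5 points; exact to the piecewise-quadratic blur
# within ~1e-3 relative).
blurred_profile <- function(z, collimation, pen, d) {
  if (d <= 0) return(beam_profile(z, collimation, pen))
  off <- d * c(-0.5, -0.25, 0, 0.25, 0.5)
  w <- c(1, 4, 2, 4, 1) / 12
  out <- 0
  for (k in seq_along(off))
    out <- out + w[k] * beam_profile(z + off[k], collimation, pen)
  out
}

# Table translation (mm) accumulated at time t since motion start, for a
# trapezoidal speed profile: ramps of duration r to/from speed v, total
# moving time Tm.
.translation_at <- function(t, v, r, Tm) {
  t <- pmax(0, pmin(t, Tm))
  if (r <= 0) return(v * t)
  accel <- pmin(t, r)
  cruise <- pmax(0, pmin(t, Tm - r) - r)
  decel <- pmax(0, t - (Tm - r))
  v * accel^2 / (2 * r) + v * cruise + v * (decel - decel^2 / (2 * r))
}

# Tube-output envelope: linear edges of duration `er` anchored so the
# continuous 10%-of-plateau crossings fall exactly at t_on and t_off.
.beam_envelope <- function(t, t_on, t_off, er) {
  if (er <= 0) return(as.numeric(t >= t_on & t <= t_off))
  up <- pmin(1, pmax(0, (t - (t_on - 0.1 * er)) / er))
  dn <- pmin(1, pmax(0, ((t_off + 0.1 * er) - t) / er))
  pmin(up, dn)
}

.apply_nuisance <- function(x, times, spec) {
  if (spec$gantry_ripple > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x * (1 + spec$gantry_ripple *
                sin(2 * pi * times / spec$protocol$rotation_time + phase))
  }
  if (spec$noise_sd > 0)
    x <- x * (1 + stats::rnorm(length(x), 0, spec$noise_sd))
  pmax(x, 0)
}

#' Simulate the three dosimeter traces of one helical scan
#'
#' Generates the bore plateau and the two trapezoidal table-dosimeter peaks
#' for a scan whose total exposed length equals the VOI length plus a known
#' ground-truth over-ranging length. The beam (fan plane) is fixed in the
#' laboratory frame; in table coordinates its center translates at the
#' nominal table speed across `voi_length + overrange - collimation` mm
#' (the table translation), so that the exposed band - translation plus one
#' full collimation width - spans `voi_length + overrange` mm, centred on
#' the VOI (half the over-ranging at each end, as required by the
#' reconstruction).
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `ct_scan_sim` with elements `bore`, `table_1`,
#'   `table_2` ([dosimeter_trace()] objects) and `truth`, a record of
#'   `overrange_length` (mm), `table_speed` (mm/s), `beam_on_duration` (s),
#'   `translation` (mm), `exposed_length` (mm) and `t_on` (s). The truth
#'   record is for test assertions only; estimators must not consume it.
#' @export
simulate_scan <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  p <- spec$protocol
  v <- nominal_table_speed(p)
  if (v <= 0)
    stop_ct("invalid_protocol", "table speed must be positive to simulate a scan")
  L <- ground_truth_overrange(spec$model, p)
  W <- p$collimation
  D <- p$voi_length + L - W            # table translation during beam-on, mm
  if (D <= 0)
    stop_ct("geometry",
            "VOI (%g mm) + over-ranging (%g mm) shorter than one collimation width",
            p$voi_length, L)
  T_beam <- D / v + spec$ramp_time     # ramps each lose half a ramp of travel
  t_on <- spec$lead_in
  t_off <- t_on + T_beam
  dt <- spec$sample_period
  n <- ceiling((t_off + spec$lead_in) / dt) + 1L
  times <- dt * (seq_len(n) - 1L)

  # Beam center in table coordinates: starts half a collimation inside the
  # exposed band, which itself starts half the over-ranging before the VOI
  # (VOI spans [0, voi_length]).
  B0 <- -L / 2 + W / 2
  beam_center <- B0 + .translation_at(times - t_on, v, spec$ramp_time, T_beam)
  env <- .beam_envelope(times, t_on, t_off, spec$edge_rise_time)

  set.seed(spec$seed)
  bore <- dosimeter_trace(.apply_nuisance(env, times, spec), dt, 0, "bore")
  pen <- spec$penumbra
  support <- (W + pen + spec$dosimeter_size) / 2
  tables <- vector("list", 2L)
  for (k in 1:2) {
    q <- spec$layout$table_positions[k]
    prof <- blurred_profile(q - beam_center, W, pen, spec$dosimeter_size) * env
    if (all(prof <= 0))
      stop_ct("geometry", "table dosimeter at %g mm never enters the beam", q)
    if (q - support < B0 || q + support > B0 + D)
      warn_ct("partial_passage",
              "table dosimeter at %g mm does not pass fully through the beam", q)
    tables[[k]] <- dosimeter_trace(.apply_nuisance(prof, times, spec), dt, 0,
                                   paste0("table_", k))
  }
  for (tr in c(list(bore), tables)) validate_scan_trace(tr)

  structure(list(bore = bore, table_1 = tables[[1]], table_2 = tables[[2]],
                 truth = list(overrange_length = L, table_speed = v,
                              beam_on_duration = T_beam, translation = D,
                              exposed_length = D + W, t_on = t_on)),
            class = "ct_scan_sim")
}

#' @export
print.ct_scan_sim <- function(x, ...) {
  cat(sprintf(
    "<ct_scan_sim> beam-on %.2f s at %.1f mm/s; exposed %.1f mm (over-ranging %.1f mm)\n",
    x$truth$beam_on_duration, x$truth$table_speed, x$truth$exposed_length,
    x$truth$overrange_length))
  invisible(x)
}

#' Simulate a computed-radiography strip exposed by one scan
#'
#' Renders the longitudinal exposure pattern of the scan as a grayscale
#' raster: an exposed band of physical length table-translation + one full
#' collimation width, flanked by penumbra ramps, plus a lane of fiducial
#' markers - a bore-side pair at a known center-to-center separation (the
#' length-to-pixel calibration) and a single far-side marker.
#'
#' @param spec A [simulation_spec()].
#' @param mm_per_pixel Physical pixel pitch of the raster, mm; must be > 0.
#' @param marker_separation Known center-to-center distance of the bore-side
#'   marker pair, mm.
#' @param strip_rows Total raster rows; the first `marker_rows` form the
#'   marker lane, the rest the film body.
#' @param marker_rows Rows of the marker lane.
#' @param margin Unexposed margin beyond each band end, mm.
#' @param image_length_mm Optional fixed physical length of the raster; a
#'   geometry error is raised if the band plus margins does not fit.
#' @return An object of class `cr_strip`: list with `image` (matrix in
#'   [0, 1], rows x columns = width x length), `mm_per_pixel`,
#'   `marker_rows`, `marker_separation`, and a `truth` record
#'   (`band_length_mm`, `band_cols`, `marker_cols`).
#' @export
simulate_cr_strip <- function(spec, mm_per_pixel = 0.4,
                              marker_separation = 200, strip_rows = 80L,
                              marker_rows = 12L, margin = 40,
                              image_length_mm = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is_number(mm_per_pixel) || mm_per_pixel <= 0)
    stop_ct("invalid_spec", "mm_per_pixel must be > 0")
  p <- spec$protocol
  v <- nominal_table_speed(p)
  L <- ground_truth_overrange(spec$model, p)
  W <- p$collimation
  D <- p$voi_length + L - W            # table translation
  band <- D + W                        # exposed physical length
  len_mm <- image_length_mm %||% (band + 2 * margin)
  if (band + 20 > len_mm)
    stop_ct("geometry", "exposed band (%.1f mm) exceeds the %.1f mm strip", band, len_mm)
  ncol <- as.integer(round(len_mm / mm_per_pixel))
  x_mm <- (seq_len(ncol) - 0.5) * mm_per_pixel   # column centers, mm

  band_start <- (len_mm - band) / 2
  pen <- spec$penumbra
  # band edge ramps mirror the beam penumbra; 10% crossings at the band ends
  up <- pmin(1, pmax(0, (x_mm - band_start) / max(pen, mm_per_pixel) + 0.1))
  dn <- pmin(1, pmax(0, (band_start + band - x_mm) / max(pen, mm_per_pixel) + 0.1))
  body_profile <- 0.9 * pmin(up, dn)

  m1 <- 15
  m2 <- m1 + marker_separation
  m3 <- len_mm - 15
  if (m2 >= len_mm)
    stop_ct("geometry", "marker pair does not fit on a %.1f mm strip", len_mm)
  marker_profile <- rep(0, ncol)
  for (m in c(m1, m2, m3)) {
    # triangular footprint, ~2 mm half-width: symmetric, so its intensity
    # centroid sits at the true (sub-pixel) marker position
    marker_profile <- marker_profile + pmax(0, 1 - abs(x_mm - m) / 2)
  }

  img <- rbind(matrix(rep(marker_profile, each = marker_rows),
                      nrow = marker_rows),
               matrix(rep(body_profile, each = strip_rows - marker_rows),
                      nrow = strip_rows - marker_rows))
  set.seed(spec$seed + 104729L)  # de-correlated from the trace noise stream
  if (spec$noise_sd > 0)
    img <- img * (1 + stats::rnorm(length(img), 0, spec$noise_sd))
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = img, mm_per_pixel = mm_per_pixel,
                 marker_rows = marker_rows,
                 marker_separation = marker_separation,
                 truth = list(band_length_mm = band,
                              band_cols = band / mm_per_pixel,
                              marker_cols = c(m1, m2, m3) / mm_per_pixel + 0.5,
                              translation = D)),
            class = "cr_strip")
}

#' @export
print.cr_strip <- function(x, ...) {
  cat(sprintf("<cr_strip> %d x %d px @ %.3f mm/px; exposed band %.1f mm\n",
              nrow(x$image), ncol(x$image), x$mm_per_pixel,
              x$truth$band_length_mm))
  invisible(x)
}
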