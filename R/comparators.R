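# The two literature methods the direct estimator is benchmarked against:
# dose-slope extrapolation (DLP versus number of rotations, extrapolated to
# zero rotations) and console readings adjusted downward by half a beam
# collimation (the film benchmark shows the raw console convention
# overstates exposure by exactly that much).

#' Series of DLP measurements at varying numbers of rotations
#'
#' @param n_rotations Number of gantry rotations of each acquisition.
#' @param dlp Measured dose-length product of each acquisition, mGy.cm.
#' @param ctdi_vol CTDIvol of the protocol, mGy.
#' @param collimation Total beam collimation, mm.
#' @param pitch Protocol pitch.
#' @return An object of class `rotation_series`.
#' @export
rotation_series <- function(n_rotations, dlp, ctdi_vol, collimation = NA_real_,
                            pitch = NA_real_) {
  if (length(n_rotations) != length(dlp))
    stop_ct("insufficient_data", "n_rotations and dlp must have equal length")
  if (length(unique(n_rotations)) < 3L)
    stop_ct("insufficient_data",
            "a dose-slope fit needs at least 3 distinct rotation counts (got %d)",
            length(unique(n_rotations)))
  o <- order(n_rotations)
  n_rotations <- n_rotations[o]; dlp <- dlp[o]
  if (any(diff(dlp) <= 0))
    stop_ct("insufficient_data", "dlp must be strictly increasing in n_rotations")
  if (!is_number(ctdi_vol) || ctdi_vol <= 0)
    stop_ct("domain", "ctdi_vol must be > 0 (mGy)")
  structure(list(n_rotations = n_rotations, dlp = dlp, ctdi_vol = ctdi_vol,
                 collimation = collimation, pitch = pitch),
            class = "rotation_series")
}

#' Dose-slope over-ranging estimate
#'
#' Ordinary least-squares fit of DLP against the number of rotations; the
#' intercept at zero rotations is the DLP attributable solely to
#' over-ranging, converted to length by dividing by CTDIvol (assuming
#' DLP = CTDIvol x length holds exactly across the over-ranged region -
#' the method's inherent first-approximation bias).
#'
#' @param series A [rotation_series()].
#' @return An [overrange_result()] with `method = "dose_slope"` and fit
#'   diagnostics (`r_squared`, `intercept_mGycm`, `intercept_se_mGycm`,
#'   `slope_mGycm_per_rotation`) attached. A negative intercept yields a
#'   flagged result, not an error.
#' @export
dose_slope_overrange <- function(series) {
  stopifnot(inherits(series, "rotation_series"))
  fit <- stats::lm(dlp ~ n_rotations,
                   data = data.frame(n_rotations = series$n_rotations,
                                     dlp = series$dlp))
  sm <- suppressWarnings(summary(fit))  # silence "essentially perfect fit"
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  a_se <- sm$coefficients[1, 2]
  len <- a / series$ctdi_vol * 10          # mGy.cm / mGy -> cm -> mm
  overrange_result(length = len,
                   total_exposed_length = NA_real_, voi_length = NA_real_,
                   uncertainty = a_se / series$ctdi_vol * 10,
                   method = "dose_slope",
                   includes_penumbra = TRUE,
                   diagnostics = list(r_squared = sm$r.squared,
                                      intercept_mGycm = a,
                                      intercept_se_mGycm = a_se,
                                      slope_mGycm_per_rotation = b),
                   pitch = series$pitch)
}

#' Simulate a rotation series for the dose-slope method
#'
#' Runs the full simulate-and-measure pipeline once per rotation count: the
#' VOI length is `n x pitch x collimation` (n rotations of table feed), the
#' scan is simulated, the total exposed length is measured by the direct
#' estimator, and the DLP is CTDIvol times that length. The over-ranging
#' embedded by the simulator is constant across the series, so the
#' dose-slope intercept should recover it.
#'
#' @param protocol A [scan_protocol()]; its `voi_length` is overridden per
#'   acquisition.
#' @param n_rotations Rotation counts (at least 3 distinct values).
#' @param model Ground-truth [overrange_model()]; default per collimation.
#' @param noise_sd,seed Passed to the simulator ([simulation_spec()]).
#' @param ... Further arguments to [simulation_spec()].
#' @return A [rotation_series()].
#' @export
simulate_rotation_series <- function(protocol, n_rotations = 2:6,
                                     model = NULL, noise_sd = 0.01,
                                     seed = 1L, ...) {
  stopifnot(inherits(protocol, "scan_protocol"))
  dlps <- numeric(length(n_rotations))
  for (k in seq_along(n_rotations)) {
    voi <- n_rotations[k] * protocol$pitch * protocol$collimation
    p <- scan_protocol(protocol$pitch, protocol$rotation_time,
                       protocol$collimation, protocol$slice_thickness,
                       voi_length = voi, ctdi_vol = protocol$ctdi_vol,
                       kvp = protocol$kvp, mas = protocol$mas, strict = FALSE)
    lay <- dosimeter_layout(c(0.1, 0.9) * voi, check_separation = FALSE)
    spec <- simulation_spec(p, layout = lay, model = model,
                            noise_sd = noise_sd, seed = seed + k, ...)
    sim <- simulate_scan(spec)
    est <- direct_overrange(sim$bore, sim$table_1, sim$table_2, lay,
                            voi_length = voi, collimation = p$collimation)
    dlps[k] <- dlp(p$ctdi_vol, est$total_exposed_length)
  }
  rotation_series(n_rotations, dlps, ctdi_vol = protocol$ctdi_vol,
                  collimation = protocol$collimation, pitch = protocol$pitch)
}

#' Adjust a console over-ranging reading by half a collimation
#'
#' Console readings following the convention of adding a full beam
#' collimation width to the table displacement overstate the over-ranging:
#' the film benchmark shows the exposed length exceeds the console
#' displacement length by only one half of a beam collimation. The adjusted
#' reading therefore subtracts `collimation / 2` from the console value.
#'
#' @param console_overrange Console over-ranging reading, mm.
#' @param collimation Total beam collimation, mm.
#' @return Adjusted over-ranging length, mm. A non-positive result is
#'   returned with a warning (over-correction), not raised.
#' @examples
#' adjusted_console_overrange(47.5, 24)  # 35.5 mm
#' @export
adjusted_console_overrange <- function(console_overrange, collimation) {
  if (!is_number(console_overrange) || console_overrange <= 0)
    stop_ct("domain", "console_overrange must be > 0 (mm)")
  if (!is.numeric(collimation) || length(collimation) != 1L ||
      !is.finite(collimation) || collimation < 0)
    stop_ct("domain", "collimation must be >= 0 (mm)")
  out <- console_overrange - collimation / 2
  if (out <= 0)
    warn_ct("over_correction",
            "adjusted console reading is non-positive (%.2f mm)", out)
  out
}

#' Compare over-ranging estimates against a reference method
#'
#' @param results List of [overrange_result()] objects (or a single one).
#' @param reference The reference [overrange_result()].
#' @return A data frame with one row per method: `method`, `length_mm`,
#'   `reference_mm`, `relative_diff_pct` (= 100 x (method - reference) /
#'   reference). Mixing results recorded at different pitches raises a
#'   grouping error; compare one pitch at a time.
#' @export
method_comparison <- function(results, reference) {
  if (inherits(results, "overrange_result")) results <- list(results)
  if (length(results) == 0L)
    stop_ct("insufficient_data", "no results to compare")
  stopifnot(all(vapply(results, inherits, TRUE, "overrange_result")),
            inherits(reference, "overrange_result"))
  pitches <- c(vapply(results, function(r) r$pitch, 0), reference$pitch)
  pitches <- pitches[!is.na(pitches)]
  if (length(unique(pitches)) > 1L)
    stop_ct("grouping",
            "results span several pitches (%s); compare one pitch at a time",
            paste(sort(unique(pitches)), collapse = ", "))
  lens <- vapply(results, function(r) r$length, 0)
  data.frame(method = vapply(results, function(r) r$method, ""),
             length_mm = lens,
             reference_mm = reference$length,
             relative_diff_pct = 100 * (lens - reference$length) / reference$length)
}

#' Published cross-method over-ranging comparison (16-slice scanner)
#'
#' Digitized published bench comparison of over-ranging lengths (mm) by
#' pitch for a 16-slice scanner at 24 mm collimation: the direct timing
#' method's average values, the dose-slope extrapolation values, and the
#' raw console readings (full-collimation convention). Dose-slope values
#' were not published at pitches 0.75 and 1.25. Intended as input for
#' [adjusted_console_overrange()] and [method_comparison()].
#'
#' @return A data frame with columns `pitch`, `direct_mm`, `dose_slope_mm`,
#'   `console_mm`.
#' @export
sensation16_comparison <- function() {
  data.frame(pitch = c(0.5, 0.75, 1, 1.25, 1.5),
             direct_mm = c(43.9, 45.6, 54.8, 62.0, 67.3),
             dose_slope_mm = c(42.6, NA, 53.5, NA, 64.3),
             console_mm = c(47.5, 53.0, 63.0, 70.5, 74.5))
}
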