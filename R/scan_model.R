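# Domain types shared by the simulator and the estimators, plus the
# deterministic kinematics of a helical scan. All lengths are carried
# internally in mm and all times in s; DLP alone is reported in mGy.cm.

# Scanner menus used by strict validation (a 16-slice scanner with a routine
# abdominal protocol): pitch 0.50-1.50 in steps of 0.05, rotation times
# 0.5/0.75/1/1.5 s, total beam collimations 12 and 24 mm, reconstruction
# slice widths 0.75-10 mm with a collimation-dependent minimum.
.pitch_menu <- seq(0.50, 1.50, by = 0.05)
.rotation_menu <- c(0.5, 0.75, 1, 1.5)
.collimation_menu <- c(12, 24)
.slice_menu <- c(0.75, 1, 1.5, 2, 3, 4, 5, 6, 8, 10)

#' Minimum reconstruction slice thickness for a beam collimation
#'
#' The scanner only offers reconstruction slice widths down to 0.75 mm for a
#' 12 mm total collimation and down to 2 mm for 24 mm. For collimations
#' outside the strict menu no minimum is imposed.
#'
#' @param collimation Total beam collimation, mm.
#' @return Minimum reconstruction slice thickness, mm.
#' @export
min_slice_thickness <- function(collimation) {
  if (isTRUE(all.equal(collimation, 12))) return(0.75)
  if (isTRUE(all.equal(collimation, 24))) return(2)
  0
}

.in_menu <- function(x, menu, tol = 1e-9) any(abs(menu - x) < tol)

#' Helical scan protocol
#'
#' Bundles the operator-selectable acquisition parameters of a helical CT
#' scan together with the console/ImPACT CTDIvol. With `strict = TRUE`
#' (default) the parameters are validated against the discrete menus of the
#' 16-slice scanner modelled by this package; `strict = FALSE` accepts any
#' positive values (useful for emulating other scanners or exact target
#' table speeds).
#'
#' @param pitch Table travel per rotation divided by total collimation
#'   (dimensionless).
#' @param rotation_time Gantry rotation time, s.
#' @param collimation Total beam collimation (N x T), mm.
#' @param slice_thickness Reconstruction slice width, mm.
#' @param voi_length Operator-selected scan (volume-of-interest) length, mm.
#' @param ctdi_vol Volume CT dose index for the protocol, mGy.
#' @param kvp Tube voltage, kV (informational).
#' @param mas Tube current-time product, mAs (informational).
#' @param strict Validate against the scanner's discrete menus?
#' @return An object of class `scan_protocol`.
#' @examples
#' p <- scan_protocol(pitch = 1, rotation_time = 0.5, collimation = 24,
#'                    slice_thickness = 5, voi_length = 251)
#' nominal_table_speed(p)
#' @export
scan_protocol <- function(pitch, rotation_time, collimation, slice_thickness,
                          voi_length, ctdi_vol = 13, kvp = 120, mas = 140,
                          strict = TRUE) {
  for (nm in c("pitch", "rotation_time", "collimation", "slice_thickness",
               "voi_length", "ctdi_vol")) {
    v <- get(nm)
    if (!is_number(v))
      stop_ct("invalid_protocol", "'%s' must be a single finite number", nm)
  }
  if (rotation_time <= 0)
    stop_ct("invalid_protocol", "rotation_time must be > 0 (got %g)", rotation_time)
  if (voi_length <= 0)
    stop_ct("invalid_protocol", "voi_length must be > 0 (got %g)", voi_length)
  if (ctdi_vol < 0)
    stop_ct("invalid_protocol", "ctdi_vol must be >= 0 (got %g)", ctdi_vol)
  if (pitch < 0)
    stop_ct("invalid_protocol", "pitch must be non-negative (got %g)", pitch)
  if (collimation <= 0)
    stop_ct("invalid_protocol", "collimation must be > 0 (got %g)", collimation)
  if (slice_thickness <= 0)
    stop_ct("invalid_protocol", "slice_thickness must be > 0 (got %g)", slice_thickness)
  if (strict) {
    if (!.in_menu(pitch, .pitch_menu))
      stop_ct("invalid_protocol",
              "pitch %g not on the scanner menu (0.50-1.50 in steps of 0.05); use strict = FALSE for arbitrary values",
              pitch)
    if (!.in_menu(rotation_time, .rotation_menu))
      stop_ct("invalid_protocol",
              "rotation_time %g s not on the scanner menu (0.5, 0.75, 1, 1.5)", rotation_time)
    if (!.in_menu(collimation, .collimation_menu))
      stop_ct("invalid_protocol",
              "collimation %g mm not on the scanner menu (12, 24)", collimation)
    if (!.in_menu(slice_thickness, .slice_menu))
      stop_ct("invalid_protocol",
              "slice_thickness %g mm not on the scanner menu", slice_thickness)
    if (slice_thickness < min_slice_thickness(collimation) - 1e-9)
      stop_ct("invalid_protocol",
              "slice_thickness %g mm below the %g mm minimum for %g mm collimation",
              slice_thickness, min_slice_thickness(collimation), collimation)
  }
  structure(list(pitch = pitch, rotation_time = rotation_time,
                 collimation = collimation, slice_thickness = slice_thickness,
                 voi_length = voi_length, ctdi_vol = ctdi_vol,
                 kvp = kvp, mas = mas, strict = strict),
            class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(
    "<scan_protocol> pitch %.2f | rotation %.2f s | collimation %g mm | slice %g mm\n",
    x$pitch, x$rotation_time, x$collimation, x$slice_thickness))
  cat(sprintf("  VOI %.1f mm | CTDIvol %.1f mGy | %g kVp, %g mAs%s\n",
              x$voi_length, x$ctdi_vol, x$kvp, x$mas,
              if (x$strict) "" else " | permissive"))
  invisible(x)
}

#' Dosimeter placement geometry
#'
#' Longitudinal positions (table coordinates, mm) of the stationary bore
#' dosimeter and of the two table-mounted dosimeters. The table dosimeter
#' separation is the single physical distance measurement of the timing
#' methodology; it is nominally 200-300 mm, and a warning is raised outside
#' that range unless `check_separation = FALSE` (short-scan series
#' necessarily use smaller separations).
#'
#' @param table_positions Numeric length-2: longitudinal table coordinates of
#'   the two table dosimeters, mm (the volume of interest starts at 0).
#' @param bore_position Longitudinal coordinate of the stationary bore
#'   dosimeter, mm (informational; the bore dosimeter stays in the fan).
#' @param check_separation Warn when the separation is outside 200-300 mm?
#' @return An object of class `dosimeter_layout` with a `separation` field.
#' @export
dosimeter_layout <- function(table_positions, bore_position = 0,
                             check_separation = TRUE) {
  if (!is.numeric(table_positions) || length(table_positions) != 2L ||
      any(!is.finite(table_positions)))
    stop_ct("invalid_layout", "table_positions must be two finite coordinates (mm)")
  sep <- abs(diff(table_positions))
  if (sep <= 0)
    stop_ct("invalid_layout", "table dosimeters must be at distinct positions")
  if (check_separation && (sep < 200 || sep > 300))
    warn_ct("layout_separation",
            "table dosimeter separation %.1f mm is outside the nominal 200-300 mm range",
            sep)
  structure(list(table_positions = sort(table_positions),
                 bore_position = bore_position, separation = sep),
            class = "dosimeter_layout")
}

#' @export
print.dosimeter_layout <- function(x, ...) {
  cat(sprintf("<dosimeter_layout> table dosimeters at %.1f / %.1f mm (separation %.1f mm)\n",
              x$table_positions[1], x$table_positions[2], x$separation))
  invisible(x)
}

#' Ground-truth over-ranging model
#'
#' Parametric law for the over-ranging length used by the simulator. The
#' dependence on pitch is linear (`pitch_intercept + pitch_slope * pitch`)
#' and the dependence on reconstruction slice thickness is piecewise: a
#' constant plateau up to `regime_boundary` (the thin-slice, cone-beam
#' -corrected reconstruction regime), an abrupt relative jump of
#' `jump_fraction` at the boundary, then a linear rise of
#' `linear_region_slope` through the thick-slice (z-filtering) regime whose
#' first menu entry sits 1 mm above the boundary. The two laws combine
#' multiplicatively around the reference configuration (pitch 1.0, any
#' constant-region slice thickness), where the model evaluates to
#' `pitch_intercept + pitch_slope`.
#'
#' @param pitch_intercept,pitch_slope Linear pitch law, mm and mm per unit
#'   pitch.
#' @param regime_boundary Slice thickness, mm, at which the reconstruction
#'   scheme switches.
#' @param constant_region_value Over-ranging of the thin-slice plateau at the
#'   reference pitch of 1.0, mm.
#' @param linear_region_slope Slope of the thick-slice regime, mm per mm of
#'   slice thickness.
#' @param jump_fraction Relative increase across the regime boundary.
#' @return An object of class `overrange_model`.
#' @seealso [siemens_overrange_model()] for defaults fitted to published
#'   measurements; [ground_truth_overrange()] to evaluate the law.
#' @export
overrange_model <- function(pitch_intercept, pitch_slope, regime_boundary,
                            constant_region_value, linear_region_slope,
                            jump_fraction) {
  for (nm in c("pitch_intercept", "pitch_slope", "regime_boundary",
               "constant_region_value", "linear_region_slope", "jump_fraction")) {
    if (!is_number(get(nm)))
      stop_ct("invalid_model", "'%s' must be a single finite number", nm)
  }
  if (constant_region_value <= 0)
    stop_ct("invalid_model", "constant_region_value must be > 0")
  if (linear_region_slope < 0 || jump_fraction < 0)
    stop_ct("invalid_model", "linear_region_slope and jump_fraction must be >= 0")
  structure(list(pitch_intercept = pitch_intercept, pitch_slope = pitch_slope,
                 regime_boundary = regime_boundary,
                 constant_region_value = constant_region_value,
                 linear_region_slope = linear_region_slope,
                 jump_fraction = jump_fraction),
            class = "overrange_model")
}

#' Default over-ranging models fitted to published 16-slice measurements
#'
#' Returns an [overrange_model()] whose parameters reproduce published
#' bench measurements on a 16-slice scanner:
#' * 24 mm collimation: over-ranging 43.8 mm at pitch 0.5 rising linearly to
#'   63.9 mm at pitch 1.5; slice-thickness plateau of 25.5 mm over 2-4 mm,
#'   a 77% jump between 4 and 5 mm, then a linear rise to 52.5 mm at 10 mm.
#' * 12 mm collimation: plateau of 11.1 mm over 0.75-2 mm, an 88% jump
#'   between 2 and 3 mm, then a linear rise to 29.7 mm at 10 mm; the pitch
#'   law is the 24 mm law rescaled so that the reference configuration
#'   (pitch 1.0, plateau) evaluates to the plateau value.
#'
#' @param collimation Total beam collimation, 12 or 24 mm.
#' @return An `overrange_model`.
#' @export
siemens_overrange_model <- function(collimation = 24) {
  ref24 <- 33.75 + 20.1          # pitch law at pitch 1.0 (mm)
  if (isTRUE(all.equal(collimation, 24))) {
    overrange_model(pitch_intercept = 33.75, pitch_slope = 20.1,
                    regime_boundary = 4, constant_region_value = 25.5,
                    linear_region_slope = (52.5 - 25.5 * 1.77) / (10 - 5),
                    jump_fraction = 0.77)
  } else if (isTRUE(all.equal(collimation, 12))) {
    s <- 11.1 / ref24
    overrange_model(pitch_intercept = 33.75 * s, pitch_slope = 20.1 * s,
                    regime_boundary = 2, constant_region_value = 11.1,
                    linear_region_slope = (29.7 - 11.1 * 1.88) / (10 - 3),
                    jump_fraction = 0.88)
  } else {
    stop_ct("invalid_model", "no default model for collimation %g mm (use 12 or 24)",
            collimation)
  }
}

#' Nominal table speed of a helical scan
#'
#' The standard helical relation: table travel per rotation is
#' pitch x collimation, so speed = pitch x collimation / rotation_time.
#'
#' @param protocol A [scan_protocol()].
#' @return Table speed, mm/s.
#' @examples
#' nominal_table_speed(scan_protocol(1, 0.5, 24, 5, 251))  # 48 mm/s
#' @export
nominal_table_speed <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  protocol$pitch * protocol$collimation / protocol$rotation_time
}

# Slice-thickness factor of the over-ranging law, before pitch scaling.
.thickness_law <- function(model, slice_thickness) {
  if (slice_thickness <= model$regime_boundary) {
    model$constant_region_value
  } else {
    model$constant_region_value * (1 + model$jump_fraction) +
      model$linear_region_slope * (slice_thickness - (model$regime_boundary + 1))
  }
}

#' Evaluate the ground-truth over-ranging length
#'
#' Evaluates the simulator's over-ranging law for a protocol:
#' `(pitch_intercept + pitch_slope * pitch) * f(slice) / f(plateau)` where
#' `f` is the piecewise constant-then-linear slice-thickness law. By
#' construction the result does not depend on rotation time or VOI length.
#'
#' @param model An [overrange_model()].
#' @param protocol A [scan_protocol()].
#' @return Over-ranging length, mm (strictly positive for valid protocols).
#' @export
ground_truth_overrange <- function(model, protocol) {
  stopifnot(inherits(model, "overrange_model"),
            inherits(protocol, "scan_protocol"))
  tmin <- min_slice_thickness(protocol$collimation)
  if (protocol$slice_thickness < tmin - 1e-9)
    stop_ct("domain",
            "slice thickness %g mm below the %g mm scanner minimum for %g mm collimation",
            protocol$slice_thickness, tmin, protocol$collimation)
  pitch_term <- model$pitch_intercept + model$pitch_slope * protocol$pitch
  len <- pitch_term * .thickness_law(model, protocol$slice_thickness) /
    model$constant_region_value
  if (!is.finite(len) || len <= 0)
    stop_ct("domain", "over-ranging model yields non-positive length (%g mm)", len)
  len
}
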