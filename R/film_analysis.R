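# Analysis of (synthetic) CR strip images: length-to-pixel calibration from
# fiducial markers, exposed-band length from a thresholded column profile,
# and the reconciliation arithmetic between film, console, and collimation.

#' Film length measurement
#'
#' @param band_pixels Band extent in pixels (mean over images).
#' @param mm_per_pixel Calibration factor, mm per pixel (> 0).
#' @param n_images Number of images averaged.
#' @param pixel_sd Standard deviation of the band extent across images,
#'   pixels (`NA` for a single image).
#' @return An object of class `film_measurement`; `exposed_length` is
#'   `band_pixels * mm_per_pixel`.
#' @export
film_measurement <- function(band_pixels, mm_per_pixel, n_images = 1L,
                             pixel_sd = NA_real_) {
  if (!is_number(mm_per_pixel) || mm_per_pixel <= 0)
    stop_ct("domain", "mm_per_pixel must be > 0")
  structure(list(band_pixels = band_pixels, mm_per_pixel = mm_per_pixel,
                 exposed_length = band_pixels * mm_per_pixel,
                 n_images = as.integer(n_images), pixel_sd = pixel_sd),
            class = "film_measurement")
}

#' @export
print.film_measurement <- function(x, ...) {
  cat(sprintf("<film_measurement> %.1f px%s x %.3f mm/px = %.1f mm (n = %d)\n",
              x$band_pixels,
              if (is.finite(x$pixel_sd)) sprintf(" (+/- %.1f px)", x$pixel_sd) else "",
              x$mm_per_pixel, x$exposed_length, x$n_images))
  invisible(x)
}

#' Length-to-pixel calibration from a fiducial marker pair
#'
#' @param marker_pixel_positions Two pixel coordinates of the marker
#'   centers (center-to-center).
#' @param known_separation Known physical center-to-center distance, mm.
#' @return Calibration factor, mm per pixel.
#' @examples
#' calibrate_film(c(100, 600), 200)  # 0.4 mm/px
#' @export
calibrate_film <- function(marker_pixel_positions, known_separation) {
  if (!is.numeric(marker_pixel_positions) ||
      length(marker_pixel_positions) != 2L ||
      any(!is.finite(marker_pixel_positions)))
    stop_ct("calibration", "marker_pixel_positions must be two pixel coordinates")
  d <- abs(diff(marker_pixel_positions))
  if (d == 0)
    stop_ct("calibration", "markers are coincident; cannot calibrate")
  if (!is_number(known_separation) || known_separation <= 0)
    stop_ct("calibration", "known_separation must be > 0 (mm)")
  known_separation / d
}

#' Locate fiducial markers on a CR strip
#'
#' Intensity-weighted centroids of the above-half-maximum runs in the
#' marker-lane row profile.
#'
#' @param strip A `cr_strip` (from [simulate_cr_strip()]).
#' @return Marker center positions in (sub-)pixel column coordinates,
#'   sorted.
#' @export
locate_markers <- function(strip) {
  stopifnot(inherits(strip, "cr_strip"))
  prof <- colMeans(strip$image[seq_len(strip$marker_rows), , drop = FALSE])
  thr <- 0.5 * max(prof)
  if (max(prof) <= 0) stop_ct("detection", "no markers found on the strip")
  above <- prof >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) stop_ct("detection", "no markers found on the strip")
  vapply(runs, function(k) {
    # widen to the full footprint so the centroid uses symmetric support
    i0 <- max(1L, starts[k] - 6L); i1 <- min(length(prof), ends[k] + 6L)
    idx <- i0:i1
    sum(idx * prof[idx]) / sum(prof[idx])
  }, 0)
}

.band_pixels_one <- function(image, marker_rows, threshold_fraction) {
  body <- image[-seq_len(marker_rows), , drop = FALSE]
  prof <- colMeans(body)
  if (max(prof) <= 0)
    stop_ct("detection", "no exposed band found (blank image)")
  tr <- dosimeter_trace(prof, sample_period = 1, t0 = 1, label = "film_profile")
  e <- tryCatch(detect_edges(tr, threshold_fraction),
                ctoverrange_no_signal = function(c)
                  stop_ct("detection", "no exposed band found (flat profile)"),
                ctoverrange_ambiguous_peak = function(c)
                  stop_ct("detection", "multiple exposed bands detected"))
  beam_on_duration(e)          # band extent in pixel units
}

#' Exposed-band length from CR strip image(s)
#'
#' Integrates the film body across the strip width into a longitudinal
#' column profile, takes the band extent between the
#' `threshold_fraction`-of-maximum crossings (with sub-pixel
#' interpolation), and converts to mm. Several images of the same exposure
#' may be supplied; the band extent is then averaged and its pixel standard
#' deviation reported.
#'
#' @param strips A `cr_strip`, or a list of them (repeat images of the same
#'   exposure).
#' @param mm_per_pixel Calibration factor, mm per pixel (e.g. from
#'   [calibrate_film()]); defaults to the strip's declared value.
#' @param threshold_fraction Fraction of the profile maximum defining the
#'   band edges (default 0.10).
#' @return A [film_measurement()].
#' @export
exposed_band_length <- function(strips, mm_per_pixel = NULL,
                                threshold_fraction = 0.10) {
  if (inherits(strips, "cr_strip")) strips <- list(strips)
  if (length(strips) == 0L || !all(vapply(strips, inherits, TRUE, "cr_strip")))
    stop_ct("detection", "strips must be one or more cr_strip objects")
  mm_per_pixel <- mm_per_pixel %||% strips[[1]]$mm_per_pixel
  px <- vapply(strips, function(s)
    .band_pixels_one(s$image, s$marker_rows, threshold_fraction), 0)
  film_measurement(band_pixels = mean(px), mm_per_pixel = mm_per_pixel,
                   n_images = length(px),
                   pixel_sd = if (length(px) > 1L) stats::sd(px) else NA_real_)
}

#' Reconcile film-measured exposure with a console displacement length
#'
#' @param exposed_length Film-measured exposed length, mm.
#' @param console_length Console displacement (total scan) length, mm.
#' @param collimation Total beam collimation, mm.
#' @return List with `excess` (= exposed - console, mm) and
#'   `excess_in_collimation_halves` (= excess / (collimation / 2)); a value
#'   near 1 confirms that the console convention under-reports the exposure
#'   by half a beam collimation.
#' @export
reconcile_lengths <- function(exposed_length, console_length, collimation) {
  for (nm in c("exposed_length", "console_length", "collimation")) {
    v <- get(nm)
    if (!is_number(v) || v <= 0)
      stop_ct("domain", "'%s' must be > 0 (mm)", nm)
  }
  excess <- exposed_length - console_length
  list(excess = excess,
       excess_in_collimation_halves = excess / (collimation / 2))
}

#' Write / read a CR strip image as grayscale PNG
#'
#' Convenience I/O for exchanging synthetic strips with external viewers;
#' requires the optional \pkg{png} package. Only the raster is stored -
#' calibration metadata travels separately.
#'
#' @param strip A `cr_strip`.
#' @param path File path.
#' @param mm_per_pixel,marker_rows,marker_separation Metadata to attach on
#'   read.
#' @return `write_cr_strip()` returns `path` invisibly; `read_cr_strip()`
#'   returns a `cr_strip` (without a truth record).
#' @export
write_cr_strip <- function(strip, path) {
  stopifnot(inherits(strip, "cr_strip"))
  if (!requireNamespace("png", quietly = TRUE))
    stop_ct("dependency", "PNG I/O needs the 'png' package")
  png::writePNG(strip$image, target = path)
  invisible(path)
}

#' @rdname write_cr_strip
#' @export
read_cr_strip <- function(path, mm_per_pixel, marker_rows = 12L,
                          marker_separation = NA_real_) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_ct("dependency", "PNG I/O needs the 'png' package")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  structure(list(image = img, mm_per_pixel = mm_per_pixel,
                 marker_rows = marker_rows,
                 marker_separation = marker_separation, truth = NULL),
            class = "cr_strip")
}
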