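# Threshold edge detection on dose-rate waveforms - the measurement core of
# the timing methodology. All downstream lengths are built from the 10%-of-
# peak crossing times extracted here.

#' Threshold-crossing times of a dosimeter trace
#'
#' @param t_lead,t_trail Leading/trailing crossing times, s.
#' @param threshold_level Absolute reading at which the crossings were taken.
#' @param peak_value Maximum reading of the trace.
#' @return An object of class `edge_times`.
#' @export
edge_times <- function(t_lead, t_trail, threshold_level, peak_value) {
  if (!is_number(t_lead) || !is_number(t_trail) || t_lead >= t_trail)
    stop_ct("invalid_edges", "t_lead must precede t_trail")
  structure(list(t_lead = t_lead, t_trail = t_trail,
                 threshold_level = threshold_level, peak_value = peak_value),
            class = "edge_times")
}

#' @export
print.edge_times <- function(x, ...) {
  cat(sprintf("<edge_times> %.4f -> %.4f s (duration %.4f s) at level %.4g (peak %.4g)\n",
              x$t_lead, x$t_trail, x$t_trail - x$t_lead,
              x$threshold_level, x$peak_value))
  invisible(x)
}

#' Detect the leading and trailing threshold crossings of a trace
#'
#' Finds the single contiguous run of samples at or above
#' `threshold_fraction` of the trace maximum and refines both crossing
#' times by linear interpolation between the straddling samples. If several
#' consecutive samples sit exactly at the threshold, the earliest is the
#' leading crossing and the latest the trailing one. Crossings are invariant
#' to uniform rescaling of the readings and to time translation.
#'
#' @param trace A [dosimeter_trace()].
#' @param threshold_fraction Fraction of the peak defining the crossings
#'   (default 0.10).
#' @param median_filter Apply a 3-sample median pre-filter for spike
#'   rejection? Off by default (the methodology uses raw traces).
#' @param interpolate Refine crossings by sub-sample linear interpolation
#'   (default) or report the sample-aligned times?
#' @return An [edge_times()] object.
#' @export
detect_edges <- function(trace, threshold_fraction = 0.10,
                         median_filter = FALSE, interpolate = TRUE) {
  stopifnot(inherits(trace, "dosimeter_trace"))
  if (!is_number(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    stop_ct("domain", "threshold_fraction must lie in (0, 1)")
  x <- trace$readings
  if (median_filter && length(x) >= 3L)
    x <- stats::runmed(x, 3L, endrule = "keep")
  peak <- max(x)
  if (peak <= 0 || all(abs(x - x[1]) < .Machine$double.eps * max(1, peak)))
    stop_ct("no_signal", "trace '%s' is all-zero or flat; no edges to detect",
            trace$label)
  thr <- threshold_fraction * peak
  above <- x >= thr
  r <- rle(above)
  runs <- which(r$values)
  if (length(runs) > 1L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    desc <- paste(sprintf("[%.3f, %.3f] s", trace$times[starts[runs]],
                          trace$times[ends[runs]]), collapse = ", ")
    stop_ct("ambiguous_peak",
            "%d disjoint above-threshold runs in trace '%s': %s",
            length(runs), trace$label, desc)
  }
  i <- which(above)[1]
  j <- which(above)[length(which(above))]
  tt <- trace$times
  dt <- trace$sample_period
  t_lead <- tt[i]
  t_trail <- tt[j]
  if (interpolate) {
    if (i > 1L && x[i - 1L] < thr)
      t_lead <- tt[i - 1L] + dt * (thr - x[i - 1L]) / (x[i] - x[i - 1L])
    if (j < length(x) && x[j + 1L] < thr)
      t_trail <- tt[j] + dt * (x[j] - thr) / (x[j] - x[j + 1L])
  }
  edge_times(t_lead, t_trail, thr, peak)
}

#' Beam-on duration from edge times
#'
#' @param edges An [edge_times()] object.
#' @return Duration `t_trail - t_lead`, s.
#' @export
beam_on_duration <- function(edges) {
  stopifnot(inherits(edges, "edge_times"))
  edges$t_trail - edges$t_lead
}

#' Table speed from the timing of two table-dosimeter peaks
#'
#' The table speed is the known physical separation of the two table
#' dosimeters divided by the time the table takes to carry them through the
#' beam. In `"lead"` mode only the leading-edge time difference is used; in
#' `"lead_and_trail"` mode the separation is divided by the mean of the
#' leading-edge and trailing-edge differences (the two modes agree within a
#' few percent on real traces).
#'
#' @param a,b [edge_times()] of the first and second table dosimeter (`b`
#'   must be the later one).
#' @param separation Physical separation of the table dosimeters, mm.
#' @param edge_mode `"lead"` (default) or `"lead_and_trail"`.
#' @return Table speed, mm/s.
#' @export
table_speed_from_traces <- function(a, b, separation,
                                    edge_mode = c("lead", "lead_and_trail")) {
  stopifnot(inherits(a, "edge_times"), inherits(b, "edge_times"))
  edge_mode <- match.arg(edge_mode)
  if (!is_number(separation) || separation <= 0)
    stop_ct("domain", "separation must be > 0 (mm)")
  d_lead <- b$t_lead - a$t_lead
  if (d_lead <= 0)
    stop_ct("ordering", "second trace does not lag the first (lead difference %g s)",
            d_lead)
  if (edge_mode == "lead") return(separation / d_lead)
  d_trail <- b$t_trail - a$t_trail
  if (d_trail <= 0)
    stop_ct("ordering", "second trace does not lag the first (trail difference %g s)",
            d_trail)
  separation / mean(c(d_lead, d_trail))
}
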