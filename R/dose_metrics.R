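# Clinical dose metrics. CTDIvol is always an input constant (console or
# ImPACT value); lengths are carried in mm and DLP reported in mGy.cm, so a
# factor of 10 appears in every conversion. Treating CTDIvol as uniform
# across the over-ranged region is the method's stated first approximation;
# CTDI is known to be inaccurate at scan edges.

#' Dose-length product
#'
#' @param ctdi_vol Volume CT dose index, mGy.
#' @param length Irradiated length, mm.
#' @return DLP = ctdi_vol x length / 10, mGy.cm.
#' @examples
#' dlp(13, 300)  # 390 mGy.cm
#' @export
dlp <- function(ctdi_vol, length) {
  if (!is.numeric(ctdi_vol) || !is.numeric(length) ||
      any(!is.finite(ctdi_vol)) || any(!is.finite(length)) ||
      any(ctdi_vol < 0) || any(length < 0))
    stop_ct("domain", "ctdi_vol and length must be non-negative")
  ctdi_vol * length / 10
}

#' Dose report for a scan with over-ranging
#'
#' Splits the DLP of a scan into its VOI and over-ranging parts and reports
#' the extra-dose fraction (over-ranging DLP relative to the VOI DLP).
#'
#' @param ctdi_vol CTDIvol, mGy.
#' @param voi_length VOI length, mm (> 0).
#' @param overrange_length Over-ranging length, mm.
#' @return An object of class `dose_report`: `voi_dlp`, `overrange_dlp`,
#'   `total_dlp` (= the sum), `extra_fraction`
#'   (= overrange_dlp / voi_dlp, invariant to CTDIvol).
#' @examples
#' dose_report(20, 300, 30)  # 60 mGy.cm of over-ranging, 10% extra dose
#' @export
dose_report <- function(ctdi_vol, voi_length, overrange_length) {
  if (!is_number(voi_length) || voi_length <= 0)
    stop_ct("domain",
            "voi_length must be > 0 (extra_fraction undefined otherwise)")
  voi_dlp <- dlp(ctdi_vol, voi_length)
  over_dlp <- dlp(ctdi_vol, overrange_length)
  structure(list(voi_dlp = voi_dlp, overrange_dlp = over_dlp,
                 total_dlp = voi_dlp + over_dlp,
                 extra_fraction = overrange_length / voi_length),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf(
    "<dose_report> VOI %.1f + over-ranging %.1f = %.1f mGy.cm (%.1f%% extra dose)\n",
    x$voi_dlp, x$overrange_dlp, x$total_dlp, 100 * x$extra_fraction))
  invisible(x)
}
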