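# File formats and the sweep driver. Traces travel as 2-column delimited
# text with a '#' metadata header; configurations as YAML or JSON; sweep
# results as CSV. All randomness of a sweep flows from the single config
# seed, so identical configs produce identical outputs.

#' Write / read a dosimeter trace as delimited text
#'
#' The format is tab-separated `time_s`, `reading` preceded by `#` header
#' lines carrying `label` and `sample_period`. Reading validates uniform
#' sampling and reports the first offending row on a gap; if the header
#' period disagrees with the data, the data-derived period is used with a
#' warning.
#'
#' @param trace A [dosimeter_trace()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   a [dosimeter_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dosimeter_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label: %s", trace$label),
               sprintf("# sample_period: %.10g", trace$sample_period),
               "time_s\treading"), con)
  utils::write.table(data.frame(time_s = trace$times,
                                reading = trace$readings),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    meta[[key]] <- trimws(sub("^[^:]*:\\s*", "", kv))
  }
  df <- utils::read.table(text = lines, comment.char = "#", header = TRUE,
                          sep = "\t")
  if (!all(c("time_s", "reading") %in% names(df)) || nrow(df) < 2L)
    stop_ct("format", "'%s' is not a two-column (time_s, reading) trace file",
            path)
  dts <- diff(df$time_s)
  dt <- stats::median(dts)
  bad <- which(abs(dts - dt) > 1e-6 * max(dt, 1e-12))
  if (length(bad) > 0L)
    stop_ct("format",
            "non-uniform sampling in '%s': first gap after data row %d (dt %.6g s vs %.6g s)",
            path, bad[1], dts[bad[1]], dt)
  if (!is.null(meta$sample_period)) {
    hp <- as.numeric(meta$sample_period)
    if (is.finite(hp) && abs(hp - dt) > 1e-6 * max(dt, 1e-12))
      warn_ct("period_mismatch",
              "header sample_period (%g s) disagrees with the data (%g s); using the data-derived period",
              hp, dt)
  }
  dosimeter_trace(df$reading, sample_period = dt, t0 = df$time_s[1],
                  label = meta$label %||% "trace")
}

#' Sweep configuration
#'
#' @param protocol Named list of protocol defaults (everything
#'   [scan_protocol()] takes except the swept parameters); must include
#'   `collimation` and may include `ctdi_vol`, `kvp`, `mas`.
#' @param sweep Named list of non-empty parameter vectors: `pitch`,
#'   `slice_thickness`, `rotation_time`, `voi_length`. Single values are
#'   allowed; every combination is simulated.
#' @param seed Base seed; the scan for combination `i` uses `seed + i`.
#' @param noise_sd Relative per-sample noise of the simulated traces.
#' @param threshold_fraction,edge_mode,convention Estimation settings,
#'   recorded in the audit trail of every output.
#' @param budget_overrides Named list overriding [uncertainty_budget()]
#'   defaults (`console_precision`, `timing_resolution`,
#'   `scintillator_diameter`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(protocol, sweep, seed = 1L, noise_sd = 0.01,
                       threshold_fraction = 0.10,
                       edge_mode = c("lead", "lead_and_trail"),
                       convention = c("exposure", "translation"),
                       budget_overrides = list()) {
  edge_mode <- match.arg(edge_mode)
  convention <- match.arg(convention)
  need <- c("pitch", "slice_thickness", "rotation_time", "voi_length")
  if (!is.list(sweep) || !all(need %in% names(sweep)))
    stop_ct("config", "sweep must name: %s", paste(need, collapse = ", "))
  for (nm in need)
    if (length(sweep[[nm]]) == 0L)
      stop_ct("config", "sweep list '%s' is empty", nm)
  if (is.null(protocol$collimation))
    stop_ct("config", "protocol defaults must include 'collimation'")
  structure(list(protocol = protocol, sweep = sweep[need],
                 seed = as.integer(seed), noise_sd = noise_sd,
                 threshold_fraction = threshold_fraction,
                 edge_mode = edge_mode, convention = convention,
                 budget_overrides = budget_overrides),
            class = "run_config")
}

#' Read a sweep configuration from YAML or JSON
#'
#' Flat sections `protocol`, `sweep`, plus optional top-level `seed`,
#' `noise_sd`, `threshold_fraction`, `edge_mode`, `convention`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw) || is.null(raw$protocol) || is.null(raw$sweep))
    stop_ct("config", "'%s' must contain 'protocol' and 'sweep' sections", path)
  run_config(protocol = raw$protocol, sweep = raw$sweep,
             seed = raw$seed %||% 1L, noise_sd = raw$noise_sd %||% 0.01,
             threshold_fraction = raw$threshold_fraction %||% 0.10,
             edge_mode = raw$edge_mode %||% "lead",
             convention = raw$convention %||% "exposure")
}

#' Run a protocol-parameter sweep
#'
#' Simulates one scan per combination of the swept parameters, estimates
#' the over-ranging with the direct method, and attaches the dose metrics.
#' Combinations whose slice thickness is below the scanner minimum for the
#' collimation are skipped with a warning. Per-VOI linear fits of estimated
#' length versus pitch and an overall fit of measured speed versus pitch
#' are appended when at least three distinct pitches are swept.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, `results.csv`,
#'   `fits.csv` and `config.json` are written there.
#' @return A list of class `sweep_result`: `results` (data frame, one row
#'   per combination), `fits` (data frame of per-VOI length-vs-pitch and
#'   speed-vs-pitch regressions, or `NULL`), and `audit` (threshold, edge
#'   mode, convention, seed).
#' @export
run_sweep <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  grid <- expand.grid(pitch = config$sweep$pitch,
                      slice_thickness = config$sweep$slice_thickness,
                      rotation_time = config$sweep$rotation_time,
                      voi_length = config$sweep$voi_length,
                      KEEP.OUT.ATTRS = FALSE)
  pd <- config$protocol
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$slice_thickness < min_slice_thickness(pd$collimation) - 1e-9) {
      warn_ct("skipped_combination",
              "skipping pitch %.2f / slice %g mm: below the scanner minimum for %g mm collimation",
              g$pitch, g$slice_thickness, pd$collimation)
      next
    }
    seed_i <- (config$seed + i) %% 2147483647L
    p <- scan_protocol(g$pitch, g$rotation_time, pd$collimation,
                       g$slice_thickness, g$voi_length,
                       ctdi_vol = pd$ctdi_vol %||% 13,
                       kvp = pd$kvp %||% 120, mas = pd$mas %||% 140,
                       strict = isTRUE(pd$strict %||% TRUE))
    lay <- dosimeter_layout(c(0.1, 0.9) * g$voi_length,
                            check_separation = FALSE)
    sim <- simulate_scan(simulation_spec(p, layout = lay,
                                         noise_sd = config$noise_sd,
                                         seed = seed_i))
    est <- direct_overrange(sim$bore, sim$table_1, sim$table_2, lay,
                            voi_length = g$voi_length,
                            collimation = pd$collimation,
                            convention = config$convention,
                            threshold_fraction = config$threshold_fraction,
                            edge_mode = config$edge_mode, pitch = g$pitch)
    dr <- dose_report(p$ctdi_vol, g$voi_length, est$length)
    rows[[i]] <- data.frame(
      pitch = g$pitch, slice_thickness = g$slice_thickness,
      rotation_time = g$rotation_time, voi_length = g$voi_length,
      seed = seed_i, length_mm = est$length,
      truth_length_mm = sim$truth$overrange_length,
      table_speed = est$table_speed,
      beam_on_s = est$beam_on_duration, uncertainty_mm = est$uncertainty,
      voi_dlp = dr$voi_dlp, overrange_dlp = dr$overrange_dlp,
      total_dlp = dr$total_dlp, extra_fraction = dr$extra_fraction)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res) || nrow(res) == 0L)
    stop_ct("config", "no valid sweep combinations")

  fits <- NULL
  if (length(unique(res$pitch)) >= 3L) {
    per_voi <- lapply(split(res, res$voi_length), function(d) {
      f <- stats::lm(length_mm ~ pitch, data = d)
      data.frame(fit = "length_vs_pitch", voi_length = d$voi_length[1],
                 intercept = unname(stats::coef(f)[1]),
                 slope = unname(stats::coef(f)[2]),
                 r_squared = summary(f)$r.squared)
    })
    fv <- stats::lm(table_speed ~ pitch, data = res)
    fits <- rbind(do.call(rbind, per_voi),
                  data.frame(fit = "speed_vs_pitch", voi_length = NA,
                             intercept = unname(stats::coef(fv)[1]),
                             slope = unname(stats::coef(fv)[2]),
                             r_squared = summary(fv)$r.squared))
    rownames(fits) <- NULL
  }
  audit <- list(threshold_fraction = config$threshold_fraction,
                edge_mode = config$edge_mode,
                convention = config$convention, seed = config$seed)
  out <- structure(list(results = res, fits = fits, audit = audit),
                   class = "sweep_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(fits))
      utils::write.csv(fits, file.path(out_dir, "fits.csv"),
                       row.names = FALSE)
    jsonlite::write_json(c(config[c("protocol", "sweep", "noise_sd",
                                    "threshold_fraction", "edge_mode",
                                    "convention")],
                           list(seed = config$seed)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d scans; over-ranging %.1f-%.1f mm\n",
              nrow(x$results), min(x$results$length_mm),
              max(x$results$length_mm)))
  if (!is.null(x$fits)) {
    v <- x$fits[x$fits$fit == "speed_vs_pitch", ]
    cat(sprintf("  speed vs pitch: R^2 = %.4f\n", v$r_squared))
  }
  invisible(x)
}

#' Serialize an over-ranging result (plus optional dose report) to JSON
#'
#' @param result An [overrange_result()].
#' @param path File path for the JSON report.
#' @param dose Optional [dose_report()] to embed.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, dose = NULL) {
  stopifnot(inherits(result, "overrange_result"))
  payload <- unclass(result)
  if (!is.null(dose)) payload$dose <- unclass(dose)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
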