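#' Read a pupil trace table
#'
#' Parses the trace-table dialect used for the per-participant pupil
#' curves: a comma-separated file whose first column is
#' `timeRelativeToPulseOnset` (seconds, negative = before onset) and whose
#' remaining columns each hold one participant's normalized pupil diameter
#' (% of baseline); `NA` marks missing data, and an all-NA column means
#' that participant did not contribute this stimulus.
#'
#' @param path CSV file path.
#' @return List of class `trace_table`: `time`, `pupil` (matrix, one
#'   column per contributing participant), `contributors`,
#'   `non_contributors`.
#' @export
read_trace_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"timeRelativeToPulseOnset" %in% names(df))
    stop("missing 'timeRelativeToPulseOnset' column in ", path)
  tm <- as.numeric(df$timeRelativeToPulseOnset)
  if (any(diff(tm) <= 0)) stop("time column must be strictly increasing")
  part <- df[setdiff(names(df), "timeRelativeToPulseOnset")]
  part <- as.matrix(data.matrix(part))
  all_na <- apply(part, 2, function(x) all(is.na(x)))
  if (all(all_na)) stop("no contributing participant column in ", path)
  structure(list(time = tm,
                 pupil = part[, !all_na, drop = FALSE],
                 contributors = colnames(part)[!all_na],
                 non_contributors = colnames(part)[all_na]),
            class = "trace_table")
}

#' @export
print.trace_table <- function(x, ...) {
  cat(sprintf("<trace_table: %d time points, %d contributors (%d NA)>\n",
              length(x$time), length(x$contributors),
              length(x$non_contributors)))
  invisible(x)
}

#' Extract one participant's trace from a trace table
#'
#' @param tab A [trace_table].
#' @param id Participant column name.
#' @param pulse_duration Pulse duration (s).
#' @return A `clean_trial`-like list (`time`, `pupil`, `pulse_duration`).
#' @export
trace_from_table <- function(tab, id, pulse_duration = 3) {
  stopifnot(inherits(tab, "trace_table"))
  if (!id %in% colnames(tab$pupil)) stop("unknown participant: ", id)
  structure(list(time = tab$time, pupil = tab$pupil[, id],
                 baseline_mm = NA_real_, mask_fraction = NA_real_,
                 pulse_duration = pulse_duration),
            class = "clean_trial")
}

#' Read a stimulus radiance table
#'
#' Parses the mean-stimulus-radiance dialect: columns `wavelength` (nm)
#' plus `MelPulse`, `MelBg`, `LMSPulse`, `LMSBg`, `red`, `blue`, each a
#' spectral radiance in W m^-2 sr^-1 nm^-1. Column order is irrelevant;
#' extra columns are ignored.
#'
#' @param path CSV file path.
#' @return Named list of [spectrum] objects (one per stimulus column).
#' @export
read_radiance_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength" %in% names(df)) stop("missing 'wavelength' column")
  wl <- as.numeric(df$wavelength)
  if (any(wl < 0)) stop("negative wavelengths")
  wanted <- c("MelPulse", "MelBg", "LMSPulse", "LMSBg", "red", "blue")
  missing <- setdiff(wanted, names(df))
  if (length(missing) > 0)
    stop("missing radiance columns: ", paste(missing, collapse = ", "))
  stats::setNames(lapply(wanted, function(cn)
    spectrum(wl, as.numeric(df[[cn]]))), wanted)
}

#' Write a device calibration as a long-format CSV
#'
#' Columns `primary, level, wavelength, radiance`, one row per measured
#' sample; the inverse of [read_calibration_table()].
#'
#' @param cal A [device_calibration].
#' @param path Output path.
#' @export
write_calibration_table <- function(cal, path) {
  stopifnot(inherits(cal, "device_calibration"))
  rows <- list()
  for (i in seq_along(cal$primaries)) {
    p <- cal$primaries[[i]]
    for (k in seq_along(p$levels)) {
      rows[[length(rows) + 1L]] <- data.frame(
        primary = i, level = p$levels[k], wavelength = cal$wavelength,
        radiance = p$spectra[k, ])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format device calibration CSV
#'
#' @param path CSV with columns `primary, level, wavelength, radiance`.
#' @return A [device_calibration].
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("primary", "level", "wavelength", "radiance")
  if (!all(need %in% names(df)))
    stop("calibration CSV needs columns: ", paste(need, collapse = ", "))
  wl <- sort(unique(df$wavelength))
  prim_ids <- sort(unique(df$primary))
  primaries <- lapply(prim_ids, function(pid) {
    sub <- df[df$primary == pid, ]
    levels <- sort(unique(sub$level))
    spectra <- t(vapply(levels, function(l) {
      s <- sub[sub$level == l, ]
      s <- s[order(s$wavelength), ]
      if (!isTRUE(all.equal(s$wavelength, wl)))
        stop("inconsistent wavelength grid for primary ", pid)
      s$radiance
    }, numeric(length(wl))))
    list(levels = levels, spectra = spectra)
  })
  device_calibration(wl, primaries)
}

#' Analysis configuration defaults
#'
#' Every tunable constant of the pipeline in one validated object: pulse
#' duration 3 s, PIPR read-out 6 s post offset with a 0-12 s search window
#' for the maximal group difference, 1 s baseline window, third-order 4 Hz
#' Butterworth smoothing at 120 Hz, masking at 3 derivative SDs or
#' confidence below 0.95, 6% silencing tolerance, Bonferroni family of 4,
#' and a 25% masked-fraction trial-exclusion threshold.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(pulse_duration = 3, pipr_t_post_offset = 6,
              pipr_search_window = c(0, 12), baseline_window = 1,
              filter_order = 3, filter_cutoff_hz = 4, fs = 120,
              mask_sd_mult = 3, mask_conf_min = 0.95,
              silencing_tolerance = 6, bonferroni_family = 4,
              exclude_threshold = 0.25, seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  num <- c("pulse_duration", "pipr_t_post_offset", "baseline_window",
           "filter_order", "filter_cutoff_hz", "fs", "mask_sd_mult",
           "mask_conf_min", "silencing_tolerance", "bonferroni_family",
           "exclude_threshold")
  for (k in num) if (!is.numeric(cfg[[k]]) || any(cfg[[k]] <= 0))
    stop("config key '", k, "' must be positive")
  structure(cfg, class = "analysis_config")
}
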