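#' Raw pupil recording
#'
#' A single trial's raw pupillometer output: time (s, nominally 120 Hz),
#' pupil diameter (mm) and per-sample tracking confidence in `[0, 1]`, plus
#' the trial annotations (pulse onset time and pulse duration).
#'
#' @param time Numeric, strictly increasing (s).
#' @param diameter Numeric, mm.
#' @param confidence Numeric in `[0, 1]`.
#' @param onset Pulse onset time (s, same clock as `time`).
#' @param pulse_duration Pulse duration (s, default 3).
#' @param fs Nominal sampling rate (Hz, default 120).
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(time, diameter, confidence, onset,
                          pulse_duration = 3, fs = 120) {
  n <- length(time)
  if (length(diameter) != n || length(confidence) != n)
    stop("time, diameter and confidence must have equal length")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop("confidence must lie in [0, 1]")
  structure(list(time = time, diameter = diameter, confidence = confidence,
                 onset = onset, pulse_duration = pulse_duration, fs = fs),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording: %d samples, %.1f-%.1f s, onset %.2f s>\n",
              length(x$time), min(x$time), max(x$time), x$onset))
  invisible(x)
}

#' Artifact mask for a raw recording
#'
#' A sample is masked if the first derivative of pupil diameter (first
#' difference over the sampling interval, attributed to the later sample of
#' each pair) falls outside mean +/- `sd_mult` standard deviations of that
#' trial's derivative distribution, or if tracking confidence is below
#' `conf_min`.
#'
#' @param raw A [raw_recording].
#' @param sd_mult Derivative threshold in SD units (default 3).
#' @param conf_min Minimum acceptable confidence (default 0.95).
#' @return Logical vector, TRUE = masked.
#' @export
mask_samples <- function(raw, sd_mult = 3, conf_min = 0.95) {
  stopifnot(inherits(raw, "raw_recording"))
  n <- length(raw$time)
  if (n < 3L) stop("need at least 3 samples to estimate the derivative SD")
  deriv <- diff(raw$diameter) / diff(raw$time)
  mu <- mean(deriv); s <- stats::sd(deriv)
  deriv_bad <- if (s > 0) abs(deriv - mu) > sd_mult * s else rep(FALSE, n - 1L)
  mask <- raw$confidence < conf_min
  mask[-1L] <- mask[-1L] | deriv_bad
  mask
}

#' Reconstruct masked samples by linear interpolation
#'
#' Interior masked runs are replaced by linear interpolation between the
#' flanking unmasked samples; masked runs touching either end of the trace
#' take the nearest unmasked value (two-sided interpolation is impossible
#' there).
#'
#' @param raw A [raw_recording] (or list with `time` and `diameter`).
#' @param mask Logical vector from [mask_samples()].
#' @return Numeric diameter series with masked samples reconstructed.
#' @export
interpolate_masked <- function(raw, mask) {
  d <- raw$diameter
  if (!any(mask)) return(d)
  if (sum(!mask) < 2L)
    stop("fewer than 2 unmasked samples; trial cannot be reconstructed")
  stats::approx(raw$time[!mask], d[!mask], xout = raw$time,
                method = "linear", rule = 2)$y
}

#' Low-pass smooth a uniformly sampled series
#'
#' Third-order Butterworth low-pass at `cutoff` Hz applied zero-phase
#' (forward-backward, so the effective amplitude response is the squared
#' one-pass magnitude and no group delay is introduced into latency
#' metrics). DC gain is 1.
#'
#' @param x Numeric series sampled uniformly at `fs`.
#' @param fs Sampling rate (Hz, default 120).
#' @param cutoff Cutoff frequency (Hz, default 4).
#' @param order Filter order (default 3).
#' @return Smoothed numeric series, same length.
#' @export
smooth_series <- function(x, fs = 120, cutoff = 4, order = 3) {
  if (any(!is.finite(x))) stop("series must be finite before smoothing")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(x)
  # odd-reflection padding lets the forward and backward passes settle
  # before they reach real data, eliminating edge transients
  npad <- ceiling(10 * fs / cutoff)
  if (n < npad / 6)
    stop("series too short for zero-phase filtering")
  npad <- min(npad, n - 1)
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(npad + 1):(npad + n)]
}

#' Normalize a trial to its pre-stimulus baseline
#'
#' Baseline is the mean diameter within the 1 s window immediately before
#' pulse onset; the trace is expressed as a percentage of that baseline
#' (100 = baseline diameter) on a time axis relative to pulse onset.
#'
#' @param time Time vector (s, recording clock).
#' @param diameter Diameter series (mm), same length.
#' @param onset Pulse onset time (s).
#' @param baseline_window Length of the pre-onset baseline window (s,
#'   default 1).
#' @param mask_fraction Fraction of samples that were interpolated
#'   (bookkeeping; default NA).
#' @param pulse_duration Pulse duration (s, default 3).
#' @return Object of class `clean_trial`: `time` (s relative to onset),
#'   `pupil` (% of baseline), `baseline_mm`, `mask_fraction`,
#'   `pulse_duration`.
#' @export
normalize_to_baseline <- function(time, diameter, onset,
                                  baseline_window = 1, mask_fraction = NA,
                                  pulse_duration = 3) {
  in_bl <- time >= onset - baseline_window & time < onset
  if (sum(in_bl) == 0 ||
      (max(time[in_bl]) - min(time[in_bl])) < baseline_window / 2)
    stop("insufficient data in the baseline window")
  bl <- mean(diameter[in_bl])
  if (!is.finite(bl) || bl <= 0) stop("non-positive baseline diameter")
  structure(list(time = time - onset, pupil = 100 * diameter / bl,
                 baseline_mm = bl, mask_fraction = mask_fraction,
                 pulse_duration = pulse_duration),
            class = "clean_trial")
}

#' @export
print.clean_trial <- function(x, ...) {
  cat(sprintf(
    "<clean_trial: %.1f-%.1f s rel. onset, baseline %.2f mm, masked %.1f%%>\n",
    min(x$time), max(x$time), x$baseline_mm,
    100 * (x$mask_fraction %||% NA)))
  invisible(x)
}

#' Full preprocessing pipeline for one trial
#'
#' Mask artifacts, reconstruct masked samples by linear interpolation,
#' resample to a uniform grid at `fs` if timestamps are jittered, smooth
#' with the zero-phase Butterworth filter, and normalize to the pre-onset
#' baseline -- in that order. Trials with more than `exclude_threshold`
#' masked samples, or that cannot be reconstructed or baselined, are
#' rejected with a reason code.
#'
#' @param raw A [raw_recording].
#' @param sd_mult,conf_min Masking thresholds (see [mask_samples()]).
#' @param cutoff,order Smoothing parameters (see [smooth_series()]).
#' @param baseline_window Baseline window length (s).
#' @param exclude_threshold Maximum tolerated masked fraction (default 0.25).
#' @return A `clean_trial`, or an object of class `excluded_trial` with a
#'   `reason` field.
#' @export
preprocess_trial <- function(raw, sd_mult = 3, conf_min = 0.95,
                             cutoff = 4, order = 3, baseline_window = 1,
                             exclude_threshold = 0.25) {
  stopifnot(inherits(raw, "raw_recording"))
  mask <- mask_samples(raw, sd_mult = sd_mult, conf_min = conf_min)
  frac <- mean(mask)
  if (frac > exclude_threshold)
    return(excluded_trial("masked_fraction_exceeds_threshold", frac))
  if (sum(!mask) < 2L)
    return(excluded_trial("too_few_unmasked_samples", frac))
  d <- interpolate_masked(raw, mask)
  # uniform resampling guards against timestamp jitter before filtering
  tu <- seq(raw$time[1], raw$time[length(raw$time)], by = 1 / raw$fs)
  du <- stats::approx(raw$time, d, xout = tu, rule = 2)$y
  ds <- tryCatch(smooth_series(du, fs = raw$fs, cutoff = cutoff,
                               order = order),
                 error = function(e) NULL)
  if (is.null(ds)) return(excluded_trial("trace_too_short_for_filter", frac))
  tryCatch(
    normalize_to_baseline(tu, ds, raw$onset,
                          baseline_window = baseline_window,
                          mask_fraction = frac,
                          pulse_duration = raw$pulse_duration),
    error = function(e) excluded_trial("baseline_failure", frac))
}

excluded_trial <- function(reason, mask_fraction = NA) {
  structure(list(reason = reason, mask_fraction = mask_fraction),
            class = "excluded_trial")
}

#' @export
print.excluded_trial <- function(x, ...) {
  cat("<excluded_trial:", x$reason, ">\n")
  invisible(x)
}
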