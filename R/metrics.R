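#' Pupil-response metrics from a clean trial
#'
#' Extracts the four response parameters from a baseline-normalized,
#' onset-aligned pupil trace:
#'
#' * `time_to_max_constriction_ms` (a): time from pulse onset to the minimum
#'   normalized diameter within the pulse-on period, in ms (earliest sample
#'   among ties).
#' * `diameter_at_max_constriction_pct` (b): that minimum, % of baseline.
#' * `redilation_rate_pct_s` (c): slope of a least-squares linear fit to the
#'   trace between the within-pulse minimum and pulse offset, % per second;
#'   positive = redilating. Undefined (NA) when the minimum falls at pulse
#'   offset.
#' * `diameter_6s_post_offset_pct` (d): normalized diameter 6 s after pulse
#'   offset (9 s after onset for a 3 s pulse), linearly interpolated between
#'   the neighbouring samples.
#'
#' @param trial A [clean_trial] (or list with `time` relative to onset and
#'   `pupil` in % baseline).
#' @param pulse_duration Pulse duration (s, default 3).
#' @param t_post_offset Time after pulse offset at which parameter (d) is
#'   read (s, default 6).
#' @return Named list of class `response_metrics`.
#' @export
extract_metrics <- function(trial, pulse_duration = 3, t_post_offset = 6) {
  t <- trial$time; y <- trial$pupil
  t_d <- pulse_duration + t_post_offset
  if (min(t) > 0 || max(t) < t_d)
    stop("trace must cover [0, pulse_duration + t_post_offset] s post onset")
  in_pulse <- t > 0 & t <= pulse_duration
  if (!any(in_pulse)) stop("no samples within the pulse-on period")
  tp <- t[in_pulse]; yp <- y[in_pulse]
  i_min <- which.min(yp)            # which.min takes the earliest tie
  a_s <- tp[i_min]
  b <- yp[i_min]
  redil <- tp >= a_s
  c_rate <- if (sum(redil) >= 2 && a_s < pulse_duration)
    unname(stats::coef(stats::lm(yp[redil] ~ tp[redil]))[2])
  else NA_real_
  d <- trace_value_at(t, y, t_d)
  structure(list(time_to_max_constriction_ms = 1000 * a_s,
                 diameter_at_max_constriction_pct = b,
                 redilation_rate_pct_s = c_rate,
                 diameter_6s_post_offset_pct = d),
            class = "response_metrics")
}

#' @export
print.response_metrics <- function(x, ...) {
  cat(sprintf(paste0("<response_metrics: a=%.0f ms, b=%.1f%%, ",
                     "c=%.2f %%/s, d=%.1f%%>\n"),
              x$time_to_max_constriction_ms,
              x$diameter_at_max_constriction_pct,
              x$redilation_rate_pct_s, x$diameter_6s_post_offset_pct))
  invisible(x)
}

# Value of a trace at an arbitrary time, linear between neighbouring samples.
trace_value_at <- function(time, pupil, at, mode = c("interpolate",
                                                     "nearest")) {
  mode <- match.arg(mode)
  if (at < min(time) || at > max(time)) return(NA_real_)
  if (mode == "interpolate")
    stats::approx(time, pupil, xout = at, method = "linear")$y
  else pupil[which.min(abs(time - at))]
}

#' Labels of the four response parameters
#' @return Character vector naming the metric fields in a/b/c/d order.
#' @export
metric_names <- function() c("time_to_max_constriction_ms",
                             "diameter_at_max_constriction_pct",
                             "redilation_rate_pct_s",
                             "diameter_6s_post_offset_pct")

#' Per-participant mean trace across trials
#'
#' Pointwise NA-aware arithmetic mean of several clean trials sharing a
#' common time grid.
#'
#' @param trials List of [clean_trial] objects (excluded trials are
#'   dropped).
#' @return A `clean_trial`-like object whose `pupil` is the mean trace, or
#'   NULL if no trial is usable.
#' @export
participant_mean_trace <- function(trials) {
  trials <- Filter(function(x) inherits(x, "clean_trial"), trials)
  if (length(trials) == 0L) return(NULL)
  tg <- trials[[1]]$time
  for (tr in trials)
    if (length(tr$time) != length(tg) || max(abs(tr$time - tg)) > 1e-9)
      stop("trials must share a common time grid")
  mat <- vapply(trials, function(tr) tr$pupil, numeric(length(tg)))
  structure(list(time = tg,
                 pupil = rowMeans(as.matrix(mat), na.rm = TRUE),
                 baseline_mm = mean(vapply(trials, `[[`, numeric(1),
                                           "baseline_mm")),
                 mask_fraction = mean(vapply(trials, function(tr)
                   tr$mask_fraction %||% NA_real_, numeric(1))),
                 pulse_duration = trials[[1]]$pulse_duration,
                 n_trials = length(trials)),
            class = "clean_trial")
}

#' Post-illumination pupil response (PIPR)
#'
#' PIPR = red-minus-blue normalized pupil diameter at a stated time after
#' pulse offset, in percentage points. Antisymmetric under swapping the two
#' traces.
#'
#' @param red,blue Traces (lists with `time` relative to onset and `pupil`
#'   in % baseline).
#' @param t_post_offset Time after pulse offset (s, default 6).
#' @param pulse_duration Pulse duration (s, default 3).
#' @return Scalar PIPR in percentage points (NA if either trace is
#'   undefined at the requested time).
#' @export
compute_pipr <- function(red, blue, t_post_offset = 6, pulse_duration = 3) {
  at <- pulse_duration + t_post_offset
  r <- trace_value_at(red$time, red$pupil, at)
  b <- trace_value_at(blue$time, blue$pupil, at)
  r - b
}

#' Group mean curve from per-participant traces
#'
#' @param traces Named list of per-participant traces on a common grid.
#' @param label Group label.
#' @return Object of class `group_curve`: `time`, `participants` (matrix,
#'   one column per participant), `mean` (NA-aware), `label`.
#' @export
group_curve <- function(traces, label = "") {
  traces <- Filter(Negate(is.null), traces)
  if (length(traces) == 0L) stop("no traces supplied")
  tg <- traces[[1]]$time
  mat <- vapply(traces, function(tr) tr$pupil, numeric(length(tg)))
  mat <- as.matrix(mat)
  structure(list(time = tg, participants = mat,
                 mean = rowMeans(mat, na.rm = TRUE), label = label),
            class = "group_curve")
}

#' Timepoint of maximal group difference
#'
#' Finds the time (reported in seconds after pulse offset) at which the
#' difference `curve_a$mean - curve_b$mean` is largest within a post-offset
#' search window; ties resolve to the earliest time.
#'
#' @param curve_a,curve_b [group_curve] objects on a common grid (e.g.,
#'   control and glaucoma PIPR curves).
#' @param window Post-offset search window (s after pulse offset), default
#'   `c(0, 12)`.
#' @param pulse_duration Pulse duration (s, default 3).
#' @return Time of maximal difference, s after pulse offset.
#' @export
max_group_difference_time <- function(curve_a, curve_b, window = c(0, 12),
                                      pulse_duration = 3) {
  if (length(curve_a$time) != length(curve_b$time) ||
      max(abs(curve_a$time - curve_b$time)) > 1e-9)
    stop("curves must share a common time grid")
  t_off <- curve_a$time - pulse_duration
  in_win <- t_off >= window[1] & t_off <= window[2]
  if (!any(in_win)) stop("search window contains no samples")
  diff_ab <- (curve_a$mean - curve_b$mean)[in_win]
  t_off[in_win][which.max(diff_ab)]
}
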