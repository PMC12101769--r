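#' Parametric pupil-response model parameters
#'
#' The generator's ground-truth normalized response `g(t)` (t in seconds
#' relative to pulse onset, value in % of baseline) is the simplest
#' piecewise-smooth curve exhibiting every feature the response metrics
#' measure:
#'
#' * `g(t) = 100` before the response latency;
#' * exponential constriction `100 - A * (1 - exp(-(t - latency) / tau_c))`
#'   until the within-pulse minimum, reached when the exponential is 95%
#'   saturated (at `latency + 3 * tau_c`);
#' * linear redilation at `redilation_rate` %/s from the minimum to pulse
#'   offset;
#' * post-offset exponential recovery toward `100 - sustained` with time
#'   constant `tau_r` (large `tau_r` / large `sustained` encode the
#'   sustained constriction characteristic of melanopsin-weighted and blue
#'   stimuli).
#'
#' @param baseline_mm Baseline pupil diameter (mm).
#' @param latency_s Response latency (s).
#' @param amplitude_pct Constriction amplitude A (% of baseline).
#' @param tau_constrict_s Constriction time constant (s).
#' @param redilation_rate_pct_s Within-pulse redilation rate (%/s).
#' @param tau_recover_s Post-offset recovery time constant (s).
#' @param sustained_pct Sustained post-offset constriction (% below
#'   baseline) that the recovery asymptotes to.
#' @param noise_sd_mm Gaussian measurement noise SD (mm).
#' @param blink_rate_hz Poisson blink rate (events per second).
#' @param blink_duration_s Blink duration (s).
#' @param blink_confidence Tracking confidence reported during blinks.
#' @return List of class `pupil_model_params`.
#' @export
pupil_model_params <- function(baseline_mm = 5, latency_s = 0.25,
                               amplitude_pct = 17, tau_constrict_s = 0.25,
                               redilation_rate_pct_s = 3.2,
                               tau_recover_s = 2, sustained_pct = 2,
                               noise_sd_mm = 0.05, blink_rate_hz = 0.1,
                               blink_duration_s = 0.15,
                               blink_confidence = 0) {
  stopifnot(baseline_mm > 0, amplitude_pct >= 0, amplitude_pct < 100,
            tau_constrict_s > 0, tau_recover_s > 0)
  structure(as.list(environment()), class = "pupil_model_params")
}

#' Default model parameters per stimulus condition
#'
#' Condition-specific defaults calibrated (on the noiseless analytic curve)
#' so that group means land on the response values typical of each stimulus
#' class: matched-contrast melanopsin- and LMS-directed pairs differ mainly
#' in the sustained post-offset constriction (about 2 percentage points at
#' 6 s post offset), and the dark-adapted narrowband blue stimulus shows a
#' large sustained constriction relative to red (PIPR about 13 percentage
#' points in healthy eyes).
#'
#' @param condition One of `"melanopsin"`, `"lms"`, `"red"`, `"blue"`.
#' @return A [pupil_model_params].
#' @export
default_pupil_params <- function(condition = c("melanopsin", "lms",
                                               "red", "blue")) {
  condition <- match.arg(condition)
  switch(condition,
    melanopsin = pupil_model_params(baseline_mm = 5, amplitude_pct = 17.0,
                                    redilation_rate_pct_s = 3.2,
                                    tau_recover_s = 2, sustained_pct = 2.07),
    lms = pupil_model_params(baseline_mm = 5, amplitude_pct = 16.3,
                             redilation_rate_pct_s = 3.3,
                             tau_recover_s = 1.5, sustained_pct = 0.34),
    red = pupil_model_params(baseline_mm = 7, amplitude_pct = 22,
                             redilation_rate_pct_s = 4,
                             tau_recover_s = 1.5, sustained_pct = 2.51),
    blue = pupil_model_params(baseline_mm = 7, amplitude_pct = 28,
                              redilation_rate_pct_s = 2,
                              tau_recover_s = 4, sustained_pct = 14.03))
}

#' Analytic ground-truth normalized pupil curve
#'
#' @param t Time relative to pulse onset (s).
#' @param params A [pupil_model_params].
#' @param pulse_duration Pulse duration (s, default 3).
#' @return `g(t)` in % of baseline.
#' @export
pupil_response_curve <- function(t, params, pulse_duration = 3) {
  with(params, {
    t_min <- latency_s + 3 * tau_constrict_s
    v_min <- 100 - amplitude_pct * (1 - exp(-3))
    # redilation cannot carry the pupil past its baseline diameter
    v_off <- min(100, v_min + redilation_rate_pct_s * (pulse_duration - t_min))
    plateau <- 100 - sustained_pct
    g <- numeric(length(t))
    pre <- t < latency_s
    con <- t >= latency_s & t <= t_min
    red <- t > t_min & t <= pulse_duration
    pos <- t > pulse_duration
    g[pre] <- 100
    g[con] <- 100 - amplitude_pct * (1 - exp(-(t[con] - latency_s) /
                                               tau_constrict_s))
    g[red] <- pmin(100, v_min + redilation_rate_pct_s * (t[red] - t_min))
    g[pos] <- plateau - (plateau - v_off) *
      exp(-(t[pos] - pulse_duration) / tau_recover_s)
    g
  })
}

#' Trial protocol timing
#'
#' @param dark_flash_range Duration range (s) of the synchronization dark
#'   flash at trial start (default 0.4-0.6).
#' @param prepulse_range Range (s) of the random background interval before
#'   the pulse (default 10-12).
#' @param pulse_duration Pulse duration (s, default 3).
#' @param post_duration Post-pulse recording period (s, default 15).
#' @param fs Sampling rate (Hz, default 120).
#' @return List of class `trial_protocol`.
#' @export
trial_protocol <- function(dark_flash_range = c(0.4, 0.6),
                           prepulse_range = c(10, 12),
                           pulse_duration = 3, post_duration = 15,
                           fs = 120) {
  if (post_duration < 9)
    stop("protocol must record at least 9 s after pulse onset")
  structure(list(dark_flash_range = dark_flash_range,
                 prepulse_range = prepulse_range,
                 pulse_duration = pulse_duration,
                 post_duration = post_duration, fs = fs),
            class = "trial_protocol")
}

#' Simulate one raw pupil recording
#'
#' Samples the analytic response curve at `fs`, adds Gaussian measurement
#' noise, and injects Poisson-timed blink artifacts (diameter collapses
#' toward a lid-occlusion value, confidence drops to `blink_confidence`).
#' Fully deterministic given the RNG state. The ground-truth curve and
#' drawn protocol timings are attached as attribute `ground_truth`.
#'
#' @param params A [pupil_model_params].
#' @param protocol A [trial_protocol].
#' @return A [raw_recording].
#' @export
simulate_trial <- function(params, protocol = trial_protocol()) {
  stopifnot(inherits(params, "pupil_model_params"),
            inherits(protocol, "trial_protocol"))
  flash <- stats::runif(1, protocol$dark_flash_range[1],
                        protocol$dark_flash_range[2])
  prepulse <- stats::runif(1, protocol$prepulse_range[1],
                           protocol$prepulse_range[2])
  onset <- flash + prepulse
  total <- onset + protocol$pulse_duration + protocol$post_duration
  time <- seq(0, total, by = 1 / protocol$fs)
  g <- pupil_response_curve(time - onset, params,
                            pulse_duration = protocol$pulse_duration)
  diameter <- params$baseline_mm * g / 100 +
    stats::rnorm(length(time), 0, params$noise_sd_mm)
  confidence <- rep(0.99, length(time))
  n_blinks <- stats::rpois(1, params$blink_rate_hz * total)
  if (n_blinks > 0) {
    starts <- stats::runif(n_blinks, 0, total - params$blink_duration_s)
    for (s in starts) {
      idx <- time >= s & time < s + params$blink_duration_s
      diameter[idx] <- 0.3 * params$baseline_mm +
        stats::rnorm(sum(idx), 0, 5 * params$noise_sd_mm)
      confidence[idx] <- params$blink_confidence
    }
  }
  rec <- raw_recording(time, diameter, confidence, onset = onset,
                       pulse_duration = protocol$pulse_duration,
                       fs = protocol$fs)
  attr(rec, "ground_truth") <- list(params = params, onset = onset,
                                    flash = flash, prepulse = prepulse,
                                    curve = g)
  rec
}

#' Cohort specification for the synthetic study
#'
#' Defines group sizes, stimulus conditions, trial counts, between-
#' participant parameter variability, injected group effect sizes, and the
#' protocol -- the study conditions the generator emulates: 20 glaucoma and
#' 15 control participants for the melanopsin/LMS-directed stimuli (30
#' trials each), of whom 16 and 12 also contribute 15 red and 15 blue
#' narrowband trials.
#'
#' @param n_glaucoma,n_control Group sizes.
#' @param n_rb_glaucoma,n_rb_control Participants per group contributing
#'   red/blue trials (first k of each group).
#' @param conditions Stimulus conditions to simulate.
#' @param n_trials Named trial counts per condition.
#' @param effect_d Named Cohen's d injected on each response metric
#'   (`a`, `b`, `c`, `d`); positive values shift the glaucoma group mean
#'   upward by d between-participant SDs on that metric's scale.
#' @param param_sd Between-participant SDs of the model parameters:
#'   `latency_s`, `tau_constrict_s`, `amplitude_pct`,
#'   `redilation_rate_pct_s`, `sustained_pct`, `baseline_mm`.
#' @param pipr_glaucoma_shift Additive shift (percentage points) on the
#'   glaucoma group's sustained constriction for the blue stimulus,
#'   encoding a reduced melanopsin-driven PIPR (default -1.9, i.e. about a
#'   2-point smaller red-minus-blue PIPR).
#' @param clinical_rho Correlation between the latent participant deficit
#'   and the synthetic clinical covariates.
#' @param protocol A [trial_protocol].
#' @param seed Integer seed; a fixed seed makes the whole cohort
#'   byte-identical across runs.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_glaucoma = 20, n_control = 15,
                        n_rb_glaucoma = 16, n_rb_control = 12,
                        conditions = c("melanopsin", "lms", "red", "blue"),
                        n_trials = c(melanopsin = 30, lms = 30,
                                     red = 15, blue = 15),
                        effect_d = c(a = 0, b = 0, c = 0, d = 0),
                        param_sd = c(latency_s = 0.05,
                                     tau_constrict_s = 0.02,
                                     amplitude_pct = 2,
                                     redilation_rate_pct_s = 1,
                                     sustained_pct = 3,
                                     baseline_mm = 0.5),
                        pipr_glaucoma_shift = -1.9,
                        clinical_rho = 0.3,
                        protocol = trial_protocol(), seed = 1) {
  stopifnot(n_glaucoma >= 1, n_control >= 1,
            n_rb_glaucoma <= n_glaucoma, n_rb_control <= n_control,
            all(is.finite(effect_d)))
  structure(as.list(environment()), class = "cohort_spec")
}

# Metric-scale between-participant SDs implied by the parameter SDs, used
# to convert an injected Cohen's d into a model-parameter shift.
metric_scale_sd <- function(param_sd, params) {
  sat <- 1 - exp(-3)
  c(a = 1000 * sqrt(param_sd[["latency_s"]]^2 +
                      9 * param_sd[["tau_constrict_s"]]^2),
    b = sat * param_sd[["amplitude_pct"]],
    c = param_sd[["redilation_rate_pct_s"]],
    d = (1 - exp(-6 / params$tau_recover_s)) * param_sd[["sustained_pct"]])
}

# Draw one participant's model parameters for a condition.
draw_participant_params <- function(base, sd, group, effect_d,
                                    condition, pipr_shift) {
  z <- stats::rnorm(6)
  p <- base
  p$latency_s <- max(0.05, base$latency_s + sd[["latency_s"]] * z[1])
  p$tau_constrict_s <- max(0.05, base$tau_constrict_s +
                             sd[["tau_constrict_s"]] * z[2])
  p$amplitude_pct <- min(60, max(2, base$amplitude_pct +
                                   sd[["amplitude_pct"]] * z[3]))
  p$redilation_rate_pct_s <- max(0, base$redilation_rate_pct_s +
                                   sd[["redilation_rate_pct_s"]] * z[4])
  p$sustained_pct <- max(0, base$sustained_pct +
                           sd[["sustained_pct"]] * z[5])
  p$baseline_mm <- max(2, base$baseline_mm + sd[["baseline_mm"]] * z[6])
  if (group == "glaucoma") {
    ms <- metric_scale_sd(sd, base)
    # a: latency shift; b: amplitude shift (up = larger diameter, smaller A);
    # c: redilation-rate shift; d: sustained shift (up = less sustained)
    p$latency_s <- p$latency_s + effect_d[["a"]] * ms[["a"]] / 1000
    p$amplitude_pct <- p$amplitude_pct -
      effect_d[["b"]] * param_sd_safe(sd, "amplitude_pct")
    p$redilation_rate_pct_s <- p$redilation_rate_pct_s +
      effect_d[["c"]] * sd[["redilation_rate_pct_s"]]
    p$sustained_pct <- max(0, p$sustained_pct -
                             effect_d[["d"]] * sd[["sustained_pct"]])
    if (condition == "blue")
      p$sustained_pct <- max(0, p$sustained_pct + pipr_shift)
  }
  list(params = p, deficit_z = z[5])
}

param_sd_safe <- function(sd, name) if (name %in% names(sd)) sd[[name]] else 0

#' Simulate a full synthetic cohort
#'
#' Draws per-participant model parameters from group distributions, applies
#' the injected group effects, simulates every trial of every condition,
#' and generates synthetic clinical covariates (visual-field Mean
#' Deviation, Pattern Standard Deviation, mean cpRNFL thickness) correlated
#' with each glaucoma participant's latent deficit at `clinical_rho`.
#'
#' @param spec A [cohort_spec].
#' @return List of class `synthetic_cohort`:
#'   * `recordings`: `recordings[[condition]][[participant]]` = list of
#'     [raw_recording] trials (participants not contributing a condition
#'     hold `NULL`);
#'   * `ground_truth`: data frame of each participant's drawn parameters
#'     per condition;
#'   * `clinical`: data frame of synthetic covariates;
#'   * `participants`: data frame of ids and groups; `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ids <- c(sprintf("glaucoma%02d", seq_len(spec$n_glaucoma)),
           sprintf("control%02d", seq_len(spec$n_control)))
  groups <- rep(c("glaucoma", "control"),
                c(spec$n_glaucoma, spec$n_control))
  contributes_rb <- c(seq_len(spec$n_glaucoma) <= spec$n_rb_glaucoma,
                      seq_len(spec$n_control) <= spec$n_rb_control)
  recordings <- list()
  gt <- list()
  deficit <- numeric(length(ids))
  for (cond in spec$conditions) {
    base <- default_pupil_params(cond)
    recordings[[cond]] <- stats::setNames(vector("list", length(ids)), ids)
    for (i in seq_along(ids)) {
      if (cond %in% c("red", "blue") && !contributes_rb[i]) next
      dp <- draw_participant_params(base, spec$param_sd, groups[i],
                                    spec$effect_d, cond,
                                    spec$pipr_glaucoma_shift)
      deficit[i] <- dp$deficit_z
      nt <- spec$n_trials[[cond]]
      recordings[[cond]][[ids[i]]] <-
        lapply(seq_len(nt), function(k)
          simulate_trial(dp$params, spec$protocol))
      gt[[length(gt) + 1L]] <- data.frame(
        participant = ids[i], group = groups[i], condition = cond,
        latency_s = dp$params$latency_s,
        amplitude_pct = dp$params$amplitude_pct,
        redilation_rate_pct_s = dp$params$redilation_rate_pct_s,
        sustained_pct = dp$params$sustained_pct,
        baseline_mm = dp$params$baseline_mm)
    }
  }
  clinical <- synth_clinical(ids, groups, deficit, spec$clinical_rho)
  structure(list(recordings = recordings,
                 ground_truth = do.call(rbind, gt),
                 clinical = clinical,
                 participants = data.frame(participant = ids,
                                           group = groups,
                                           contributes_rb = contributes_rb),
                 spec = spec),
            class = "synthetic_cohort")
}

# Synthetic clinical covariates: normal marginals matched to typical
# moderate-glaucoma / healthy screening values, correlated with the latent
# deficit z-score at rho within the glaucoma group.
synth_clinical <- function(ids, groups, deficit, rho) {
  n <- length(ids)
  mix <- function(z) rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
  gl <- groups == "glaucoma"
  md <- ifelse(gl, -5.72 + 2.67 * mix(-deficit), 0.52 + 0.62 * stats::rnorm(n))
  psd <- ifelse(gl, 7.67 + 2.88 * mix(deficit), 1.43 + 0.21 * stats::rnorm(n))
  rnfl <- ifelse(gl, 62.8 + 8.6 * mix(-deficit), 96.2 + 7.6 * stats::rnorm(n))
  data.frame(participant = ids, group = groups, vf_md_db = md,
             vf_psd_db = psd, cprnfl_um = rnfl)
}

#' Preprocess a synthetic cohort into per-participant mean traces
#'
#' Runs the full cleaning pipeline on every trial and averages each
#' participant's clean trials on a common onset-aligned grid covering
#' `[-1, 18]` s.
#'
#' @param cohort A [synthetic_cohort].
#' @param grid_range Time range (s relative to onset) of the common grid.
#' @param ... Passed to [preprocess_trial()].
#' @return Named list `traces[[condition]][[participant]]` of mean
#'   [clean_trial] objects (NULL where no usable trial).
#' @export
preprocess_cohort <- function(cohort, grid_range = c(-1, 18), ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  fs <- cohort$spec$protocol$fs
  grid <- seq(grid_range[1], grid_range[2], by = 1 / fs)
  out <- list()
  for (cond in names(cohort$recordings)) {
    out[[cond]] <- lapply(cohort$recordings[[cond]], function(trials) {
      if (is.null(trials)) return(NULL)
      clean <- lapply(trials, function(raw) {
        ct <- preprocess_trial(raw, ...)
        if (!inherits(ct, "clean_trial")) return(ct)
        # common onset-aligned grid so trials can be averaged pointwise
        ct$pupil <- stats::approx(ct$time, ct$pupil, xout = grid,
                                  rule = 2)$y
        ct$time <- grid
        ct
      })
      participant_mean_trace(clean)
    })
  }
  out
}

#' Write cohort traces in the supplementary-table dialect
#'
#' Emits the eight-file layout (`{group}{Stimulus}Stimulus.csv` for group
#' in control/glaucoma and stimulus in Blue/Red/LMS/Melanopsin): first
#' column `timeRelativeToPulseOnset` (s), one column per participant (% of
#' baseline), all-NA columns for participants who did not contribute that
#' stimulus.
#'
#' @param traces Output of [preprocess_cohort()].
#' @param participants Data frame with `participant` and `group` columns
#'   (all cohort members; non-contributors get NA columns).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_supplementary_dialect <- function(traces, participants, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stim_name <- c(melanopsin = "Melanopsin", lms = "LMS",
                 red = "Red", blue = "Blue")
  paths <- character(0)
  for (cond in names(traces)) {
    for (grp in c("control", "glaucoma")) {
      ids <- participants$participant[participants$group == grp]
      cols <- lapply(ids, function(id) {
        tr <- traces[[cond]][[id]]
        if (is.null(tr)) return(NULL) else tr
      })
      tg <- NULL
      for (tr in cols) if (!is.null(tr)) { tg <- tr$time; break }
      if (is.null(tg)) tg <- numeric(0)
      df <- data.frame(timeRelativeToPulseOnset = tg)
      for (k in seq_along(ids)) {
        df[[ids[k]]] <- if (is.null(cols[[k]])) rep(NA_real_, length(tg))
                        else cols[[k]]$pupil
      }
      path <- file.path(dir, sprintf("%s%sStimulus.csv", grp,
                                     stim_name[[cond]]))
      utils::write.csv(df, path, row.names = FALSE, na = "NA")
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Synthetic calibration of a multi-primary light source
#'
#' Gaussian-shaped primary spectra (peak wavelength, FWHM, peak spectral
#' radiance per primary) scaled by a monotone level-response curve
#' `level^gamma`, measured at `n_levels` input levels including 0 and 1 --
#' a stand-in for a spectroradiometric characterization of a 10-primary
#' device.
#'
#' @param n_primaries Number of primaries (default 10).
#' @param peaks Peak wavelengths (nm); default 10 LEDs spanning 420-660 nm.
#' @param fwhm Full width at half maximum (nm), recycled.
#' @param max_radiance Peak spectral radiance at full drive
#'   (W m^-2 sr^-1 nm^-1), recycled.
#' @param gamma Exponent of the level-response curve (1 = linear).
#' @param n_levels Number of measured levels (>= 2, includes 0 and 1).
#' @param wavelength Measurement grid (nm).
#' @return A [device_calibration].
#' @export
make_device_calibration <- function(n_primaries = 10,
                                    peaks = seq(420, 660,
                                                length.out = n_primaries),
                                    fwhm = 25, max_radiance = 0.02,
                                    gamma = 1, n_levels = 5,
                                    wavelength = canonical_grid(2)) {
  if (any(peaks < 380 | peaks > 780)) stop("peaks must lie in 380-780 nm")
  if (n_levels < 2) stop("need at least 2 levels")
  fwhm <- rep_len(fwhm, n_primaries)
  max_radiance <- rep_len(max_radiance, n_primaries)
  levels <- seq(0, 1, length.out = n_levels)
  primaries <- lapply(seq_len(n_primaries), function(i) {
    sigma <- fwhm[i] / (2 * sqrt(2 * log(2)))
    full <- max_radiance[i] * exp(-(wavelength - peaks[i])^2 / (2 * sigma^2))
    spectra <- t(vapply(levels, function(l) l^gamma * full,
                        numeric(length(wavelength))))
    list(levels = levels, spectra = spectra)
  })
  device_calibration(wavelength, primaries)
}
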