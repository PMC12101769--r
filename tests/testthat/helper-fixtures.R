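# Shared fixtures: idealized devices, boxcar sensitivities, and in-memory
# trace tables built from synthetic cohorts.

# Boxcar sensitivity over [lo, hi] nm (1 inside, 0 outside).
boxcar_sensitivity <- function(receptor, lo, hi, grid = canonical_grid()) {
  structure(list(receptor = receptor, wavelength = grid,
                 value = as.numeric(grid >= lo & grid <= hi)),
            class = "sensitivity_function")
}

# Two-primary toy device with disjoint boxcar primaries and a constant
# leakage floor at level 0, so Weber contrast stays finite:
# radiance(level) = (leak + (1 - leak) * level) * R_full, identically in
# wavelength. Primary 1 emits only in 400-500 nm, primary 2 in 600-700 nm.
toy_boxcar_device <- function(leak = 0.1) {
  wl <- seq(380, 780, by = 5)
  box <- function(lo, hi) 1e-3 * as.numeric(wl >= lo & wl <= hi)
  mk <- function(lo, hi) {
    full <- box(lo, hi)
    list(levels = c(0, 1), spectra = rbind(leak * full, full))
  }
  device_calibration(wl, list(mk(400, 500), mk(600, 700)))
}

toy_sensitivities <- function() {
  list(melanopsin = boxcar_sensitivity("melanopsin", 400, 500),
       cone = boxcar_sensitivity("cone", 600, 700))
}

# Weber contrast of the toy primary between levels b (background) and p
# (pulse): shape cancels, only the leakage-affine level response remains.
toy_contrast <- function(p, b, leak = 0.1)
  100 * ((leak + (1 - leak) * p) / (leak + (1 - leak) * b) - 1)

# Build the named trace-table list run_full_analysis() expects directly
# from preprocess_cohort() output (no file round trip).
tables_from_traces <- function(traces, participants) {
  out <- list()
  for (cond in names(traces)) {
    for (grp in c("glaucoma", "control")) {
      ids <- participants$participant[participants$group == grp]
      trs <- traces[[cond]][ids]
      keep <- !vapply(trs, is.null, logical(1))
      if (!any(keep)) next
      tg <- trs[[which(keep)[1]]]$time
      mat <- vapply(trs[keep], function(tr) tr$pupil, numeric(length(tg)))
      out[[paste(grp, cond, sep = "_")]] <-
        structure(list(time = tg, pupil = as.matrix(mat),
                       contributors = ids[keep],
                       non_contributors = ids[!keep]),
                  class = "trace_table")
    }
  }
  out
}

# Small cohort spec used when the full study scale is not needed.
small_cohort_spec <- function(seed, n_trials = 4, ...) {
  cohort_spec(n_glaucoma = 6, n_control = 5,
              n_rb_glaucoma = 5, n_rb_control = 4,
              n_trials = c(melanopsin = n_trials, lms = n_trials,
                           red = n_trials, blue = n_trials),
              seed = seed, ...)
}
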