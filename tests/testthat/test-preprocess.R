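# Pupillometry cleaning: masking, interpolation, smoothing, normalization.

make_raw <- function(diameter, confidence = rep(1, length(diameter)),
                     fs = 120, onset = 2) {
  raw_recording(seq_along(diameter) / fs, diameter, confidence,
                onset = onset, fs = fs)
}

test_that("masking catches low confidence and derivative outliers", {
  n <- 240
  clean <- make_raw(rep(5, n))
  expect_false(any(mask_samples(clean)))

  conf <- rep(1, n); conf[100] <- 0.90
  low <- make_raw(rep(5, n), conf)
  expect_equal(which(mask_samples(low)), 100L)

  # confidence exactly at threshold is acceptable (strictly below masks)
  conf[100] <- 0.95
  expect_false(any(mask_samples(make_raw(rep(5, n), conf))))
})

test_that("a step jump is masked exactly as the hand-computed rule says", {
  set.seed(42)
  n <- 600; fs <- 120
  d <- 5 + 0.01 * rnorm(n)
  d[301:n] <- d[301:n] + 1     # injected step at sample 301
  raw <- make_raw(d, fs = fs)
  mask <- mask_samples(raw)
  # oracle: recompute first differences / SD by hand
  deriv <- diff(d) * fs
  bad <- abs(deriv - mean(deriv)) > 3 * sd(deriv)
  expect_equal(which(mask), which(bad) + 1L)
  expect_true(301 %in% which(mask))
})

test_that("interpolation is exact on midpoints and linear ramps", {
  raw <- make_raw(c(4, 4, 5, 6, 6))
  mask <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  raw$diameter[3] <- 99      # corrupted sample
  expect_equal(interpolate_masked(raw, mask)[3], 5)
  expect_equal(interpolate_masked(raw, rep(FALSE, 5)), raw$diameter)

  # random masks on a linear ramp reconstruct it exactly
  set.seed(7)
  ramp <- make_raw(seq(4, 6, length.out = 240))
  truth <- ramp$diameter
  mask <- runif(240) < 0.2
  mask[c(1, 240)] <- FALSE
  ramp$diameter[mask] <- 0
  expect_equal(interpolate_masked(ramp, mask), truth, tolerance = 1e-12)

  # leading edge gap takes the nearest unmasked value
  lead <- make_raw(c(9, 9, 5, 5, 5))
  expect_equal(interpolate_masked(lead, c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               rep(5, 5))
})

test_that("zero-phase Butterworth matches the analytic magnitude response", {
  fs <- 120; n <- 20 * fs
  t <- (0:(n - 1)) / fs
  expect_equal(smooth_series(rep(7, n)), rep(7, n), tolerance = 1e-9)

  # forward-backward third-order Butterworth: |H(f)|^2 = 1/(1+(f/fc)^6)
  gain2 <- function(f, fc = 4, ord = 3) 1 / (1 + (f / fc)^(2 * ord))
  amp_ratio <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- smooth_series(x)
    mid <- (5 * fs):(15 * fs)
    fit <- lm(y[mid] ~ sin(2 * pi * f * t[mid]) + cos(2 * pi * f * t[mid]))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_equal(amp_ratio(1), gain2(1), tolerance = 0.02)
  expect_equal(amp_ratio(3), gain2(3), tolerance = 0.02)
  # 30 Hz is attenuated at least as strongly as the analytic stop band
  expect_lte(amp_ratio(30), gain2(30) * 1.02)
})

test_that("smoothing preserves the mean of a stationary segment", {
  set.seed(9)
  x <- 5 + 0.1 * rnorm(3600)
  y <- smooth_series(x)
  mid <- 600:3000
  expect_lt(abs(mean(y[mid]) / mean(x[mid]) - 1), 0.001)
})

test_that("baseline normalization yields mean 100 over the window, exactly", {
  fs <- 120
  tm <- seq(0, 12, by = 1 / fs)
  d <- 5 + 0.3 * sin(tm)
  ct <- normalize_to_baseline(tm, d, onset = 6)
  in_bl <- ct$time >= -1 & ct$time < 0
  expect_equal(mean(ct$pupil[in_bl]), 100, tolerance = 1e-9)

  # constant 6 mm baseline with a later 5.1 mm sample -> 85%
  d2 <- rep(6, length(tm)); d2[tm > 8] <- 5.1
  ct2 <- normalize_to_baseline(tm, d2, onset = 6)
  expect_equal(ct2$pupil[length(tm)], 85, tolerance = 1e-9)

  expect_error(normalize_to_baseline(tm, rep(0, length(tm)), onset = 6),
               "baseline")
  expect_error(normalize_to_baseline(tm, d, onset = 0.1), "baseline")
})

test_that("the full pipeline recovers generator ground truth", {
  params <- default_pupil_params("melanopsin")
  params$noise_sd_mm <- 0; params$blink_rate_hz <- 0
  set.seed(123)
  raw <- simulate_trial(params)
  ct <- preprocess_trial(raw)
  expect_s3_class(ct, "clean_trial")
  # on a noiseless trace the +/-3 SD derivative rule flags only the few
  # samples at the sharp response onset
  expect_lte(ct$mask_fraction, 0.02)
  # compare to the analytic curve over the analysis window
  keep <- ct$time >= -1 & ct$time <= 17
  truth <- pupil_response_curve(ct$time[keep], params)
  rmse <- sqrt(mean((ct$pupil[keep] - truth)^2))
  expect_lt(rmse, 0.5)
  # recovered baseline equals the model baseline within 0.5%
  expect_equal(ct$baseline_mm, params$baseline_mm,
               tolerance = 0.005 * params$baseline_mm)
})

test_that("mask fraction tracks injected blink artifacts", {
  params <- default_pupil_params("melanopsin")
  params$blink_rate_hz <- 0.3
  set.seed(77)
  raw <- simulate_trial(params)
  gt_blink <- mean(raw$confidence < 0.95)
  ct <- preprocess_trial(raw, exclude_threshold = 1)
  n_blinks <- sum(diff(c(0, raw$confidence < 0.95)) == 1)
  n <- length(raw$time)
  expect_gte(ct$mask_fraction, gt_blink)
  expect_lte(ct$mask_fraction, gt_blink + (2 * n_blinks + 4) / n)
})

test_that("trials exceeding the masked-fraction threshold are excluded with a reason", {
  n <- 2400
  conf <- rep(1, n); conf[1:1000] <- 0.5
  raw <- make_raw(rep(5, n), conf, onset = 10)
  out <- preprocess_trial(raw, exclude_threshold = 0.25)
  expect_s3_class(out, "excluded_trial")
  expect_match(out$reason, "masked_fraction")
})

test_that("preprocessing an already-clean trace changes it only marginally", {
  # measurement noise keeps the derivative SD noise-dominated, as in real
  # recordings, so the re-run masks essentially nothing
  params <- default_pupil_params("lms")
  params$blink_rate_hz <- 0
  set.seed(5)
  raw <- simulate_trial(params)
  ct1 <- preprocess_trial(raw)
  # feed the cleaned output back through the pipeline
  raw2 <- raw_recording(ct1$time + raw$onset,
                        ct1$pupil * ct1$baseline_mm / 100,
                        rep(1, length(ct1$time)), onset = raw$onset)
  ct2 <- preprocess_trial(raw2)
  keep <- ct2$time >= -1 & ct2$time <= 17
  dev <- abs(ct2$pupil[keep] - approx(ct1$time, ct1$pupil, ct2$time[keep])$y)
  expect_lt(sqrt(mean(dev^2)), 0.5)
  # the scale-relative derivative rule may re-flag the steepest part of
  # the constriction itself; away from it the trace is unchanged
  tt <- ct2$time[keep]
  expect_lt(max(dev[tt < 0 | tt > 1.5]), 0.5)
})
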