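# Device forward model and silent-substitution solver.

test_that("forward model reproduces measured knots and interpolates between them", {
  cal <- make_device_calibration(n_primaries = 3, n_levels = 3)
  # all off -> zero spectrum
  expect_equal(max(abs(predict_spd(cal, c(0, 0, 0))$value)), 0)
  # exactly at a measured level -> that measured spectrum
  s <- predict_spd(cal, c(0.5, 0, 0))
  expect_equal(s$value, cal$primaries[[1]]$spectra[2, ])
  # midpoint between measured levels -> hand-computed linear interpolation
  s <- predict_spd(cal, c(0.25, 0, 0))
  manual <- 0.5 * cal$primaries[[1]]$spectra[1, ] +
    0.5 * cal$primaries[[1]]$spectra[2, ]
  expect_equal(s$value, manual)
  # superposition across primaries
  s12 <- predict_spd(cal, c(0.5, 0.5, 0))
  expect_equal(s12$value,
               predict_spd(cal, c(0.5, 0, 0))$value +
                 predict_spd(cal, c(0, 0.5, 0))$value)
  expect_error(predict_spd(cal, c(2, 0, 0)), "bounds")
})

test_that("solver finds the closed-form optimum on the boxcar toy device", {
  cal <- toy_boxcar_device(leak = 0.1)
  pair <- solve_max_contrast(cal, target = "melanopsin", silenced = "cone",
                             tolerance = 6, restarts = 4, seed = 2,
                             sensitivities = toy_sensitivities())
  expect_true(pair$success)
  # analytic optimum: pulse primary 1 at max, background at lower bound,
  # cone primary equal in pulse and background -> contrast 900%
  expect_equal(unname(pair$contrasts["melanopsin"]),
               toy_contrast(1, 0), tolerance = 0.01)
  expect_lt(abs(pair$contrasts["cone"]), 0.1)
})

test_that("relaxing the silencing constraint cannot reduce the target contrast", {
  cal <- toy_boxcar_device()
  sens <- toy_sensitivities()
  tight <- solve_max_contrast(cal, "melanopsin", "cone", tolerance = 1,
                              restarts = 3, seed = 5, sensitivities = sens)
  loose <- solve_max_contrast(cal, "melanopsin", "cone", tolerance = 1e6,
                              restarts = 3, seed = 5, sensitivities = sens)
  expect_gte(loose$contrasts["melanopsin"] + 1e-6,
             tight$contrasts["melanopsin"])
})

test_that("matched-contrast mode reaches the requested summary contrast", {
  cal <- toy_boxcar_device(leak = 0.1)
  sens <- toy_sensitivities()
  pair <- solve_matched_contrast(cal, match_contrast = 100,
                                 target = "cone", silenced = "melanopsin",
                                 tolerance = 6, restarts = 4, seed = 3,
                                 sensitivities = sens)
  expect_true(pair$success)
  expect_equal(unname(pair$contrasts["cone"]), 100, tolerance = 0.5)
  expect_lt(abs(pair$contrasts["melanopsin"]), 6)
  # closed form: achieved radiance ratio on the cone primary must be 2:1
  b <- pair$background_settings[2]; p <- pair$pulse_settings[2]
  expect_equal((0.1 + 0.9 * p) / (0.1 + 0.9 * b), 2, tolerance = 0.01)
})

test_that("match_contrast = 0 admits the trivial background = pulse solution", {
  cal <- toy_boxcar_device()
  pair <- solve_matched_contrast(cal, match_contrast = 0,
                                 target = "cone", silenced = "melanopsin",
                                 restarts = 3, seed = 4,
                                 sensitivities = toy_sensitivities())
  expect_true(pair$success)
  expect_lt(abs(pair$contrasts["cone"]), 1)
  expect_lt(abs(pair$contrasts["melanopsin"]), 6)
})

test_that("solver is reproducible and self-consistent under a fixed seed", {
  cal <- toy_boxcar_device()
  sens <- toy_sensitivities()
  p1 <- solve_max_contrast(cal, "melanopsin", "cone", restarts = 3,
                           seed = 11, sensitivities = sens)
  p2 <- solve_max_contrast(cal, "melanopsin", "cone", restarts = 3,
                           seed = 11, sensitivities = sens)
  expect_identical(p1$background_settings, p2$background_settings)
  expect_identical(p1$pulse_settings, p2$pulse_settings)
  # contrasts recomputed from the spectra equal those stored in the pair
  ct <- stimulus_contrasts(p1, receptors = c("melanopsin", "cone"),
                           sensitivities = sens)
  expect_equal(unclass(ct), unclass(p1$contrasts), tolerance = 1e-6)
})

test_that("verification flags failures and passes on compliant pairs", {
  cal <- toy_boxcar_device()
  sens <- toy_sensitivities()
  prob <- ss_problem("melanopsin", "cone", mode = "maximize",
                     tolerance = 6, sensitivities = sens)
  # identical spectra: silenced checks pass, target check fails
  same <- stimulus_pair(cal, background = c(0.5, 0.5), pulse = c(0.5, 0.5),
                        problem = prob)
  v <- verify_pair(same, prob, target_min = 200)
  expect_true(all(v$silenced_ok))
  expect_false(v$target_ok)
  expect_false(v$pass)
  # deliberately violated silencing: cone modulated well past tolerance
  bad <- stimulus_pair(cal, background = c(0.2, 0.1), pulse = c(1, 0.9),
                       problem = prob)
  vb <- verify_pair(bad, prob)
  expect_false(all(vb$silenced_ok))
  expect_false(vb$pass)
})

test_that("narrowband pair matching equalizes unweighted total radiance", {
  # identical primaries stay at equal (full) levels
  wl <- seq(380, 780, by = 5)
  g <- 1e-3 * exp(-(wl - 500)^2 / 200)
  same <- device_calibration(wl, rep(list(list(levels = c(0, 1),
                                               spectra = rbind(0 * g, g))), 2))
  nb <- narrowband_pair(same, 1, 2)
  expect_equal(unname(nb$total_radiance["red"]),
               unname(nb$total_radiance["blue"]), tolerance = 1e-9)
  expect_equal(nb$red_settings[1], 1)
  expect_equal(nb$blue_settings[2], 1)

  # 2:1 total-radiance primaries (linear response): larger scaled to 0.5
  two <- device_calibration(wl, list(
    list(levels = c(0, 1), spectra = rbind(0 * g, 2 * g)),
    list(levels = c(0, 1), spectra = rbind(0 * g, g))))
  nb2 <- narrowband_pair(two, 1, 2)
  expect_equal(nb2$red_settings[1], 0.5, tolerance = 1e-9)
  expect_equal(unname(nb2$total_radiance["red"]),
               unname(nb2$total_radiance["blue"]), tolerance = 1e-6)

  # synthetic device primaries 9 and 3: matched within 1e-6 relative
  cal <- make_device_calibration()
  nb3 <- narrowband_pair(cal, 9, 3)
  expect_equal(unname(nb3$total_radiance["red"] / nb3$total_radiance["blue"]),
               1, tolerance = 1e-6)
})
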