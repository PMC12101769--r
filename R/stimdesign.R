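#' Device calibration for a multi-primary light source
#'
#' Stores measured spectral radiance of each primary across normalized input
#' levels (0 = off, 1 = full 12-bit drive). The forward model assumes
#' superposition across primaries and piecewise-linear radiance response
#' within each primary's measured levels.
#'
#' @param wavelength Common wavelength grid (nm) of all measured spectra.
#' @param primaries A list, one element per primary, each a list with
#'   `levels` (sorted numeric vector in `[0, 1]`, containing 0 and the
#'   maximum level 1) and `spectra` (matrix, rows = levels, cols =
#'   wavelengths, non-negative radiance).
#' @return An object of class `device_calibration`.
#' @export
device_calibration <- function(wavelength, primaries) {
  wavelength <- as.numeric(wavelength)
  if (any(diff(wavelength) <= 0)) stop("wavelength grid must be increasing")
  for (i in seq_along(primaries)) {
    p <- primaries[[i]]
    if (is.null(p$levels) || is.null(p$spectra))
      stop("each primary needs 'levels' and 'spectra'")
    if (length(p$levels) < 2L)
      stop("each primary needs at least two measured levels")
    if (is.unsorted(p$levels, strictly = TRUE))
      stop("levels must be strictly increasing")
    if (abs(p$levels[1]) > 1e-12 || abs(p$levels[length(p$levels)] - 1) > 1e-9)
      stop("levels must include 0 and 1")
    if (!is.matrix(p$spectra) ||
        nrow(p$spectra) != length(p$levels) ||
        ncol(p$spectra) != length(wavelength))
      stop("spectra must be a levels x wavelength matrix")
  }
  structure(list(wavelength = wavelength, primaries = primaries),
            class = "device_calibration")
}

#' @export
print.device_calibration <- function(x, ...) {
  cat(sprintf("<device_calibration: %d primaries, %d wavelengths (%g-%g nm)>\n",
              length(x$primaries), length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Number of primaries of a calibrated device
#' @param cal A [device_calibration].
#' @export
n_primaries <- function(cal) length(cal$primaries)

#' Predict the spectral output of the device at given settings
#'
#' For each primary the spectrum at the requested level is obtained by
#' linear interpolation between the two bracketing measured levels,
#' wavelength by wavelength; the device output is the sum over primaries.
#'
#' @param cal A [device_calibration].
#' @param settings Numeric vector of per-primary intensities in `[0, 1]`.
#' @return A [spectrum] on the calibration's wavelength grid.
#' @export
predict_spd <- function(cal, settings) {
  stopifnot(inherits(cal, "device_calibration"))
  settings <- as.numeric(settings)
  if (length(settings) != n_primaries(cal))
    stop("settings length must equal the number of primaries")
  if (any(settings < -1e-12 | settings > 1 + 1e-12))
    stop("settings out of [0, 1] bounds")
  settings <- pmin(pmax(settings, 0), 1)
  total <- numeric(length(cal$wavelength))
  for (i in seq_along(cal$primaries)) {
    p <- cal$primaries[[i]]
    lev <- settings[i]
    k <- findInterval(lev, p$levels, rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(p$levels) - 1L)
    w <- (lev - p$levels[k]) / (p$levels[k + 1] - p$levels[k])
    total <- total + (1 - w) * p$spectra[k, ] + w * p$spectra[k + 1, ]
  }
  spectrum(cal$wavelength, total)
}

#' Silent-substitution design problem
#'
#' @param target Receptor(s) whose contrast is maximized (`mode =
#'   "maximize"`) or driven to `match_contrast` (`mode = "match"`).
#' @param silenced Receptor(s) whose absolute contrast must stay within
#'   `tolerance`.
#' @param mode `"maximize"` or `"match"`.
#' @param match_contrast Target summary contrast (%) for `mode = "match"`;
#'   the summary is the mean Weber contrast across `target` receptors.
#' @param tolerance Maximum allowed absolute contrast (%) on each silenced
#'   receptor (default 6, the design envelope used for these stimuli).
#' @param restarts Number of multi-start launches of the local optimizer.
#' @param seed Integer seed making the stochastic search reproducible.
#' @param maxit Iteration cap per local optimization stage.
#' @param sensitivities Optional named list of [sensitivity_function]
#'   objects overriding [photoreceptor_sensitivity()] for the named
#'   receptors (used e.g. for idealized test devices).
#' @return An object of class `silent_substitution_problem`.
#' @export
ss_problem <- function(target, silenced, mode = c("maximize", "match"),
                       match_contrast = NULL, tolerance = 6,
                       restarts = 20, seed = 1, maxit = 300,
                       sensitivities = NULL) {
  mode <- match.arg(mode)
  if (length(intersect(target, silenced)) > 0)
    stop("target and silenced receptor sets must be disjoint")
  if (tolerance <= 0) stop("tolerance must be positive")
  if (mode == "match" && is.null(match_contrast))
    stop("mode = 'match' needs match_contrast")
  structure(list(target = target, silenced = silenced, mode = mode,
                 match_contrast = match_contrast, tolerance = tolerance,
                 restarts = restarts, seed = seed, maxit = maxit,
                 sensitivities = sensitivities),
            class = "silent_substitution_problem")
}

# Resolve a receptor name to its sensitivity, honouring overrides.
resolve_sensitivity <- function(r, sensitivities = NULL) {
  if (!is.null(sensitivities) && r %in% names(sensitivities))
    sensitivities[[r]]
  else photoreceptor_sensitivity(r)
}

# Per-receptor alpha-opic radiances of the predicted spectrum at settings.
settings_radiances <- function(cal, settings, receptors, grid,
                               sensitivities = NULL) {
  spd <- predict_spd(cal, settings)
  vapply(receptors, function(r)
    alphaopic_radiance(spd, resolve_sensitivity(r, sensitivities),
                       grid = grid), numeric(1))
}

# Contrasts (%) for all receptors given concatenated c(background, pulse).
pair_contrasts_from_x <- function(cal, x, receptors, grid,
                                  sensitivities = NULL) {
  np <- n_primaries(cal)
  bg <- settings_radiances(cal, x[seq_len(np)], receptors, grid,
                           sensitivities)
  pu <- settings_radiances(cal, x[np + seq_len(np)], receptors, grid,
                           sensitivities)
  100 * (pu - bg) / bg
}

# Precompute per-(receptor, primary, level) alpha-opic integrals so the
# optimizer evaluates radiances with a few arithmetic operations instead of
# re-integrating spectra. Exactly mirrors alphaopic_radiance(): linear
# resampling onto `grid` (zero outside support) and trapezoidal weights.
compile_radiance_model <- function(cal, receptors, grid,
                                   sensitivities = NULL) {
  wts <- diff(grid)
  wts <- c(wts[1] / 2, (wts[-length(wts)] + wts[-1]) / 2,
           wts[length(wts)] / 2)
  sens <- vapply(receptors, function(r) {
    s <- resolve_sensitivity(r, sensitivities)
    stats::approx(s$wavelength, s$value, xout = grid, yleft = 0,
                  yright = 0)$y
  }, numeric(length(grid)))
  tabs <- lapply(seq_along(cal$primaries), function(i) {
    p <- cal$primaries[[i]]
    lev_spectra <- vapply(seq_along(p$levels), function(k)
      stats::approx(cal$wavelength, p$spectra[k, ], xout = grid,
                    yleft = 0, yright = 0)$y, numeric(length(grid)))
    crossprod(lev_spectra, sens * wts)   # levels x receptors
  })
  list(levels = lapply(cal$primaries, `[[`, "levels"), tabs = tabs,
       receptors = receptors)
}

# Fast per-receptor radiances at settings using the compiled model.
compiled_radiances <- function(model, settings) {
  out <- numeric(length(model$receptors))
  for (p in seq_along(model$tabs)) {
    lv <- model$levels[[p]]
    k <- findInterval(settings[p], lv, rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(lv) - 1L)
    w <- (settings[p] - lv[k]) / (lv[k + 1] - lv[k])
    out <- out + (1 - w) * model$tabs[[p]][k, ] + w * model$tabs[[p]][k + 1, ]
  }
  names(out) <- model$receptors
  out
}

compiled_contrasts <- function(model, x) {
  np <- length(model$tabs)
  bg <- compiled_radiances(model, x[seq_len(np)])
  pu <- compiled_radiances(model, x[np + seq_len(np)])
  100 * (pu - bg) / bg
}

# Penalized objective used by the multi-start search. Returns a value to
# MINIMIZE. `w` is the penalty weight on squared silenced contrast.
ss_objective <- function(x, model, problem, w) {
  ct <- compiled_contrasts(model, x)
  if (any(!is.finite(ct))) return(1e9)
  pen <- w * sum(ct[problem$silenced]^2)
  if (problem$mode == "maximize") {
    -mean(ct[problem$target]) + pen
  } else {
    (mean(ct[problem$target]) - problem$match_contrast)^2 + pen
  }
}

#' Solve a silent-substitution design problem
#'
#' Joint optimization of background and pulse device settings (2 x
#' n_primaries variables in `[0, 1]`) by a stochastic multi-start scheme:
#' random feasible starting points, box-constrained quasi-Newton local
#' optimization (`optim(method = "L-BFGS-B")`), and a penalty-continuation
#' ladder that tightens the silencing constraint at each stage. The incumbent
#' is the best candidate whose silenced contrasts satisfy the problem
#' tolerance; with a fixed seed the result is fully reproducible.
#'
#' @param cal A [device_calibration].
#' @param problem A [ss_problem].
#' @param grid Integration grid for contrasts.
#' @return A [stimulus_pair] on success. If no candidate satisfies the
#'   silencing tolerance the best infeasible candidate is returned with
#'   `success = FALSE`.
#' @export
solve_silent_substitution <- function(cal, problem, grid = canonical_grid()) {
  stopifnot(inherits(cal, "device_calibration"),
            inherits(problem, "silent_substitution_problem"))
  np <- n_primaries(cal)
  receptors <- union(problem$target, problem$silenced)
  model <- compile_radiance_model(cal, receptors, grid,
                                  problem$sensitivities)
  weights <- c(1, 10, 100, 1e4, 1e6)

  best <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(problem$seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })

  for (r in seq_len(problem$restarts)) {
    # random interior start; keep radiances away from zero so contrasts exist
    x <- stats::runif(2 * np, min = 0.05, max = 0.95)
    for (w in weights) {
      fit <- stats::optim(x, ss_objective, model = model,
                          problem = problem, w = w,
                          method = "L-BFGS-B", lower = rep(0, 2 * np),
                          upper = rep(1, 2 * np),
                          control = list(maxit = problem$maxit))
      x <- fit$par
    }
    ct <- compiled_contrasts(model, x)
    if (any(!is.finite(ct))) next
    feas <- all(abs(ct[problem$silenced]) <= problem$tolerance)
    # candidates are ranked with a residual-silencing penalty so a cleanly
    # silenced pair beats a sloppier one that merely clears the tolerance
    score <- (if (problem$mode == "maximize") mean(ct[problem$target])
              else -abs(mean(ct[problem$target]) - problem$match_contrast)) -
      100 * sum(ct[problem$silenced]^2)
    cand <- list(x = x, contrasts = ct, feasible = feas, score = score)
    if (is.null(best) ||
        (feas && !best$feasible) ||
        (feas == best$feasible && score > best$score)) best <- cand
  }

  if (is.null(best)) stop("optimizer produced no evaluable candidate")
  bg <- best$x[seq_len(np)]
  pu <- best$x[np + seq_len(np)]
  stimulus_pair(cal, background = bg, pulse = pu, grid = grid,
                problem = problem, success = best$feasible)
}

#' Maximize contrast on target receptors while silencing others
#'
#' Convenience wrapper for the melanopsin-directed design: maximum melanopsin
#' contrast with the cones silenced (or any other target/silenced split).
#'
#' @inheritParams solve_silent_substitution
#' @param target,silenced Receptor names.
#' @param tolerance,restarts,seed,sensitivities Passed to [ss_problem()].
#' @export
solve_max_contrast <- function(cal, target = "melanopsin",
                               silenced = c("L", "M", "S"),
                               tolerance = 6, restarts = 20, seed = 1,
                               grid = canonical_grid(),
                               sensitivities = NULL) {
  solve_silent_substitution(
    cal, ss_problem(target, silenced, mode = "maximize",
                    tolerance = tolerance, restarts = restarts, seed = seed,
                    sensitivities = sensitivities),
    grid = grid)
}

#' Find a contrast-matched control pair
#'
#' The control design: drive the target receptors (typically L, M, S) at a
#' prescribed summary contrast -- the mean Weber contrast across the target
#' set -- while silencing the other class (typically melanopsin).
#'
#' @inheritParams solve_max_contrast
#' @param match_contrast Summary contrast (%) to reproduce, usually the
#'   melanopsin contrast achieved by [solve_max_contrast()].
#' @export
solve_matched_contrast <- function(cal, match_contrast,
                                   target = c("L", "M", "S"),
                                   silenced = "melanopsin",
                                   tolerance = 6, restarts = 20, seed = 1,
                                   grid = canonical_grid(),
                                   sensitivities = NULL) {
  solve_silent_substitution(
    cal, ss_problem(target, silenced, mode = "match",
                    match_contrast = match_contrast, tolerance = tolerance,
                    restarts = restarts, seed = seed,
                    sensitivities = sensitivities),
    grid = grid)
}

#' Background/pulse stimulus pair
#'
#' Bundles device settings, predicted spectra, achieved per-opsin contrasts
#' and luminances for a background+pulse pair.
#'
#' @param cal A [device_calibration].
#' @param background,pulse Settings vectors in `[0, 1]`.
#' @param grid Integration grid.
#' @param problem Optional [ss_problem] that produced the pair.
#' @param success Whether the solver reported a feasible solution.
#' @return Object of class `stimulus_pair` with elements
#'   `background_settings`, `pulse_settings`, `background_spectrum`,
#'   `pulse_spectrum`, `contrasts`, `luminance` (named: background, pulse),
#'   `problem`, `success`.
#' @export
stimulus_pair <- function(cal, background, pulse, grid = canonical_grid(),
                          problem = NULL, success = NA) {
  bg_spd <- predict_spd(cal, background)
  pu_spd <- predict_spd(cal, pulse)
  receptors <- if (!is.null(problem))
    union(problem$target, problem$silenced) else default_receptors()
  ct <- stimulus_contrasts(list(background = bg_spd, pulse = pu_spd),
                           receptors = receptors, grid = grid,
                           sensitivities = problem$sensitivities)
  structure(list(
    background_settings = background, pulse_settings = pulse,
    background_spectrum = bg_spd, pulse_spectrum = pu_spd,
    contrasts = ct,
    luminance = c(background = luminance(bg_spd, grid = grid),
                  pulse = luminance(pu_spd, grid = grid)),
    problem = problem, success = success), class = "stimulus_pair")
}

#' @export
print.stimulus_pair <- function(x, ...) {
  cat("<stimulus_pair>\n")
  if (!is.na(x$success)) cat("  solver success:", x$success, "\n")
  cat(sprintf("  luminance: background %.4g, pulse %.4g cd/m^2\n",
              x$luminance["background"], x$luminance["pulse"]))
  print(x$contrasts)
  invisible(x)
}

#' Verify a stimulus pair against its design constraints
#'
#' Recomputes contrasts from the pair's spectra and checks each silenced
#' receptor against the tolerance and the target against the design goal.
#'
#' @param pair A [stimulus_pair].
#' @param problem A [ss_problem] (defaults to the one stored in the pair).
#' @param target_min For `mode = "maximize"`: minimum acceptable target
#'   contrast (%; default 200).
#' @param match_tol For `mode = "match"`: allowed deviation of the summary
#'   target contrast from `match_contrast` (percentage points, default 5).
#' @return List of class `pair_verification` with per-constraint pass flags,
#'   the recomputed contrasts and luminances, and overall `pass`.
#' @export
verify_pair <- function(pair, problem = pair$problem,
                        target_min = 200, match_tol = 5) {
  stopifnot(inherits(pair, "stimulus_pair"))
  if (is.null(problem)) stop("no design problem available to verify against")
  ct <- stimulus_contrasts(pair,
                           receptors = union(problem$target,
                                             problem$silenced),
                           sensitivities = problem$sensitivities)
  silenced_ok <- abs(ct[problem$silenced]) <= problem$tolerance
  summary_target <- mean(ct[problem$target])
  target_ok <- if (problem$mode == "maximize") summary_target >= target_min
               else abs(summary_target - problem$match_contrast) <= match_tol
  structure(list(contrasts = ct, summary_target = summary_target,
                 silenced_ok = silenced_ok, target_ok = target_ok,
                 luminance = pair$luminance,
                 pass = all(silenced_ok) && target_ok),
            class = "pair_verification")
}

#' @export
print.pair_verification <- function(x, ...) {
  cat("<pair_verification> pass:", x$pass, "\n")
  print(round(unclass(x$contrasts), 3))
  cat(sprintf("  summary target contrast: %.2f%%\n", x$summary_target))
  invisible(x)
}

#' Narrowband pair matched for unweighted total radiance
#'
#' Takes two primaries at full drive and scales the level of the one with
#' the larger unweighted total radiance (trapezoidal integral over 380-780
#' nm) so both deliver the same total radiance; all other primaries off.
#'
#' @param cal A [device_calibration].
#' @param primary_red,primary_blue Primary indices (1-based).
#' @return List with `red` and `blue` [spectrum] objects, the settings
#'   vectors (`red_settings`, `blue_settings`), and the matched
#'   `total_radiance`.
#' @export
narrowband_pair <- function(cal, primary_red, primary_blue) {
  stopifnot(inherits(cal, "device_calibration"))
  np <- n_primaries(cal)
  if (primary_red > np || primary_blue > np)
    stop("primary index out of range")
  total_at <- function(idx, lev) {
    s <- numeric(np); s[idx] <- lev
    spd <- predict_spd(cal, s)
    list(spd = spd, total = pracma::trapz(spd$wavelength, spd$value))
  }
  red_full <- total_at(primary_red, 1)
  blue_full <- total_at(primary_blue, 1)
  red_lev <- 1; blue_lev <- 1
  target <- min(red_full$total, blue_full$total)
  if (target <= 0) stop("a primary has zero total radiance; cannot match")
  # bisect the larger primary's level down to the common total radiance
  match_level <- function(idx, target) {
    f <- function(l) total_at(idx, l)$total - target
    stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  }
  if (red_full$total > target + 1e-15 * target)
    red_lev <- match_level(primary_red, target)
  if (blue_full$total > target + 1e-15 * target)
    blue_lev <- match_level(primary_blue, target)
  red <- total_at(primary_red, red_lev)
  blue <- total_at(primary_blue, blue_lev)
  rs <- numeric(np); rs[primary_red] <- red_lev
  bs <- numeric(np); bs[primary_blue] <- blue_lev
  list(red = red$spd, blue = blue$spd,
       red_settings = rs, blue_settings = bs,
       total_radiance = c(red = red$total, blue = blue$total))
}
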