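#' Spectral radiance on a wavelength grid
#'
#' A `spectrum` is the package's basic radiometric object: spectral radiance
#' (W m^-2 sr^-1 nm^-1) sampled on a strictly increasing wavelength grid in
#' nanometres. The canonical analysis grid is 380-780 nm at 1 nm.
#'
#' @param wavelength Numeric vector of wavelengths (nm), strictly increasing.
#' @param value Numeric vector of spectral radiance, same length as
#'   `wavelength`. Small negative values (measurement noise) are permitted at
#'   construction; integration clips them to zero unless asked not to.
#' @return An object of class `spectrum`: a list with elements `wavelength`
#'   and `value`.
#' @examples
#' s <- spectrum(380:780, rep(0.01, 401))
#' luminance(s)
#' @export
spectrum <- function(wavelength, value) {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have equal length")
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least two samples")
  if (any(!is.finite(wavelength)) || any(!is.finite(value)))
    stop("wavelength and value must be finite")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(wavelength = wavelength, value = value), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d samples, %g-%g nm, peak %.4g W m-2 sr-1 nm-1>\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              max(x$value)))
  invisible(x)
}

#' Canonical analysis wavelength grid
#'
#' 380-780 nm at the given step. All alpha-opic integrals are evaluated on
#' this grid after linear resampling.
#'
#' @param step Grid spacing in nm (default 1).
#' @return Numeric vector of wavelengths.
#' @export
canonical_grid <- function(step = 1) seq(380, 780, by = step)

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation; wavelengths outside the source support get radiance
#' zero (a measured spectrum is taken to vanish outside its measured band).
#'
#' @param x A [spectrum].
#' @param grid Target wavelength grid (nm), strictly increasing.
#' @return A [spectrum] on `grid`.
#' @export
resample_spectrum <- function(x, grid) {
  stopifnot(inherits(x, "spectrum"))
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("target grid is empty")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("target grid must be strictly increasing")
  v <- stats::approx(x$wavelength, x$value, xout = grid,
                     method = "linear", yleft = 0, yright = 0)$y
  if (length(grid) < 2L) {
    # single-point resampling used internally; wrap in a 2-point spectrum
    return(v)
  }
  spectrum(grid, v)
}

# Clip small negative radiances (measurement noise) before integrating.
clip_negative <- function(values, clip = TRUE) {
  if (clip) pmax(values, 0) else values
}

#' Alpha-opic radiance of a spectrum
#'
#' Weights the spectral radiance by a photoreceptor's relative spectral
#' sensitivity and integrates over wavelength (trapezoidal rule on the
#' canonical grid), giving radiance in W m^-2 sr^-1.
#'
#' @param x A [spectrum].
#' @param sens A [sensitivity_function], or a receptor name accepted by
#'   [photoreceptor_sensitivity()].
#' @param grid Wavelength grid for the integral (default [canonical_grid()]).
#' @param clip_negatives Clip negative radiances to zero before integrating
#'   (default TRUE).
#' @return Scalar radiance (W m^-2 sr^-1).
#' @export
alphaopic_radiance <- function(x, sens, grid = canonical_grid(),
                               clip_negatives = TRUE) {
  stopifnot(inherits(x, "spectrum"))
  if (is.character(sens)) sens <- photoreceptor_sensitivity(sens)
  stopifnot(inherits(sens, "sensitivity_function"))
  if (min(x$wavelength) > max(sens$wavelength) ||
      max(x$wavelength) < min(sens$wavelength))
    stop("spectrum and sensitivity have disjoint wavelength supports")
  xs <- resample_spectrum(x, grid)
  ss <- stats::approx(sens$wavelength, sens$value, xout = grid,
                      method = "linear", yleft = 0, yright = 0)$y
  pracma::trapz(grid, clip_negative(xs$value, clip_negatives) * ss)
}

#' Photopic luminance of a spectrum
#'
#' `683 * integral of L_e(lambda) V(lambda) dlambda`, in cd m^-2, using the
#' photopic luminosity function (see [photoreceptor_sensitivity()] for the
#' analytic form used).
#'
#' @inheritParams alphaopic_radiance
#' @return Luminance in cd m^-2.
#' @export
luminance <- function(x, grid = canonical_grid(), clip_negatives = TRUE) {
  683 * alphaopic_radiance(x, photoreceptor_sensitivity("V_photopic"),
                           grid = grid, clip_negatives = clip_negatives)
}

#' Weber contrast between a pulse and its background
#'
#' `100 * (pulse - background) / background`, in percent; the sign of the
#' modulation is preserved.
#'
#' @param pulse,background Scalar radiances (same units); `background` must
#'   be strictly positive.
#' @return Contrast in percent.
#' @export
weber_contrast <- function(pulse, background) {
  if (!is.finite(background) || background <= 0)
    stop("Weber contrast needs background radiance > 0")
  100 * (pulse - background) / background
}

#' Per-opsin Weber contrasts of a stimulus pair
#'
#' Computes alpha-opic radiances of the background and pulse spectra and the
#' resulting Weber contrast for each requested receptor. Scale-invariant:
#' scaling both spectra by a common positive factor leaves all contrasts
#' unchanged.
#'
#' @param pair A [stimulus_pair], or a list with elements `background` and
#'   `pulse`, both [spectrum] objects.
#' @param receptors Character vector of receptor names (default melanopsin
#'   and the three cones).
#' @param grid Integration grid.
#' @param sensitivities Optional named list of [sensitivity_function]
#'   objects overriding the standard curves for the named receptors.
#' @return Named numeric vector of contrasts (%), class `contrast_set`.
#' @export
stimulus_contrasts <- function(pair,
                               receptors = c("melanopsin", "L", "M", "S"),
                               grid = canonical_grid(),
                               sensitivities = NULL) {
  bg <- pair$background_spectrum %||% pair$background
  pu <- pair$pulse_spectrum %||% pair$pulse
  stopifnot(inherits(bg, "spectrum"), inherits(pu, "spectrum"))
  out <- vapply(receptors, function(r) {
    s <- resolve_sensitivity(r, sensitivities)
    weber_contrast(alphaopic_radiance(pu, s, grid = grid),
                   alphaopic_radiance(bg, s, grid = grid))
  }, numeric(1))
  structure(out, class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat("Weber contrasts (%):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
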