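#' Photoreceptor spectral sensitivity functions
#'
#' Relative (peak-normalized) spectral sensitivities for the five human
#' photoreceptor classes plus the photopic luminosity function. The opsin
#' curves are generated from the Govardovskii et al. (2000) A1 visual-pigment
#' nomogram (alpha + beta absorbance bands) evaluated at the field-standard
#' alpha-opic peak wavelengths:
#'
#' | receptor     | peak (nm) |
#' |--------------|-----------|
#' | S            | 448       |
#' | melanopsin   | 490       |
#' | rhodopsin    | 507       |
#' | M            | 542       |
#' | L            | 570       |
#'
#' These are synthetic nomogram approximations of the standard 10-degree
#' alpha-opic sensitivities, not the published tabulations; they reproduce
#' the heavy spectral overlap between melanopsin and the cones that makes
#' silent substitution necessary, which is what the design and contrast
#' machinery depends on. The photopic luminosity function uses the standard
#' closed-form approximation `1.019 * exp(-285.4 * (lambda_um - 0.559)^2)`.
#'
#' @param receptor One of `"L"`, `"M"`, `"S"`, `"melanopsin"`,
#'   `"rhodopsin"`, `"V_photopic"`.
#' @param grid Wavelength grid (nm) on which to evaluate (default
#'   [canonical_grid()]).
#' @return An object of class `sensitivity_function`: list with `receptor`,
#'   `wavelength`, `value` (unitless, peak-normalized, in `[0, 1]`).
#' @examples
#' mel <- photoreceptor_sensitivity("melanopsin")
#' mel$wavelength[which.max(mel$value)]
#' @export
photoreceptor_sensitivity <- function(receptor = c("L", "M", "S",
                                                   "melanopsin", "rhodopsin",
                                                   "V_photopic"),
                                      grid = canonical_grid()) {
  receptor <- match.arg(receptor)
  peaks <- c(L = 570, M = 542, S = 448, melanopsin = 490, rhodopsin = 507)
  v <- if (receptor == "V_photopic") {
    um <- grid / 1000
    1.019 * exp(-285.4 * (um - 0.559)^2)
  } else {
    govardovskii_template(grid, peaks[[receptor]])
  }
  v <- v / max(v)
  structure(list(receptor = receptor, wavelength = grid, value = v),
            class = "sensitivity_function")
}

# Govardovskii et al. (2000) A1 pigment template: alpha band as a sum of
# exponentials in x = lambda_max / lambda, plus a Gaussian beta band.
govardovskii_template <- function(wavelength, lambda_max) {
  x <- lambda_max / wavelength
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  bwd <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((wavelength - lmb) / bwd)^2)
  alpha + beta
}

#' @export
print.sensitivity_function <- function(x, ...) {
  cat(sprintf("<sensitivity_function: %s, %g-%g nm, peak at %g nm>\n",
              x$receptor, min(x$wavelength), max(x$wavelength),
              x$wavelength[which.max(x$value)]))
  invisible(x)
}

#' Standard receptor set used in stimulus design
#'
#' @return Character vector: melanopsin plus the three cone opsins.
#' @export
default_receptors <- function() c("melanopsin", "L", "M", "S")
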