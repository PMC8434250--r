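# Pseudo-Voigt band model: linear mix of Gaussian and Lorentzian profiles
# sharing center, height and FWHM; mixing fraction eta in [0, 1]
# (0 = pure Gaussian, 1 = pure Lorentzian).

#' Construct a peak component
#'
#' @param center band center, cm-1.
#' @param height peak height, arbitrary (typically 1460-normalized) units.
#' @param fwhm full width at half maximum, cm-1 (> 0).
#' @param eta Lorentzian fraction in [0, 1].
#' @return a one-row data frame of class `peak_component` with columns
#'   `center`, `height`, `fwhm`, `eta`, `area` (closed-form, infinite
#'   support).
#' @export
peak_component <- function(center, height, fwhm, eta = 0) {
  n <- max(length(center), length(height), length(fwhm), length(eta))
  center <- rep_len(center, n); height <- rep_len(height, n)
  fwhm <- rep_len(fwhm, n); eta <- rep_len(eta, n)
  if (any(fwhm <= 0)) stop("fwhm must be > 0", call. = FALSE)
  if (any(height < 0)) stop("height must be >= 0", call. = FALSE)
  if (any(eta < 0 | eta > 1)) stop("eta must lie in [0, 1]", call. = FALSE)
  out <- data.frame(center = center, height = height, fwhm = fwhm, eta = eta)
  out$area <- component_area(out)
  class(out) <- c("peak_component", "data.frame")
  out
}

#' Closed-form pseudo-Voigt band area
#'
#' Area on infinite support:
#' `eta * (pi/2) * h * w  +  (1 - eta) * h * w * sqrt(pi / (4 log 2))`,
#' i.e. the Lorentzian and Gaussian areas weighted by the mixing fraction.
#'
#' @param c a `peak_component` (or any data frame with `height`, `fwhm`,
#'   `eta` columns).
#' @return numeric vector of areas in a.u. * cm-1.
#' @export
component_area <- function(c) {
  with(c, eta * (pi / 2) * height * fwhm +
         (1 - eta) * height * fwhm * sqrt(pi / (4 * log(2))))
}

#' Evaluate pseudo-Voigt profiles
#'
#' @param x wavenumbers, cm-1.
#' @param center,height,fwhm,eta band parameters (vectorized over bands).
#' @return if one band, a numeric vector over `x`; if several, the sum of
#'   all band profiles at each `x`.
#' @export
pseudo_voigt <- function(x, center, height, fwhm, eta = 0) {
  n <- max(length(center), length(height), length(fwhm), length(eta))
  center <- rep_len(center, n); height <- rep_len(height, n)
  fwhm <- rep_len(fwhm, n); eta <- rep_len(eta, n)
  y <- numeric(length(x))
  for (i in seq_len(n)) {
    u <- (x - center[i]) / fwhm[i]
    g <- exp(-4 * log(2) * u^2)
    l <- 1 / (1 + 4 * u^2)
    y <- y + height[i] * (eta[i] * l + (1 - eta[i]) * g)
  }
  y
}

# evaluate the composite model of a component table plus linear baseline
eval_components <- function(x, comps, b0 = 0, b1 = 0, x0 = 0) {
  pseudo_voigt(x, comps$center, comps$height, comps$fwhm, comps$eta) +
    b0 + b1 * (x - x0)
}
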