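# Preprocessing chain: replicate averaging, cropping, fluorescence baseline
# correction, reference-band normalization, Savitzky-Golay derivatives.

#' Average replicate spectra on a common grid
#'
#' Replicates are linearly interpolated onto a common uniform grid spanning
#' the intersection of their axis ranges; the pointwise mean and sample
#' (n-1) standard deviation are returned. Quantitative work in this field
#' conventionally averages at least three independent acquisitions and
#' expects the replicate SD to stay below 5% of the local mean; the returned
#' `sd_warning` flag reports whether that bound was exceeded anywhere the
#' mean signal is appreciable (> 1% of the maximum, to avoid flagging
#' near-zero baseline points).
#'
#' @param spectra list of [raman_spectrum] replicates (>= 1).
#' @param grid_step grid spacing in cm-1; default is the median native
#'   spacing of the first replicate.
#' @param sd_limit relative-SD warning threshold (fraction of local mean).
#' @return list with `mean` (a [raman_spectrum]), `sd` (numeric profile on
#'   the same grid), `n`, and logical `sd_warning`.
#' @export
average_replicates <- function(spectra, grid_step = NULL, sd_limit = 0.05) {
  if (!length(spectra)) stop("empty replicate list", call. = FALSE)
  lapply(spectra, validate_spectrum)
  lo <- max(vapply(spectra, function(s) min(s$wavenumber), 0))
  hi <- min(vapply(spectra, function(s) max(s$wavenumber), 0))
  if (lo >= hi) stop("replicate axes do not overlap", call. = FALSE)
  if (is.null(grid_step))
    grid_step <- stats::median(diff(spectra[[1]]$wavenumber))
  grid <- seq(lo, hi, by = grid_step)
  ymat <- vapply(spectra, function(s)
    stats::approx(s$wavenumber, s$intensity, xout = grid)$y, numeric(length(grid)))
  ymat <- matrix(ymat, nrow = length(grid))
  mu <- rowMeans(ymat)
  sdv <- if (ncol(ymat) > 1) apply(ymat, 1, stats::sd) else rep(0, length(grid))
  # relative SD judged against the local mean, floored at 10% of the
  # spectrum maximum so near-zero baseline points cannot trip the flag
  ref <- pmax(abs(mu), 0.1 * max(abs(mu)))
  warn <- any(sdv > sd_limit * ref)
  if (warn)
    warning("replicate SD exceeds ", 100 * sd_limit, "% of local mean",
            call. = FALSE)
  out <- raman_spectrum(grid, mu, meta = spectra[[1]]$meta)
  out <- add_provenance(out, sprintf("averaged %d replicates, step %.4g",
                                     length(spectra), grid_step))
  list(mean = out, sd = sdv, n = length(spectra), sd_warning = warn)
}

#' Crop a spectrum to a wavenumber region
#'
#' Keeps points with `lo <= wavenumber <= hi` (closed interval).
#'
#' @param s a [raman_spectrum].
#' @param region numeric `c(lo, hi)` in cm-1.
#' @return cropped [raman_spectrum]; error if the region contains no points.
#' @export
crop_spectrum <- function(s, region) {
  validate_spectrum(s)
  stopifnot(length(region) == 2, region[1] < region[2])
  keep <- s$wavenumber >= region[1] & s$wavenumber <= region[2]
  if (!any(keep))
    stop(sprintf("crop region [%g, %g] contains no points", region[1], region[2]),
         call. = FALSE)
  out <- raman_spectrum(s$wavenumber[keep], s$intensity[keep], meta = s$meta)
  add_provenance(out, sprintf("cropped to [%g, %g]", region[1], region[2]))
}

#' Fluorescence baseline correction through anchor-window minima
#'
#' Finds the minimum-intensity point inside each anchor window, fits a
#' linear or low-order polynomial baseline through those anchor points by
#' least squares, and subtracts it. This removes the broad fluorescence
#' background that dominates FT-Raman spectra of plant material while
#' leaving band shapes untouched, provided the anchors sit in band-free
#' regions.
#'
#' @param s a [raman_spectrum].
#' @param kind `"linear"` or `"polynomial"`.
#' @param anchor_windows list of `c(lo, hi)` windows whose intensity minima
#'   anchor the fit; >= 2 for linear, >= degree+1 for polynomial.
#' @param degree polynomial degree (<= 5), used when `kind = "polynomial"`.
#' @return list with `spectrum` (corrected) and `baseline` (a list holding
#'   `kind`, `coefficients` in increasing power order, `anchor_windows`,
#'   and the anchor points used).
#' @export
baseline_correct <- function(s, kind = c("linear", "polynomial"),
                             anchor_windows, degree = 3) {
  validate_spectrum(s)
  kind <- match.arg(kind)
  if (kind == "polynomial" && degree > 5)
    stop("polynomial baseline degree must be <= 5", call. = FALSE)
  deg <- if (kind == "linear") 1L else as.integer(degree)
  if (length(anchor_windows) < deg + 1)
    stop("need at least ", deg + 1, " anchor windows", call. = FALSE)
  anchors <- t(vapply(anchor_windows, function(w) {
    idx <- which(s$wavenumber >= w[1] & s$wavenumber <= w[2])
    if (!length(idx)) stop(sprintf("anchor window [%g, %g] empty", w[1], w[2]),
                           call. = FALSE)
    i <- idx[which.min(s$intensity[idx])]
    c(s$wavenumber[i], s$intensity[i])
  }, numeric(2)))
  if (length(unique(anchors[, 1])) < deg + 1)
    stop("degenerate anchor points (coincident wavenumbers)", call. = FALSE)
  # centre the axis for numerical conditioning of the polynomial fit
  x0 <- mean(s$wavenumber)
  fit <- stats::lm.fit(outer(anchors[, 1] - x0, 0:deg, `^`), anchors[, 2])
  bl <- drop(outer(s$wavenumber - x0, 0:deg, `^`) %*% fit$coefficients)
  out <- raman_spectrum(s$wavenumber, s$intensity - bl, meta = s$meta)
  out <- add_provenance(out, sprintf("baseline corrected (%s, %d anchors)",
                                     kind, nrow(anchors)))
  list(spectrum = out,
       baseline = list(kind = kind, coefficients = unname(fit$coefficients),
                       center = x0, anchor_windows = anchor_windows,
                       anchors = anchors))
}

#' Normalize to a reference band
#'
#' Divides all intensities by the maximum intensity found in a search window
#' around the reference band, so that spectra recorded at different laser
#' powers or accumulation counts become comparable. The canonical reference
#' for cereal/protein FT-Raman work is the C-H deformation band near
#' 1460 cm-1, present in every sample.
#'
#' @param s a [raman_spectrum] (normally baseline-corrected first).
#' @param ref_center reference band position, cm-1.
#' @param search_window `c(lo, hi)` window searched for the band maximum;
#'   default `ref_center + c(-10, 10)`.
#' @return list with `spectrum` (normalized; maximum in the window equals 1)
#'   and `record` (`ref_center`, `search_window`, `divisor`).
#' @export
normalize_to_band <- function(s, ref_center = 1460, search_window = NULL) {
  validate_spectrum(s)
  if (is.null(search_window)) search_window <- ref_center + c(-10, 10)
  idx <- which(s$wavenumber >= search_window[1] & s$wavenumber <= search_window[2])
  if (!length(idx))
    stop("search window outside spectrum axis", call. = FALSE)
  divisor <- max(s$intensity[idx])
  if (!is.finite(divisor) || divisor <= 0)
    stop("no positive reference band in window [", search_window[1], ", ",
         search_window[2], "]", call. = FALSE)
  out <- raman_spectrum(s$wavenumber, s$intensity / divisor, meta = s$meta)
  out <- add_provenance(out, sprintf("normalized to band at %g (divisor %.6g)",
                                     ref_center, divisor))
  list(spectrum = out,
       record = list(ref_center = ref_center, search_window = search_window,
                     divisor = divisor))
}

# Average intensities within contiguous wavenumber bins of the given step;
# a noise-reducing coarsening used before derivative-based peak seeding.
bin_uniform <- function(s, step) {
  br <- seq(min(s$wavenumber), max(s$wavenumber) + step, by = step)
  f <- cut(s$wavenumber, br, right = FALSE)
  keep <- tabulate(f, nbins = nlevels(f)) > 0
  wn <- as.numeric(tapply(s$wavenumber, f, mean))[keep]
  it <- as.numeric(tapply(s$intensity, f, mean))[keep]
  raman_spectrum(wn, it, meta = s$meta)
}

# Resample to a uniform grid by linear interpolation; step defaults to the
# median native spacing. Returns the spectrum unchanged if already uniform.
resample_uniform <- function(s, step = NULL) {
  d <- diff(s$wavenumber)
  if (is.null(step)) step <- stats::median(d)
  if (max(abs(d - step)) < 1e-9 * step) return(s)
  grid <- seq(min(s$wavenumber), max(s$wavenumber), by = step)
  raman_spectrum(grid, stats::approx(s$wavenumber, s$intensity, xout = grid)$y,
                 meta = s$meta)
}

#' Smoothed second derivative
#'
#' Savitzky-Golay second derivative: the spectrum is resampled to a uniform
#' grid if necessary, then filtered with a local polynomial of order
#' `poly_order` over `smooth_window` points, evaluated at its second
#' derivative. Local minima of the result mark the centers of overlapped
#' band components and seed the decomposition.
#'
#' @param s a [raman_spectrum].
#' @param smooth_window odd number of points in the filter window; must
#'   exceed `poly_order`.
#' @param poly_order polynomial order (>= 2 so the second derivative exists
#'   exactly for quadratics).
#' @return a [raman_spectrum] holding d2I/dnu2 on the (possibly resampled)
#'   uniform grid.
#' @export
second_derivative <- function(s, smooth_window = 11, poly_order = 3) {
  validate_spectrum(s, strict = TRUE)
  if (smooth_window %% 2 == 0) stop("smooth_window must be odd", call. = FALSE)
  if (poly_order < 2) stop("poly_order must be >= 2", call. = FALSE)
  if (smooth_window <= poly_order)
    stop("smooth_window must exceed poly_order", call. = FALSE)
  s <- resample_uniform(s)
  if (smooth_window > length(s$wavenumber))
    stop("smooth_window larger than spectrum", call. = FALSE)
  h <- s$wavenumber[2] - s$wavenumber[1]
  d2 <- signal::sgolayfilt(s$intensity, p = poly_order, n = smooth_window,
                           m = 2, ts = h)
  raman_spectrum(s$wavenumber, d2, meta = s$meta)
}
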