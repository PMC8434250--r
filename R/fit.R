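# Second-derivative-seeded pseudo-Voigt decomposition of a spectral region
# by bounded Levenberg-Marquardt least squares.

#' Seed band components from second-derivative minima
#'
#' Overlapped band centers appear as local minima of the smoothed second
#' derivative. Each qualifying minimum (negative, with depth at least
#' `min_prominence` of the deepest minimum in the region) yields one seed
#' component centered at the minimum, with height taken from the spectrum at
#' that point and a default per-region seed FWHM.
#'
#' @param s baseline-corrected [raman_spectrum].
#' @param region `c(lo, hi)` cm-1.
#' @param d2 optional precomputed second derivative of `s` on the same grid
#'   (see [second_derivative()]); computed internally when `NULL`.
#' @param min_prominence fraction of the deepest minimum's depth a minimum
#'   must reach to qualify.
#' @param seed_fwhm initial FWHM assigned to every seed, cm-1.
#' @param d2_window derivative smoothing span in cm-1 (converted to the
#'   nearest odd point count for the native grid) when `d2` is computed
#'   internally.
#' @param min_separation minimum distance between seeds, cm-1; of two
#'   qualifying minima closer than this, only the deeper survives. Guards
#'   against noise-split minima on finely sampled spectra.
#' @param bin_step bin width (cm-1) for noise-averaging the spectrum before
#'   the derivative; 0 disables. Binning trades grid resolution for noise
#'   suppression, which matters more than resolution for locating broad,
#'   overlapped bands.
#' @return a `peak_component` data frame (ascending center), `eta = 0`.
#' @export
seed_components <- function(s, region, d2 = NULL, min_prominence = 0.08,
                            seed_fwhm = 12, d2_window = 13,
                            min_separation = 4, bin_step = 1) {
  validate_spectrum(s, strict = TRUE)
  if (is.null(d2)) {
    if (bin_step > 1.5 * stats::median(diff(s$wavenumber)))
      s <- bin_uniform(s, bin_step)
    step <- stats::median(diff(s$wavenumber))
    npts <- max(5L, as.integer(round(d2_window / step)))
    if (npts %% 2 == 0) npts <- npts + 1L
    npts <- min(npts, length(s$wavenumber) - (1 - length(s$wavenumber) %% 2))
    d2 <- second_derivative(s, smooth_window = npts)
  }
  inside <- d2$wavenumber >= region[1] & d2$wavenumber <= region[2]
  x <- d2$wavenumber[inside]
  y <- d2$intensity[inside]
  n <- length(y)
  if (n < 3) stop("region too narrow for seeding", call. = FALSE)
  i <- 2:(n - 1)
  is_min <- y[i] < y[i - 1] & y[i] <= y[i + 1] & y[i] < 0
  cand <- i[is_min]
  if (!length(cand))
    stop("no second-derivative minima in region; supply seeds manually",
         call. = FALSE)
  depth <- -y[cand]
  cand <- cand[depth >= min_prominence * max(depth)]
  # greedy non-maximum suppression: deepest first, drop close neighbours
  if (min_separation > 0 && length(cand) > 1) {
    o <- order(y[cand])
    keep <- integer(0)
    for (i in cand[o]) {
      if (!length(keep) || all(abs(x[i] - x[keep]) >= min_separation))
        keep <- c(keep, i)
    }
    cand <- sort(keep)
  }
  # sub-grid center refinement: parabola through the minimum and its
  # neighbours
  frac <- 0.5 * (y[cand - 1] - y[cand + 1]) /
    (y[cand - 1] - 2 * y[cand] + y[cand + 1])
  frac[!is.finite(frac) | abs(frac) > 1] <- 0
  h_grid <- stats::median(diff(x))
  centers <- x[cand] + frac * h_grid
  inreg <- s$intensity[s$wavenumber >= region[1] & s$wavenumber <= region[2]]
  floor_ <- min(inreg)
  heights <- stats::approx(s$wavenumber, s$intensity, xout = centers)$y - floor_
  heights <- pmax(heights, 1e-6 * max(abs(s$intensity)))
  # Gaussian curvature relation at the apex: d2 = -8 ln2 h / w^2
  w_est <- sqrt(8 * log(2) * heights / pmax(-y[cand], 1e-12))
  w_est[!is.finite(w_est)] <- seed_fwhm
  w_est <- pmin(pmax(w_est, 0.7 * seed_fwhm), 1.3 * seed_fwhm)
  peak_component(centers, heights, fwhm = w_est, eta = 0)
}

#' Decompose a spectral region into pseudo-Voigt bands
#'
#' The central fitting routine: a sum of pseudo-Voigt components (optionally
#' on a local linear baseline) is refined against the data in `region` by
#' bounded Levenberg-Marquardt least squares. Seeds come from
#' [seed_components()] unless supplied. When an [assignment_scheme()] is
#' given, every scheme window is guaranteed at least one seed and each
#' component's center is confined to its window expanded by the scheme
#' tolerance, which prevents label-crossing during refinement.
#'
#' @param s baseline-corrected (and typically normalized) [raman_spectrum].
#' @param region `c(lo, hi)` cm-1 fit region.
#' @param seeds optional `peak_component` seed table; defaults to
#'   second-derivative seeding.
#' @param scheme optional [assignment_scheme()] supplying center windows.
#' @param shape `"gaussian"` (default), `"lorentzian"`, or `"pseudo_voigt"`
#'   (eta fitted per band).
#' @param baseline fit a local linear baseline over the region (`TRUE`) or
#'   assume the region is already flat (`FALSE`).
#' @param fwhm_limits `c(min, max)` bounds on component FWHM, cm-1;
#'   `NULL` uses `c(3, min(60, diff(region) / 2))` so no single band can
#'   masquerade as the regional background.
#' @param center_slack half-width of the center bound when no scheme is
#'   given and a component has no neighbours to define one, cm-1.
#' @param control list: `ftol` relative-cost convergence tolerance,
#'   `maxiter` iteration cap.
#' @param restarts number of extra deterministic perturbed-seed starts
#'   tried when the first refinement lands in a poor local minimum; the
#'   lowest-cost solution wins. Restarting stops early once the composite
#'   correlates with the data at r >= 0.9999 or two successive starts fail
#'   to improve the cost.
#' @param ... passed to [seed_components()] when seeding internally.
#' @return an object of class `band_fit`; see Details.
#' @details The returned object has elements `components` (refined
#'   `peak_component` table, ascending center, closed-form areas),
#'   `baseline` (`b0`, `b1`, `x0` of the local line, or `NULL`), `data`
#'   (the cropped spectrum), `fitted_curve`, `pearson_r` (correlation of
#'   composite and data over the region), `residual_rms`, `converged`,
#'   `n_iterations`, `n_pinned` (components driven to zero height),
#'   `region`, `shape`.
#'   Methods: `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`,
#'   `plot`, `simulate`.
#' @examples
#' truth <- peak_component(c(520, 540), c(1, 0.6), c(10, 12))
#' x <- seq(495, 565, by = 0.5)
#' s <- raman_spectrum(x, pseudo_voigt(x, truth$center, truth$height,
#'                                     truth$fwhm, truth$eta))
#' f <- fit_bands(s, c(500, 560), seeds = truth)
#' summary(f)
#' @export
fit_bands <- function(s, region, seeds = NULL, scheme = NULL,
                      shape = c("gaussian", "lorentzian", "pseudo_voigt"),
                      baseline = TRUE, fwhm_limits = NULL,
                      center_slack = 5,
                      control = list(ftol = 1e-10, maxiter = 500),
                      restarts = 8, ...) {
  shape <- match.arg(shape)
  cl <- match.call()
  if (is.null(fwhm_limits))
    fwhm_limits <- c(3, min(60, diff(range(region)) / 2))
  sr <- crop_spectrum(s, region)
  if (is.null(seeds)) seeds <- seed_components(s, region, ...)
  if (!nrow(seeds)) stop("no seeds", call. = FALSE)
  if (any(seeds$center < region[1] | seeds$center > region[2]))
    stop("seeds outside fit region", call. = FALSE)
  seeds <- seeds[order(seeds$center), , drop = FALSE]
  if (!is.null(scheme)) seeds <- ensure_window_seeds(seeds, scheme, sr)

  ymax <- max(abs(sr$intensity))
  fit_eta <- shape == "pseudo_voigt"
  x0 <- mean(range(sr$wavenumber))
  sdy_data <- stats::sd(sr$intensity)
  # robust high-frequency noise estimate (fourth differences cancel the
  # smooth signal almost completely): the fit residual cannot beat this
  # floor, so reaching it means the decomposition explains the data
  noise_floor <- stats::mad(diff(sr$intensity, differences = 4)) / sqrt(70)
  rms_target <- 1.2 * max(noise_floor, 1e-8 * sdy_data)
  npts <- length(sr$intensity)
  ctrl <- minpack.lm::nls.lm.control(
    ftol = control$ftol %||% 1e-10, ptol = 1e-10,
    maxiter = min(control$maxiter %||% 500, 1024),
    maxfev = 200000)

  # center box per seed: assignment window (+ tolerance) under a scheme,
  # otherwise half the distance to the neighbouring seed
  bounds_for <- function(sd_tab) {
    if (!is.null(scheme)) {
      win <- scheme_window_of(sd_tab$center, scheme)
      e <- scheme$entries
      j <- match(win$label, e$label)
      flo <- e$fit_lo[j]
      fhi <- e$fit_hi[j]
      list(lo = ifelse(is.na(win$lo),
                       pmax(region[1], sd_tab$center - center_slack),
                       flo - scheme$tolerance),
           hi = ifelse(is.na(win$hi),
                       pmin(region[2], sd_tab$center + center_slack),
                       fhi + scheme$tolerance))
    } else {
      k <- nrow(sd_tab)
      gap <- if (k > 1) diff(sd_tab$center) else numeric(0)
      half <- if (k > 1)
        pmin(c(gap[1], pmin(gap[-length(gap)], gap[-1]), gap[length(gap)]),
             2 * center_slack) / 2
      else rep(center_slack, 1)
      half <- pmax(half, 1)
      list(lo = pmax(region[1], sd_tab$center - half),
           hi = pmin(region[2], sd_tab$center + half))
    }
  }

  # one bounded Levenberg-Marquardt refinement from a seed table
  fit_once <- function(sd_tab, ftol = NULL) {
    if (!is.null(ftol)) {
      ctrl <- minpack.lm::nls.lm.control(ftol = ftol, ptol = ftol,
                                         maxiter = 1024, maxfev = 200000)
    }
    k <- nrow(sd_tab)
    bx <- bounds_for(sd_tab)
    ctr0 <- pmin(pmax(sd_tab$center, bx$lo), bx$hi)
    eta0 <- switch(shape, gaussian = rep(0, k), lorentzian = rep(1, k),
                   pseudo_voigt = pmin(pmax(sd_tab$eta, 0.01), 0.99))
    par <- c(ctr0, pmax(sd_tab$height, 1e-6 * ymax),
             pmin(pmax(sd_tab$fwhm, fwhm_limits[1]), fwhm_limits[2]))
    lower <- c(bx$lo, rep(0, k), rep(fwhm_limits[1], k))
    upper <- c(bx$hi, rep(3 * ymax, k), rep(fwhm_limits[2], k))
    if (fit_eta) {
      par <- c(par, eta0); lower <- c(lower, rep(0, k))
      upper <- c(upper, rep(1, k))
    }
    if (baseline) {
      par <- c(par, 0, 0)
      lower <- c(lower, -Inf, -Inf); upper <- c(upper, Inf, Inf)
    }
    unpack <- function(p) {
      comps <- data.frame(center = p[1:k], height = p[(k + 1):(2 * k)],
                          fwhm = p[(2 * k + 1):(3 * k)],
                          eta = if (fit_eta) p[(3 * k + 1):(4 * k)]
                                else rep(switch(shape, gaussian = 0,
                                                lorentzian = 1), k))
      nb <- 3 * k + fit_eta * k
      b <- if (baseline) p[(nb + 1):(nb + 2)] else c(0, 0)
      list(comps = comps, b0 = b[1], b1 = b[2])
    }
    resid_fn <- function(p) {
      u <- unpack(p)
      sr$intensity - eval_components(sr$wavenumber, u$comps, u$b0, u$b1, x0)
    }
    # analytic Jacobian of the residual (negative model gradient)
    jac_fn <- function(p) {
      u <- unpack(p)
      x <- sr$wavenumber
      J <- matrix(0, length(x), length(p))
      c8 <- 8 * log(2)
      for (i in seq_len(k)) {
        ui <- (x - u$comps$center[i]) / u$comps$fwhm[i]
        g <- exp(-4 * log(2) * ui^2)
        l <- 1 / (1 + 4 * ui^2)
        et <- u$comps$eta[i]; h <- u$comps$height[i]; w <- u$comps$fwhm[i]
        shape <- et * l + (1 - et) * g
        dc <- h * (et * l^2 * 8 * ui / w + (1 - et) * g * c8 * ui / w)
        dw <- h * (et * l^2 * 8 * ui^2 / w + (1 - et) * g * c8 * ui^2 / w)
        J[, i] <- -dc
        J[, k + i] <- -shape
        J[, 2 * k + i] <- -dw
        if (fit_eta) J[, 3 * k + i] <- -h * (l - g)
      }
      if (baseline) {
        nb <- 3 * k + fit_eta * k
        J[, nb + 1] <- -1
        J[, nb + 2] <- -(x - x0)
      }
      J
    }
    res <- minpack.lm::nls.lm(par, lower = lower, upper = upper,
                              fn = resid_fn, jac = jac_fn, control = ctrl)
    list(res = res, u = unpack(res$par))
  }

  jitter_seeds <- function(sd_tab) {
    k <- nrow(sd_tab)
    sd_tab$center <- pmin(pmax(sd_tab$center + stats::runif(k, -3, 3),
                               region[1]), region[2])
    sd_tab$height <- sd_tab$height * stats::runif(k, 0.5, 1.5)
    sd_tab$fwhm <- pmin(pmax(sd_tab$fwhm * stats::runif(k, 0.6, 1.5),
                             fwhm_limits[1]), fwhm_limits[2])
    sd_tab
  }

  # a seeding-independent start: one band per scheme window at its
  # midpoint, height read off the spectrum
  canonical_tab <- if (!is.null(scheme)) {
    e <- scheme$entries
    ctr <- (e$fit_lo + e$fit_hi) / 2
    ok <- ctr >= min(sr$wavenumber) & ctr <= max(sr$wavenumber)
    if (any(ok)) {
      h <- stats::approx(sr$wavenumber, sr$intensity, xout = ctr[ok])$y
      peak_component(ctr[ok], pmax(h - min(sr$intensity), 1e-6 * ymax),
                     mean(fwhm_limits), 0)
    }
  }

  # deterministic multistart over seed tables; keep the lowest cost, stop
  # once the residual reaches the noise floor or improvement stalls
  rs_seed <- as.integer(sum(region) * 97 + nrow(seeds)) %% 2147483647L
  tabs <- c(list(seeds),
            if (!is.null(canonical_tab)) list(canonical_tab),
            if (restarts > 0) with_seed(rs_seed, lapply(seq_len(restarts),
              function(j) jitter_seeds(seeds))))
  best <- NULL
  stalled <- 0
  for (tb in tabs) {
    cand <- fit_once(tb)
    if (is.null(best) || cand$res$deviance < best$res$deviance * (1 - 1e-4)) {
      if (!is.null(best)) stalled <- 0
      if (is.null(best) || cand$res$deviance < best$res$deviance) best <- cand
    } else {
      stalled <- stalled + 1
    }
    if (sqrt(best$res$deviance / npts) <= rms_target || stalled >= 3) break
  }

  # extra-sum-of-squares F-test between nested component counts; returns
  # the p-value of the larger model's improvement
  ftest_p <- function(rss_small, rss_big, q, p_big) {
    df2 <- npts - p_big
    if (df2 <= 0 || rss_big <= 0) return(0)
    f <- ((rss_small - rss_big) / q) / (rss_big / df2)
    stats::pf(max(f, 0), q, df2, lower.tail = FALSE)
  }
  n_par <- function(k) (3 + fit_eta) * k + 2 * baseline

  # repair pass: an under-resolved fit often hides two bands inside one
  # broad component. Split a large component in two and refit; keep the
  # split only when it explains genuine structure (residual reaches the
  # noise floor, or the added band is overwhelmingly significant), so
  # noise is never chased with spurious extra bands.
  split_seed <- function(cc, j) {
    child <- cc[c(j, j), ]
    child$center <- cc$center[j] + c(-1, 1) * cc$fwhm[j] / 4
    child$height <- cc$height[j] * 0.65
    child$fwhm <- max(cc$fwhm[j] * 0.6, fwhm_limits[1])
    tb2 <- rbind(cc[-j, ], child)
    tb2$center <- pmin(pmax(tb2$center, region[1]), region[2])
    tb2[order(tb2$center), , drop = FALSE]
  }
  for (split_try in seq_len(3)) {
    if (sqrt(best$res$deviance / npts) <= rms_target) break
    cc <- best$u$comps
    # candidate seed tables: a band where the (smoothed) residual is
    # largest -- a band the seeding missed leaves a coherent positive
    # residual bump -- and splits of the two largest components
    tabs_try <- list()
    rsd <- sr$intensity - eval_components(sr$wavenumber, cc,
                                          best$u$b0, best$u$b1, x0)
    rsd_s <- stats::filter(rsd, rep(1 / 9, 9), sides = 2)
    rsd_s[is.na(rsd_s)] <- 0
    i_max <- which.max(rsd_s)
    if (rsd_s[i_max] > 0) {
      add <- peak_component(min(max(sr$wavenumber[i_max], region[1]),
                                region[2]),
                            max(rsd_s[i_max], 1e-6 * ymax),
                            mean(fwhm_limits) / 1.5, 0)
      tb_add <- rbind(cc, as.data.frame(add)[, names(cc)])
      tabs_try <- c(tabs_try, list(tb_add[order(tb_add$center), ]))
    }
    areas <- cc$height * cc$fwhm
    for (j in utils::head(order(areas, decreasing = TRUE), 2)) {
      if (is.finite(areas[j]) && areas[j] > 0)
        tabs_try <- c(tabs_try, list(split_seed(cc, j)))
    }
    # evaluate all structural candidates; keep the best admissible one
    winner <- NULL
    for (tb2 in tabs_try) {
      cand <- tryCatch(fit_once(tb2), error = function(e) NULL)
      if (is.null(cand) || cand$res$deviance >= best$res$deviance) next
      p_c <- ftest_p(best$res$deviance, cand$res$deviance,
                     3 + fit_eta, n_par(nrow(cc) + 1))
      at_floor <- sqrt(cand$res$deviance / npts) <= rms_target
      if (!(at_floor || p_c < 1e-6)) next
      if (is.null(winner) || cand$res$deviance < winner$res$deviance)
        winner <- cand
      if (at_floor) break
    }
    if (is.null(winner)) break
    best <- winner
  }

  # last-resort basin hops: jitter the current best solution itself
  for (extra in seq_len(3)) {
    if (sqrt(best$res$deviance / npts) <= rms_target) break
    tb <- with_seed(rs_seed + extra, jitter_seeds(best$u$comps))
    cand <- tryCatch(fit_once(tb), error = function(e) NULL)
    if (!is.null(cand) && cand$res$deviance < best$res$deviance)
      best <- cand
  }

  # parsimony passes: drop or merge components the data do not require
  # (the residual stays essentially at the noise floor without them).
  # Restores identifiability when seeding or splitting produced more bands
  # than the spectrum supports.
  # a simpler model is kept when it costs essentially nothing (residual
  # unchanged) or when the removed band is statistically unsupported
  accept_rms <- function(cand, q = 3 + fit_eta) {
    if (is.null(cand)) return(FALSE)
    if (sqrt(cand$res$deviance / npts) <=
        1.001 * sqrt(best$res$deviance / npts)) return(TRUE)
    ftest_p(cand$res$deviance, best$res$deviance, q,
            n_par(nrow(best$u$comps))) > 0.01
  }
  repeat {
    if (nrow(best$u$comps) <= 1 ||
        sqrt(best$res$deviance / npts) > 3 * rms_target) break
    cc <- best$u$comps
    changed <- FALSE
    # removal, smallest areas first
    for (j in utils::head(order(cc$height * cc$fwhm), 3)) {
      cand <- tryCatch(fit_once(cc[-j, , drop = FALSE]),
                       error = function(e) NULL)
      if (accept_rms(cand)) { best <- cand; changed <- TRUE; break }
    }
    # merge the most overlapped adjacent pair
    if (!changed && nrow(cc) > 1) {
      d <- diff(cc$center)
      wmin <- pmin(cc$fwhm[-nrow(cc)], cc$fwhm[-1])
      j <- which.min(d / wmin)
      if (d[j] < 0.6 * wmin[j]) {
        a <- cc$height * cc$fwhm
        merged <- cc[j, ]
        merged$center <- sum(cc$center[j:(j + 1)] * a[j:(j + 1)]) /
          sum(a[j:(j + 1)])
        merged$height <- cc$height[j] + cc$height[j + 1]
        merged$fwhm <- sum(a[j:(j + 1)]) / merged$height
        merged$fwhm <- min(max(merged$fwhm, fwhm_limits[1]), fwhm_limits[2])
        tb3 <- rbind(cc[-c(j, j + 1), ], merged)
        tb3 <- tb3[order(tb3$center), , drop = FALSE]
        cand <- tryCatch(fit_once(tb3), error = function(e) NULL)
        if (accept_rms(cand)) { best <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }

  # final polish at high precision: settles flat-valley solutions and
  # removes residual parameter drift left by the coarser first pass
  pol <- tryCatch(fit_once(best$u$comps, ftol = 1e-14),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$res$deviance <= best$res$deviance) best <- pol

  res <- best$res
  u <- best$u
  fitted_curve <- eval_components(sr$wavenumber, u$comps, u$b0, u$b1, x0)
  rss_tr <- res$rsstrace
  tail_ok <- length(rss_tr) >= 3 && {
    d <- abs(diff(utils::tail(rss_tr, 3))) / max(utils::tail(rss_tr, 1), 1e-300)
    all(d < 1e-6)
  }
  converged <- res$info %in% 1:3 || tail_ok ||
    sqrt(res$deviance / npts) <= rms_target
  if (!converged)
    warning("decomposition did not converge in ", res$niter, " iterations",
            call. = FALSE)
  comps <- peak_component(u$comps$center, pmax(u$comps$height, 0),
                          u$comps$fwhm, pmin(pmax(u$comps$eta, 0), 1))
  o <- order(comps$center)
  comps <- comps[o, , drop = FALSE]
  rownames(comps) <- NULL
  sdy <- stats::sd(sr$intensity)
  r <- if (sdy > 0 && stats::sd(fitted_curve) > 0)
    stats::cor(sr$intensity, fitted_curve) else NA_real_

  structure(list(
    components = comps,
    baseline = if (baseline) list(b0 = u$b0, b1 = u$b1, x0 = x0) else NULL,
    data = sr, fitted_curve = fitted_curve,
    pearson_r = r,
    residual_rms = sqrt(mean((sr$intensity - fitted_curve)^2)),
    converged = converged, n_iterations = res$niter,
    rss_trace = res$rsstrace,
    n_pinned = sum(comps$height <= 0),
    region = region, shape = shape, call = cl),
    class = "band_fit")
}

#' Workflow wrappers for the two standard fit regions
#'
#' `decompose_amide_i()` fits the 1590-1710 cm-1 amide I region against the
#' secondary-structure scheme with component widths bounded to 6-30 cm-1
#' (condensed-phase amide I sub-band widths); `decompose_ss()` fits the
#' 500-550 cm-1 disulfide stretching region against the conformer scheme
#' with widths bounded to 5-20 cm-1. Both include a local linear baseline.
#'
#' @param s baseline-corrected (and for solid samples, 1460-normalized)
#'   [raman_spectrum].
#' @param region fit region, cm-1.
#' @param ... passed on to [fit_bands()].
#' @return a `band_fit`.
#' @export
decompose_amide_i <- function(s, region = c(1590, 1710), ...) {
  fit_bands(s, region, scheme = amide_i_scheme(), fwhm_limits = c(6, 30),
            d2_window = 7, bin_step = 0, min_prominence = 0.05, ...)
}

#' @rdname decompose_amide_i
#' @export
decompose_ss <- function(s, region = c(500, 550), ...) {
  fit_bands(s, region, scheme = ss_conformer_scheme(),
            fwhm_limits = c(5, 20), d2_window = 7, bin_step = 0,
            min_prominence = 0.05, ...)
}

# assign each center to a scheme window (NA when outside all windows)
scheme_window_of <- function(centers, scheme) {
  e <- scheme$entries
  lo <- hi <- rep(NA_real_, length(centers))
  lab <- rep(NA_character_, length(centers))
  for (j in seq_len(nrow(e))) {
    hit <- centers >= e$lo[j] & centers <= e$hi[j]
    lo[hit] <- e$lo[j]; hi[hit] <- e$hi[j]; lab[hit] <- e$label[j]
  }
  # second pass: nearest window edge within tolerance
  out <- is.na(lab)
  if (any(out)) {
    for (i in which(out)) {
      d <- pmax(e$lo - centers[i], centers[i] - e$hi, 0)
      j <- which.min(d)
      if (d[j] <= scheme$tolerance) {
        lo[i] <- e$lo[j]; hi[i] <- e$hi[j]; lab[i] <- e$label[j]
      }
    }
  }
  list(lo = lo, hi = hi, label = lab)
}

# guarantee each scheme window holds >= 1 seed; missing windows get a seed
# at the window midpoint with the local spectrum height
ensure_window_seeds <- function(seeds, scheme, sr) {
  e <- scheme$entries
  win <- scheme_window_of(seeds$center, scheme)
  missing <- setdiff(e$label, win$label)
  for (lab in missing) {
    j <- which(e$label == lab)
    ctr <- (e$fit_lo[j] + e$fit_hi[j]) / 2
    if (ctr < min(sr$wavenumber) || ctr > max(sr$wavenumber)) next
    h <- stats::approx(sr$wavenumber, sr$intensity, xout = ctr)$y
    seeds <- rbind(seeds, peak_component(ctr, max(h, 1e-6), 12, 0))
  }
  seeds <- seeds[order(seeds$center), , drop = FALSE]
  rownames(seeds) <- NULL
  class(seeds) <- c("peak_component", "data.frame")
  seeds
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("Band decomposition over [%g, %g] cm-1 (%s)\n",
              x$region[1], x$region[2], x$shape))
  cat(sprintf("  %d components, Pearson r = %.6f, residual RMS = %.3g\n",
              nrow(x$components), x$pearson_r, x$residual_rms))
  cat(sprintf("  converged: %s (%d iterations)%s\n", x$converged,
              x$n_iterations,
              if (x$n_pinned) sprintf(", %d pinned at zero height", x$n_pinned)
              else ""))
  invisible(x)
}

#' @export
summary.band_fit <- function(object, ...) {
  out <- list(components = object$components, pearson_r = object$pearson_r,
              residual_rms = object$residual_rms,
              converged = object$converged,
              n_iterations = object$n_iterations, region = object$region,
              baseline = object$baseline, shape = object$shape)
  class(out) <- "summary.band_fit"
  out
}

#' @export
print.summary.band_fit <- function(x, ...) {
  cat(sprintf("Band decomposition over [%g, %g] cm-1 (%s)\n",
              x$region[1], x$region[2], x$shape))
  tab <- x$components
  tab$area_pct <- 100 * tab$area / sum(tab$area)
  print(format(tab, digits = 4), row.names = TRUE)
  if (!is.null(x$baseline))
    cat(sprintf("local linear baseline: %.4g + %.4g * (nu - %.6g)\n",
                x$baseline$b0, x$baseline$b1, x$baseline$x0))
  cat(sprintf("Pearson r = %.6f, residual RMS = %.4g, converged = %s (%d it.)\n",
              x$pearson_r, x$residual_rms, x$converged, x$n_iterations))
  invisible(x)
}

#' @export
coef.band_fit <- function(object, ...) {
  m <- as.matrix(object$components[, c("center", "height", "fwhm", "eta")])
  rownames(m) <- sprintf("band%d", seq_len(nrow(m)))
  m
}

#' @export
fitted.band_fit <- function(object, ...) object$fitted_curve

#' @export
residuals.band_fit <- function(object, ...)
  object$data$intensity - object$fitted_curve

#' Evaluate a fitted decomposition on new wavenumbers
#'
#' @param object a `band_fit`.
#' @param newdata numeric wavenumbers (defaults to the fit grid).
#' @param components include per-component curves as a matrix attribute.
#' @param ... unused.
#' @return composite model values at `newdata`.
#' @export
predict.band_fit <- function(object, newdata = NULL, components = FALSE, ...) {
  x <- if (is.null(newdata)) object$data$wavenumber else as.numeric(newdata)
  b <- object$baseline %||% list(b0 = 0, b1 = 0, x0 = 0)
  y <- eval_components(x, object$components, b$b0, b$b1, b$x0)
  if (components) {
    cm <- vapply(seq_len(nrow(object$components)), function(i)
      pseudo_voigt(x, object$components$center[i], object$components$height[i],
                   object$components$fwhm[i], object$components$eta[i]),
      numeric(length(x)))
    attr(y, "components") <- cm
  }
  y
}

#' Plot a fitted decomposition
#'
#' Data points, fitted composite, the individual band profiles and the local
#' baseline, in the style of published amide I decomposition figures.
#'
#' @param x a `band_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.band_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$wavenumber, d$intensity, pch = 16, cex = 0.4,
                 col = "grey40", xlab = expression(paste(
                   "wavenumber (", cm^-1, ")")),
                 ylab = "intensity (a.u.)", ...)
  graphics::lines(d$wavenumber, x$fitted_curve, col = "red3", lwd = 2)
  b <- x$baseline %||% list(b0 = 0, b1 = 0, x0 = 0)
  bl <- b$b0 + b$b1 * (d$wavenumber - b$x0)
  for (i in seq_len(nrow(x$components)))
    graphics::lines(d$wavenumber, bl +
                      pseudo_voigt(d$wavenumber, x$components$center[i],
                                   x$components$height[i],
                                   x$components$fwhm[i], x$components$eta[i]),
                    col = "steelblue")
  graphics::lines(d$wavenumber, bl, lty = 2, col = "grey60")
  invisible(x)
}

#' Simulate spectra from a fitted decomposition
#'
#' Draws spectra equal to the fitted composite plus i.i.d. Gaussian noise at
#' the fit's residual RMS.
#'
#' @param object a `band_fit`.
#' @param nsim number of spectra.
#' @param seed optional RNG seed (restored on exit).
#' @param ... unused.
#' @return list of [raman_spectrum] objects.
#' @export
simulate.band_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  lapply(seq_len(nsim), function(i)
    raman_spectrum(object$data$wavenumber,
                   object$fitted_curve +
                     stats::rnorm(length(object$fitted_curve),
                                  sd = object$residual_rms)))
}
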