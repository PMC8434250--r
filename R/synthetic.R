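# Seeded synthetic FT-Raman spectra with known component truth: the test
# bed for every pipeline stage and for parameter-recovery experiments.

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

#' Construct a synthetic ground truth
#'
#' Holds everything needed to generate a synthetic spectrum and to score a
#' recovery experiment against it: the true pseudo-Voigt components, a
#' smooth polynomial background standing in for kernel fluorescence, the
#' additive noise level, the replicate-to-replicate multiplicative jitter,
#' the grid, and the seed.
#'
#' @param components a [peak_component()] table.
#' @param background polynomial coefficients (increasing power, degree <= 4)
#'   evaluated on the grid centered at its midpoint.
#' @param noise_sigma additive Gaussian noise SD as a fraction of the
#'   maximum clean intensity.
#' @param replicate_jitter multiplicative replicate SD fraction (< 0.05,
#'   matching the convention that replicate SD stays below 5%).
#' @param grid `c(lo, hi, step)` cm-1.
#' @param seed integer RNG seed.
#' @param fractions optional named truth fractions (percent) recorded for
#'   recovery scoring.
#' @return a `synthetic_truth` object.
#' @export
synthetic_truth <- function(components, background = numeric(0),
                            noise_sigma = 0.005, replicate_jitter = 0.02,
                            grid = c(300, 2000, 1), seed = 1,
                            fractions = NULL) {
  stopifnot(noise_sigma >= 0, replicate_jitter >= 0, grid[3] > 0,
            grid[1] < grid[2])
  if (replicate_jitter >= 0.05)
    stop("replicate_jitter must stay below 0.05", call. = FALSE)
  if (length(background) > 5)
    stop("background degree must be <= 4", call. = FALSE)
  structure(list(components = components, background = background,
                 noise_sigma = noise_sigma,
                 replicate_jitter = replicate_jitter,
                 grid = grid, seed = as.integer(seed), fractions = fractions),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d components on [%g, %g] @ %g cm-1, ",
              nrow(x$components), x$grid[1], x$grid[2], x$grid[3]))
  cat(sprintf("noise %.3g, jitter %.3g, seed %d\n", x$noise_sigma,
              x$replicate_jitter, x$seed))
  if (!is.null(x$fractions)) print(round(x$fractions, 2))
  invisible(x)
}

# clean (noise-free) curve of a truth on its grid
truth_curve <- function(truth, x = NULL) {
  if (is.null(x)) x <- seq(truth$grid[1], truth$grid[2], by = truth$grid[3])
  y <- pseudo_voigt(x, truth$components$center, truth$components$height,
                    truth$components$fwhm, truth$components$eta)
  if (length(truth$background)) {
    xc <- x - mean(range(x))
    y <- y + drop(outer(xc, seq_along(truth$background) - 1, `^`) %*%
                    truth$background)
  }
  y
}

#' Generate a synthetic spectrum from a truth
#'
#' Intensity = sum of pseudo-Voigt components + polynomial background +
#' seeded additive Gaussian noise. Replicates (`replicate > 1`) draw an
#' independent noise realization and a multiplicative intensity factor
#' `1 + N(0, replicate_jitter)`, emulating repositioning between
#' acquisitions. Deterministic given `truth$seed` and `replicate`.
#'
#' @param truth a [synthetic_truth()].
#' @param replicate replicate index (changes the noise stream only).
#' @return list with `spectrum` (a [raman_spectrum]) and `truth` (echoed).
#' @export
generate_spectrum <- function(truth, replicate = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  x <- seq(truth$grid[1], truth$grid[2], by = truth$grid[3])
  clean <- truth_curve(truth, x)
  s <- with_seed(truth$seed + 104729L * (replicate - 1L), {
    fac <- if (replicate > 1 && truth$replicate_jitter > 0)
      1 + stats::rnorm(1, sd = truth$replicate_jitter) else 1
    noise <- if (truth$noise_sigma > 0)
      stats::rnorm(length(x), sd = truth$noise_sigma * max(abs(clean)))
    else 0
    raman_spectrum(x, fac * clean + noise,
                   meta = list(synthetic = TRUE, seed = truth$seed,
                               replicate = replicate,
                               state = if (truth$grid[2] > 2100) "solid"
                                       else "liquid"))
  })
  list(spectrum = s, truth = truth)
}

# draw a flat (symmetric Dirichlet) simplex sample, in percent
simplex_percent <- function(n) {
  g <- stats::rexp(n)
  100 * g / sum(g)
}

#' Synthetic gliadin-extract amide I truth
#'
#' Emulates the amide I envelope of a liquid gliadin extract: five
#' secondary-structure bands with centers inside the published windows
#' (beta-sheet 1634-1640, alpha-helix 1649-1652, random coil ~1663,
#' beta-turn 1677-1678, antiparallel beta-sheet 1690-1692 cm-1) plus two
#' aromatic side-chain bands (1607-1610 and 1620-1627 cm-1), on a weak
#' linear background. Structural areas follow the truth fractions (flat
#' simplex prior unless pinned); aromatic areas are a few percent of the
#' structural total. Widths default to condensed-phase Raman values:
#' FWHM 14-22 cm-1 structural, 8-12 cm-1 aromatic.
#'
#' @param seed RNG seed.
#' @param fractions optional percent vector (beta_sheet, alpha_helix,
#'   random_coil, beta_turn, abeta_sheet) pinning the truth; drawn from a
#'   flat simplex when `NULL`.
#' @param noise_sigma additive noise fraction of peak intensity.
#' @param grid `c(lo, hi, step)` cm-1.
#' @param min_separation minimum pairwise center distance enforced by
#'   rejection sampling (0 disables).
#' @param replicate_jitter multiplicative replicate SD fraction.
#' @return a [synthetic_truth()] with `$fractions` set.
#' @export
gliadin_truth <- function(seed = 1, fractions = NULL, noise_sigma = 0.005,
                          grid = c(1585, 1715, 0.25), min_separation = 0,
                          replicate_jitter = 0.02) {
  with_seed(seed, {
    windows <- rbind(
      aromatic_1608 = c(1607, 1610), aromatic_1624 = c(1620, 1627),
      beta_sheet = c(1634, 1640), alpha_helix = c(1649, 1652),
      random_coil = c(1662, 1664), beta_turn = c(1677, 1678),
      abeta_sheet = c(1690, 1692))
    draw_centers <- function() {
      stats::runif(nrow(windows), windows[, 1], windows[, 2])
    }
    centers <- draw_centers()
    if (min_separation > 0) {
      for (try in 1:500) {
        if (min(diff(sort(centers))) >= min_separation) break
        centers <- draw_centers()
      }
      if (min(diff(sort(centers))) < min_separation)
        stop("could not satisfy min_separation", call. = FALSE)
    }
    fwhm <- c(stats::runif(2, 8, 12), stats::runif(5, 14, 22))
    if (is.null(fractions)) fractions <- simplex_percent(5)
    fractions <- 100 * fractions / sum(fractions)
    names(fractions) <- rownames(windows)[3:7]
    total <- 10
    areas <- c(stats::runif(2, 0.03, 0.08) * total, total * fractions / 100)
    gauss_area_per_h <- fwhm * sqrt(pi / (4 * log(2)))
    comps <- peak_component(centers, areas / gauss_area_per_h, fwhm, eta = 0)
    hmax <- max(comps$height)
    synthetic_truth(comps,
                    background = c(0.05 * hmax, 1e-4 * hmax),
                    noise_sigma = noise_sigma,
                    replicate_jitter = replicate_jitter,
                    grid = grid, seed = seed, fractions = fractions)
  })
}

#' Synthetic disulfide-region truth
#'
#' Five S-S stretching sub-bands at the positions seen in curve-fitted
#' kernel endosperm spectra (~513 ggg; 519 and 525 tgg; 533 and 546 tgt
#' cm-1, each jittered by up to 1 cm-1), on a weak linear background.
#' Sub-band areas are drawn from a uniform prior unless conformer-class
#' fractions are pinned, in which case each class area is split between its
#' sub-bands at a random ratio.
#'
#' @param seed RNG seed.
#' @param fractions optional percent vector (SSggg, SStgg, SStgt).
#' @param areas optional explicit 5-vector of sub-band areas (overrides
#'   `fractions`).
#' @param noise_sigma additive noise fraction of peak intensity.
#' @param grid `c(lo, hi, step)` cm-1.
#' @param replicate_jitter multiplicative replicate SD fraction.
#' @return a [synthetic_truth()] with `$fractions` set (class percents).
#' @export
ss_region_truth <- function(seed = 1, fractions = NULL, areas = NULL,
                            noise_sigma = 0.005, grid = c(495, 555, 0.25),
                            replicate_jitter = 0.02) {
  with_seed(seed, {
    centers <- c(513, 519, 525, 533, 546) + stats::runif(5, -1, 1)
    fwhm <- stats::runif(5, 9, 14)
    if (is.null(areas)) {
      if (is.null(fractions)) {
        areas <- stats::runif(5, 0.5, 1.5)
      } else {
        fractions <- 100 * fractions / sum(fractions)
        split2 <- function(a) { r <- stats::runif(1, 0.3, 0.7); c(r, 1 - r) * a }
        areas <- c(fractions[1], split2(fractions[2]), split2(fractions[3])) / 10
      }
    }
    frac <- c(SSggg = areas[1], SStgg = sum(areas[2:3]),
              SStgt = sum(areas[4:5]))
    frac <- 100 * frac / sum(frac)
    gauss_area_per_h <- fwhm * sqrt(pi / (4 * log(2)))
    comps <- peak_component(centers, areas / gauss_area_per_h, fwhm, eta = 0)
    hmax <- max(comps$height)
    synthetic_truth(comps,
                    background = c(0.1 * hmax, 2e-3 * hmax),
                    noise_sigma = noise_sigma,
                    replicate_jitter = replicate_jitter,
                    grid = grid, seed = seed, fractions = frac)
  })
}

#' Synthetic wheat kernel endosperm truth
#'
#' A full 300-2000 cm-1 kernel endosperm spectrum: the starch-dominated
#' marker bands (440, 480, 865, 940, 1052, 1084, 1127, 1260, 1340, 1380,
#' 1460, 1600 cm-1 and the amide I envelope at 1660 cm-1), the C-S stretch
#' bands (optionally including the 640 cm-1 gauche band), the tyrosine
#' doublet with a configurable height ratio, the tryptophan 760 cm-1 band,
#' and the S-S conformer sub-bands, all riding on a broad cubic
#' fluorescence background.
#'
#' Heights are expressed relative to the 1460 cm-1 reference band (height
#' 1), so the generated spectra land near the normalized scale after
#' baseline correction and 1460-normalization.
#'
#' @param seed RNG seed.
#' @param ss_fractions optional conformer percents (SSggg, SStgg, SStgt);
#'   flat simplex prior when `NULL`.
#' @param tyr_ratio tyrosine I(855)/I(835) height ratio; drawn U(1.5, 2.6)
#'   when `NULL`.
#' @param trp_height tryptophan 760 height on the relative scale; drawn
#'   U(0.11, 0.15) when `NULL`.
#' @param include_cs640 include the 640 cm-1 gauche C-S band.
#' @param noise_sigma additive noise fraction of peak intensity.
#' @param background_amplitude fluorescence background height relative to
#'   the 1460 band.
#' @param replicate_jitter multiplicative replicate SD fraction.
#' @return a [synthetic_truth()] with `$fractions` = conformer percents.
#' @export
endosperm_truth <- function(seed = 1, ss_fractions = NULL, tyr_ratio = NULL,
                            trp_height = NULL, include_cs640 = TRUE,
                            noise_sigma = 0.005, background_amplitude = 1,
                            replicate_jitter = 0.02) {
  with_seed(seed, {
    if (is.null(ss_fractions)) ss_fractions <- simplex_percent(3)
    ss_fractions <- 100 * ss_fractions / sum(ss_fractions)
    if (is.null(tyr_ratio)) tyr_ratio <- stats::runif(1, 1.5, 2.6)
    if (is.null(trp_height)) trp_height <- stats::runif(1, 0.11, 0.15)

    marker_centers <- c(440, 480, 865, 940, 1052, 1084, 1127, 1260, 1340,
                        1380, 1460, 1600, 1660)
    marker_heights <- c(0.35, 1.2, 0.25, 0.5, 0.5, 0.5, 0.45, 0.3, 0.35,
                        0.4, 1.0, 0.2, 0.55)
    marker_fwhm <- c(24, 20, 16, 18, 16, 16, 16, 22, 22, 18, 20, 14, 34)

    cs_centers <- c(if (include_cs640) 640, 670, 702, 718)
    cs_heights <- c(if (include_cs640) 0.08, 0.10, 0.05, 0.09)
    cs_fwhm <- rep(12, length(cs_centers))

    tyr835 <- 0.08
    aa_centers <- c(760, 835, 855)
    aa_heights <- c(trp_height, tyr835, tyr_ratio * tyr835)
    aa_fwhm <- c(10, 9, 9)

    # S-S sub-bands: class areas from fractions, split between sub-bands
    ss_centers <- c(513, 519, 525, 533, 546) + stats::runif(5, -1, 1)
    ss_fwhm <- stats::runif(5, 9, 14)
    split2 <- function(a) { r <- stats::runif(1, 0.3, 0.7); c(r, 1 - r) * a }
    ss_total_area <- 1.5
    ss_areas <- ss_total_area *
      c(ss_fractions[1], split2(ss_fractions[2]), split2(ss_fractions[3])) / 100
    ss_heights <- ss_areas / (ss_fwhm * sqrt(pi / (4 * log(2))))

    comps <- peak_component(
      c(marker_centers, cs_centers, aa_centers, ss_centers),
      c(marker_heights, cs_heights, aa_heights, ss_heights),
      c(marker_fwhm, cs_fwhm, aa_fwhm, ss_fwhm), eta = 0)

    # broad decaying fluorescence: cubic in the centered axis, positive
    bg <- background_amplitude * c(0.6, -6e-4, 1.5e-7, 5e-11)
    names(ss_fractions) <- c("SSggg", "SStgg", "SStgt")
    synthetic_truth(comps, background = bg, noise_sigma = noise_sigma,
                    replicate_jitter = replicate_jitter,
                    grid = c(300, 2000, 1), seed = seed,
                    fractions = ss_fractions)
  })
}

#' Generate a replicated synthetic study set
#'
#' Draws `n_samples` independent truths from a preset's priors and
#' `n_replicates` spectra per truth (at least 3, matching the convention of
#' averaging three or more independent acquisitions).
#'
#' @param preset `"endosperm"`, `"gliadin_liquid"`, or `"ss_region"`.
#' @param n_samples number of independent truths.
#' @param n_replicates replicates per truth (>= 3).
#' @param seed master seed; per-sample seeds derive from it.
#' @param ... passed to the preset truth constructor.
#' @return list of `n_samples` elements, each with `truth` and `replicates`
#'   (list of [raman_spectrum]).
#' @export
generate_study_set <- function(preset = c("endosperm", "gliadin_liquid",
                                          "ss_region"),
                               n_samples = 1, n_replicates = 3, seed = 1,
                               ...) {
  preset <- match.arg(preset)
  if (n_replicates < 3)
    stop("n_replicates must be >= 3", call. = FALSE)
  sample_seeds <- with_seed(seed, sample.int(2^30, n_samples))
  maker <- switch(preset, endosperm = endosperm_truth,
                  gliadin_liquid = gliadin_truth, ss_region = ss_region_truth)
  lapply(seq_len(n_samples), function(i) {
    truth <- maker(seed = sample_seeds[i], ...)
    reps <- lapply(seq_len(n_replicates), function(r) {
      g <- generate_spectrum(truth, replicate = r)
      g$spectrum$meta$sample_id <- sprintf("%s_%02d", preset, i)
      g$spectrum$meta$replicate <- r
      g$spectrum
    })
    list(truth = truth, replicates = reps)
  })
}

#' Parameter-recovery experiment
#'
#' For each noise level, generates `n_per_cell` truths, runs the full
#' decomposition + quantification pipeline on each generated spectrum, and
#' scores the recovered fractions against truth. Fit failures are counted,
#' not fatal.
#'
#' @param preset `"gliadin_liquid"` (amide I fractions) or `"ss_region"`
#'   (conformer fractions).
#' @param noise_grid vector of noise sigmas (fraction of peak intensity).
#' @param n_per_cell truths per noise level.
#' @param seed master seed.
#' @param csv optional path; when given, the table is written there.
#' @return data frame with one row per (sigma, label): `bias` and `rmse` in
#'   percentage points, plus per-sigma `min_pearson_r` and `n_failed`
#'   attached as attributes `summary`.
#' @export
recovery_experiment <- function(preset = c("gliadin_liquid", "ss_region"),
                                noise_grid = c(0, 0.005, 0.01),
                                n_per_cell = 20, seed = 1, csv = NULL) {
  preset <- match.arg(preset)
  rows <- list(); summ <- list()
  cell_seeds <- with_seed(seed, matrix(sample.int(2^30,
    length(noise_grid) * n_per_cell), nrow = length(noise_grid)))
  for (gi in seq_along(noise_grid)) {
    sig <- noise_grid[gi]
    errs <- list(); rs <- c(); failed <- 0
    for (j in seq_len(n_per_cell)) {
      res <- tryCatch(suppressWarnings({
        tr <- if (preset == "gliadin_liquid")
          gliadin_truth(seed = cell_seeds[gi, j], noise_sigma = sig)
        else ss_region_truth(seed = cell_seeds[gi, j], noise_sigma = sig)
        g <- generate_spectrum(tr)
        if (preset == "gliadin_liquid") {
          fit <- decompose_amide_i(g$spectrum)
          rep_ <- quantify_amide_i(fit)
        } else {
          fit <- decompose_ss(g$spectrum)
          rep_ <- quantify_ss_conformers(fit)
        }
        list(err = rep_$fractions[names(tr$fractions)] - tr$fractions,
             r = fit$pearson_r)
      }), error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1; next }
      errs[[length(errs) + 1]] <- res$err
      rs <- c(rs, res$r)
    }
    if (length(errs)) {
      em <- do.call(rbind, errs)
      for (lab in colnames(em))
        rows[[length(rows) + 1]] <- data.frame(
          sigma = sig, label = lab, bias = mean(em[, lab]),
          rmse = sqrt(mean(em[, lab]^2)))
    }
    summ[[length(summ) + 1]] <- data.frame(
      sigma = sig, min_pearson_r = if (length(rs)) min(rs) else NA_real_,
      n_failed = failed)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- do.call(rbind, summ)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
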