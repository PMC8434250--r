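# Assignment schemes and area-based quantification: secondary-structure
# fractions from amide I, disulfide conformer fractions from 500-550 cm-1,
# and aromatic marker indices.

#' Build an assignment scheme
#'
#' An assignment scheme maps fitted components to structure or conformer
#' classes via labelled wavenumber windows. Windows must not overlap;
#' components falling between windows are assigned to the nearest window
#' edge within `tolerance`, otherwise they are reported as unassigned.
#'
#' @param name scheme name.
#' @param entries data frame with columns `label`, `lo`, `hi`, `class`
#'   (`"structural"`, `"aromatic"` or `"conformer"`), and optionally
#'   `fit_lo`/`fit_hi`: narrower windows (the literature band positions)
#'   to which component centers are confined during refinement. Without
#'   them the assignment window itself constrains the centers.
#' @param tolerance cm-1 slack for out-of-window assignment (and for the
#'   center constraint applied during fitting).
#' @return an `assignment_scheme` object.
#' @export
assignment_scheme <- function(name, entries, tolerance = 2) {
  stopifnot(is.data.frame(entries),
            all(c("label", "lo", "hi", "class") %in% names(entries)))
  if (is.null(entries$fit_lo)) {
    entries$fit_lo <- entries$lo
    entries$fit_hi <- entries$hi
  }
  stopifnot(all(entries$fit_lo >= entries$lo - 1e-9),
            all(entries$fit_hi <= entries$hi + 1e-9))
  entries <- entries[order(entries$lo), , drop = FALSE]
  if (any(entries$hi[-nrow(entries)] > entries$lo[-1]))
    stop("scheme windows overlap", call. = FALSE)
  key <- entries$label[entries$class != "aromatic"]
  if (anyDuplicated(key))
    stop("duplicate structural/conformer labels", call. = FALSE)
  rownames(entries) <- NULL
  structure(list(name = name, entries = entries, tolerance = tolerance),
            class = "assignment_scheme")
}

#' @export
print.assignment_scheme <- function(x, ...) {
  cat(sprintf("Assignment scheme '%s' (tolerance %g cm-1)\n", x$name,
              x$tolerance))
  print(x$entries)
  invisible(x)
}

#' Amide I secondary-structure scheme
#'
#' Default windows tile the 1590-1710 cm-1 amide I region around the
#' positions where the individual secondary-structure components of wheat
#' gliadins are found: beta-sheet 1634-1640, alpha-helix 1649-1652, random
#' coil 1663, beta-turn 1677-1678 and antiparallel beta-sheet 1690-1692
#' cm-1, plus two aromatic side-chain bands (Phe/Trp/Tyr) in 1607-1610 and
#' 1620-1627 cm-1 that must be fitted but are excluded from the structural
#' denominator.
#'
#' @return an [assignment_scheme()].
#' @export
amide_i_scheme <- function() {
  assignment_scheme("amide_I", data.frame(
    label = c("aromatic_1608", "aromatic_1624", "beta_sheet", "alpha_helix",
              "random_coil", "beta_turn", "abeta_sheet"),
    lo = c(1603, 1616, 1630, 1645, 1657, 1671, 1684),
    hi = c(1613, 1629, 1644, 1656, 1670, 1683, 1696),
    # centers are held near the literature band positions during fitting
    fit_lo = c(1607, 1620, 1634, 1649, 1662, 1677, 1690),
    fit_hi = c(1610, 1627, 1640, 1652, 1664, 1678, 1692),
    class = c("aromatic", "aromatic", rep("structural", 5))))
}

#' Disulfide-bridge conformer scheme
#'
#' Sub-band windows for the S-S stretching region: ~510 cm-1
#' gauche-gauche-gauche, ~525 cm-1 trans-gauche-gauche, ~545 cm-1
#' trans-gauche-trans. Each class may contain several fitted sub-bands whose
#' areas are summed.
#'
#' @return an [assignment_scheme()].
#' @export
ss_conformer_scheme <- function() {
  assignment_scheme("ss_conformers", data.frame(
    label = c("SSggg", "SStgg", "SStgt"),
    lo = c(505, 517.5, 528.5),
    hi = c(517, 528, 550),
    class = "conformer"))
}

# shared assignment step: returns component table with label/class columns
assign_components <- function(comps, scheme) {
  win <- scheme_window_of(comps$center, scheme)
  comps$label <- win$label
  cls <- scheme$entries$class[match(win$label, scheme$entries$label)]
  comps$class <- cls
  comps
}

#' Quantify amide I secondary-structure fractions
#'
#' Assigns each fitted component of an amide I decomposition to a scheme
#' window and reports structural fractions
#' `100 * area(label) / total structural area`. Aromatic-class areas are
#' fitted but excluded from the denominator and reported separately;
#' components outside all windows go to `unassigned` with a warning.
#'
#' @param fit a [fit_bands()] result over a region containing 1590-1710
#'   cm-1, or a bare `peak_component` table.
#' @param scheme the amide I [assignment_scheme()].
#' @return a `structure_report`: list with `fractions` (named percents over
#'   structural labels, summing to 100), `aromatic_areas`, `unassigned`
#'   (component rows), `scheme_name`, `components` (annotated table).
#' @examples
#' comps <- peak_component(c(1637, 1650, 1663, 1677, 1691),
#'                         height = 1, fwhm = 15)
#' comps$area <- c(19, 25, 26, 27, 3)
#' quantify_amide_i(comps)$fractions
#' @export
quantify_amide_i <- function(fit, scheme = amide_i_scheme()) {
  comps <- if (inherits(fit, "band_fit")) fit$components else fit
  comps <- assign_components(as.data.frame(comps), scheme)
  struct <- comps[!is.na(comps$class) & comps$class == "structural", ]
  arom <- comps[!is.na(comps$class) & comps$class == "aromatic", ]
  unas <- comps[is.na(comps$class), ]
  if (nrow(unas))
    warning(nrow(unas), " component(s) outside all scheme windows",
            call. = FALSE)
  tot <- sum(struct$area)
  if (!(tot > 0)) stop("zero total structural area", call. = FALSE)
  labs <- scheme$entries$label[scheme$entries$class == "structural"]
  fr <- vapply(labs, function(l) 100 * sum(struct$area[struct$label == l]) / tot,
               0)
  ar <- if (nrow(arom)) {
    alabs <- unique(arom$label)
    stats::setNames(vapply(alabs, function(l) sum(arom$area[arom$label == l]), 0),
                    alabs)
  } else stats::setNames(numeric(0), character(0))
  structure(list(fractions = fr, aromatic_areas = ar, unassigned = unas,
                 scheme_name = scheme$name, components = comps),
            class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat("Secondary-structure fractions [%] (scheme", x$scheme_name, ")\n")
  print(round(x$fractions, 1))
  if (length(x$aromatic_areas)) {
    cat("aromatic band areas (excluded from denominator):\n")
    print(signif(x$aromatic_areas, 4))
  }
  if (nrow(x$unassigned)) cat(nrow(x$unassigned), "unassigned component(s)\n")
  invisible(x)
}

#' Quantify disulfide-bridge conformer fractions
#'
#' Sums fitted sub-band areas per conformer class over the 500-550 cm-1 S-S
#' stretching region and reports
#' `100 * class area / total area` for gauche-gauche-gauche,
#' trans-gauche-gauche and trans-gauche-trans.
#'
#' @param fit a [fit_bands()] result covering 500-550 cm-1, or a bare
#'   `peak_component` table.
#' @param scheme the conformer [assignment_scheme()].
#' @return a `conformer_report`: list with `fractions` (named percents
#'   summing to 100), `member_bands` (centers per class), `unassigned`,
#'   `scheme_name`.
#' @examples
#' comps <- peak_component(c(513, 519, 525, 533, 546), 1, 12)
#' comps$area <- c(15, 20, 19, 30, 16)
#' quantify_ss_conformers(comps)$fractions
#' @export
quantify_ss_conformers <- function(fit, scheme = ss_conformer_scheme()) {
  comps <- if (inherits(fit, "band_fit")) fit$components else fit
  comps <- assign_components(as.data.frame(comps), scheme)
  member <- comps[!is.na(comps$class) & comps$class == "conformer", ]
  unas <- comps[is.na(comps$class), ]
  if (nrow(unas))
    warning(nrow(unas), " component(s) outside all scheme windows",
            call. = FALSE)
  tot <- sum(member$area)
  if (!(tot > 0)) stop("zero total conformer area", call. = FALSE)
  labs <- scheme$entries$label
  fr <- vapply(labs, function(l) 100 * sum(member$area[member$label == l]) / tot,
               0)
  mb <- lapply(labs, function(l) member$center[member$label == l])
  names(mb) <- labs
  structure(list(fractions = fr, member_bands = mb, unassigned = unas,
                 scheme_name = scheme$name),
            class = "conformer_report")
}

#' @export
print.conformer_report <- function(x, ...) {
  cat("Disulfide conformer fractions [%]:\n")
  print(round(x$fractions, 1))
  for (l in names(x$member_bands))
    cat(sprintf("  %s: bands at %s\n", l,
                paste(round(x$member_bands[[l]], 1), collapse = ", ")))
  invisible(x)
}

# height of the tallest local maximum of s inside window; NA when none
local_max_height <- function(s, window) {
  idx <- which(s$wavenumber >= window[1] & s$wavenumber <= window[2])
  if (length(idx) < 3) return(c(NA_real_, NA_real_))
  y <- s$intensity[idx]
  n <- length(y)
  i <- 2:(n - 1)
  is_max <- y[i] > y[i - 1] & y[i] >= y[i + 1]
  # window edges qualify when the spectrum keeps rising into the window
  cand <- i[is_max]
  if (!length(cand)) return(c(NA_real_, NA_real_))
  best <- cand[which.max(y[cand])]
  c(s$wavenumber[idx[best]], y[best])
}

#' Tyrosine Fermi doublet ratio I(855)/I(835)
#'
#' The height ratio of the tyrosine doublet reports the hydrogen-bonding
#' state of the phenol OH: ratios in 0.9-1.43 indicate tyrosines acting as
#' both donors and acceptors in moderate hydrogen bonds, ratios above 1.43
#' indicate the phenolic oxygen acting as a positive-charge (proton)
#' acceptor, and ratios of about 2 or more suggest exposed residues in the
#' anionic form. Heights are peak maxima measured on a baseline-corrected,
#' 1460-normalized spectrum.
#'
#' @param s baseline-corrected spectrum covering 820-870 cm-1.
#' @param window_855,window_835 search windows, cm-1.
#' @return list with `ratio`, `category` (one of `below_range`,
#'   `donor_acceptor`, `positive_charge_acceptor`), `exposed_anionic`
#'   (logical, ratio >= 2), `height_855`, `height_835`.
#' @export
tyrosine_doublet_ratio <- function(s, window_855 = c(849, 861),
                                   window_835 = c(829, 841)) {
  p855 <- local_max_height(s, window_855)
  p835 <- local_max_height(s, window_835)
  if (!is.finite(p855[2]) || !is.finite(p835[2]) || p835[2] <= 0)
    stop("tyrosine doublet maxima not found in 855/835 windows", call. = FALSE)
  ratio <- p855[2] / p835[2]
  category <- if (ratio < 0.9) "below_range"
  else if (ratio <= 1.43) "donor_acceptor"
  else "positive_charge_acceptor"
  list(ratio = ratio, category = category, exposed_anionic = ratio >= 2.0,
       height_855 = p855[2], height_835 = p835[2],
       center_855 = p855[1], center_835 = p835[1])
}

#' Tryptophan 760 cm-1 intensity
#'
#' Height of the tryptophan indole band at ~760 cm-1 on the 1460-normalized
#' scale; its decrease reports strengthening of hydrogen bonds involving
#' Trp residues.
#'
#' @param s baseline-corrected, 1460-normalized spectrum.
#' @param window search window, cm-1.
#' @return list with `height` and `center` of the detected maximum.
#' @export
tryptophan_intensity <- function(s, window = c(754, 766)) {
  p <- local_max_height(s, window)
  if (!is.finite(p[2]))
    stop("no tryptophan band maximum in window [", window[1], ", ",
         window[2], "]", call. = FALSE)
  list(height = p[2], center = p[1])
}

#' Default marker-band catalog for wheat kernel endosperm
#'
#' The characteristic FT-Raman bands of kernel endosperm: the starch marker
#' bands at 480 and 940 cm-1, polysaccharide skeletal/fingerprint bands,
#' lipid/CH deformation bands, the polyphenol ring mode at 1600 cm-1, the
#' amide I maximum near 1660 cm-1, and the methionine/cysteine C-S stretch
#' region (640 gauche; 670, 702 shoulder, 718 cm-1).
#'
#' @return data frame with `label`, `center`, `lo`, `hi`.
#' @export
marker_catalog <- function() {
  centers <- c(440, 480, 640, 670, 702, 718, 760, 835, 855, 865, 940, 1052,
               1084, 1127, 1260, 1340, 1380, 1460, 1600, 1660)
  labels <- c("pyranose_440", "starch_480", "cs_gauche_640", "cs_670",
              "cs_702", "cs_718", "trp_760", "tyr_835", "tyr_855",
              "glycosidic_865", "starch_940", "polysacch_1052",
              "polysacch_1084", "polysacch_1127", "lipid_1260", "lipid_1340",
              "polysacch_1380", "ch_def_1460", "phenolic_1600", "amide_I_1660")
  data.frame(label = labels, center = centers, lo = centers - 6,
             hi = centers + 6)
}

#' Detect catalogued marker bands
#'
#' For each catalog entry, reports whether a local maximum (or, failing
#' that, a shoulder, detected as a local minimum of the smoothed second
#' derivative) is present in the window, with its position and normalized
#' height. Absence is a valid result, not an error.
#'
#' @param s baseline-corrected, normalized spectrum.
#' @param catalog data frame as from [marker_catalog()].
#' @param min_height detection threshold on the locally floored height
#'   (peak minus the window-neighbourhood minimum), which makes detection
#'   robust to residual baseline offsets.
#' @param d2 optional precomputed second derivative (for shoulder calls).
#' @return data frame: `label`, `present`, `center`, `height`, `shoulder`.
#'   `height` is the raw spectrum value at the detected position.
#' @export
detect_marker_bands <- function(s, catalog = marker_catalog(),
                                min_height = 0.02, d2 = NULL) {
  if (is.null(d2)) d2 <- second_derivative(s)
  local_floor <- function(w) {
    idx <- which(s$wavenumber >= w[1] - 6 & s$wavenumber <= w[2] + 6)
    if (!length(idx)) return(0)
    min(s$intensity[idx])
  }
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    w <- c(catalog$lo[i], catalog$hi[i])
    if (w[1] < min(s$wavenumber) || w[2] > max(s$wavenumber))
      return(data.frame(label = catalog$label[i], present = FALSE,
                        center = NA_real_, height = NA_real_,
                        shoulder = FALSE))
    floor_i <- local_floor(w)
    p <- local_max_height(s, w)
    shoulder <- FALSE
    if (!is.finite(p[2]) || p[2] - floor_i < min_height) {
      # shoulder: curvature minimum without a free-standing maximum
      idx <- which(d2$wavenumber >= w[1] & d2$wavenumber <= w[2])
      if (length(idx) >= 3) {
        y <- d2$intensity[idx]
        j <- 2:(length(y) - 1)
        mins <- j[y[j] < y[j - 1] & y[j] <= y[j + 1] & y[j] < 0]
        if (length(mins)) {
          k <- mins[which.min(y[mins])]
          ctr <- d2$wavenumber[idx[k]]
          h <- stats::approx(s$wavenumber, s$intensity, xout = ctr)$y
          if (is.finite(h) && h - floor_i >= min_height) {
            p <- c(ctr, h); shoulder <- TRUE
          }
        }
      }
    }
    present <- is.finite(p[2]) && p[2] - floor_i >= min_height
    data.frame(label = catalog$label[i], present = present,
               center = if (present) p[1] else NA_real_,
               height = if (present) p[2] else NA_real_,
               shoulder = present && shoulder)
  })
  do.call(rbind, out)
}

#' Combined per-sample feature vector
#'
#' Flattens structure, conformer and marker reports into one named numeric
#' row suitable for export to external multivariate tools (PCA, heat maps).
#'
#' @param structure optional `structure_report`.
#' @param conformers optional `conformer_report`.
#' @param markers optional list with `tyr` ([tyrosine_doublet_ratio()]
#'   output) and `trp` ([tryptophan_intensity()] output).
#' @return one-row data frame.
#' @export
feature_row <- function(structure = NULL, conformers = NULL, markers = NULL) {
  v <- c(
    if (!is.null(structure)) structure$fractions,
    if (!is.null(conformers)) conformers$fractions,
    if (!is.null(markers$tyr)) c(tyr_ratio = markers$tyr$ratio),
    if (!is.null(markers$trp)) c(trp_760 = markers$trp$height))
  as.data.frame(as.list(v))
}
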