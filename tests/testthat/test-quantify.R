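table3_centers <- c(1637, 1650, 1663, 1677, 1691)
table3_labels <- c("beta_sheet", "alpha_helix", "random_coil", "beta_turn",
                   "abeta_sheet")

make_amide_components <- function(areas, aromatic = TRUE) {
  comps <- peak_component(table3_centers, 1, 15)
  comps$area <- areas
  if (aromatic) {
    ar <- peak_component(c(1608, 1624), 1, 10)
    ar$area <- c(5, 7)
    comps <- rbind(comps, ar)
  }
  comps
}

test_that("area proportions reproduce published secondary-structure rows", {
  # gliadins lacking omega fractions
  rep1 <- quantify_amide_i(make_amide_components(c(19, 25, 26, 27, 3)))
  expect_equal(unname(rep1$fractions[table3_labels]), c(19, 25, 26, 27, 3),
               tolerance = 1e-12)
  # full gliadin set
  rep2 <- quantify_amide_i(make_amide_components(c(12, 29, 31, 25, 3)))
  expect_equal(unname(rep2$fractions[table3_labels]), c(12, 29, 31, 25, 3),
               tolerance = 1e-12)
  # aromatic areas excluded from the denominator but reported
  expect_equal(sum(rep1$aromatic_areas), 12)
})

test_that("structure fractions are scale-invariant and sum to 100", {
  base <- make_amide_components(c(19, 25, 26, 27, 3))
  doubled <- base
  doubled$area <- 2 * doubled$area
  expect_equal(quantify_amide_i(base)$fractions,
               quantify_amide_i(doubled)$fractions, tolerance = 1e-12)
  expect_equal(sum(quantify_amide_i(base)$fractions), 100, tolerance = 1e-6)

  solo <- peak_component(1650, 1, 15)
  expect_equal(unname(quantify_amide_i(solo)$fractions["alpha_helix"]), 100)
})

test_that("unassignable components are reported, zero area is an error", {
  comps <- rbind(make_amide_components(c(19, 25, 26, 27, 3)),
                 peak_component(1712, 1, 10))
  expect_warning(rep_ <- quantify_amide_i(comps), "outside")
  expect_equal(nrow(rep_$unassigned), 1)
  zero <- peak_component(1650, 0, 15)
  expect_error(quantify_amide_i(zero), "zero total")
})

test_that("disulfide sub-band areas reproduce published conformer rows", {
  mk <- function(centers, areas) {
    comps <- peak_component(centers, 1, 10)
    comps$area <- areas
    comps
  }
  # line lacking omega-gliadins: 15 / 39 / 46
  r1 <- quantify_ss_conformers(mk(c(513, 519, 525, 533, 546),
                                  c(15, 20, 19, 30, 16)))
  expect_equal(unname(r1$fractions), c(15, 39, 46), tolerance = 1e-12)
  # control line: 18 / 46 / 36
  r2 <- quantify_ss_conformers(mk(c(514, 519, 524, 531, 545),
                                  c(18, 25, 21, 20, 16)))
  expect_equal(unname(r2$fractions), c(18, 46, 36), tolerance = 1e-12)
  expect_equal(sum(r1$fractions), 100, tolerance = 1e-6)
  # permutation invariance
  perm <- mk(c(546, 513, 525, 519, 533), c(16, 15, 19, 20, 30))
  expect_equal(quantify_ss_conformers(perm)$fractions, r1$fractions,
               tolerance = 1e-12)
  # a single band at 510 is pure g-g-g
  solo <- quantify_ss_conformers(peak_component(510, 1, 10))
  expect_equal(unname(solo$fractions), c(100, 0, 0))
})

test_that("scheme construction rejects overlapping windows", {
  expect_error(assignment_scheme("bad", data.frame(
    label = c("a", "b"), lo = c(500, 505), hi = c(510, 515),
    class = "conformer")), "overlap")
})

test_that("tyrosine doublet ratio and category thresholds", {
  x <- seq(800, 900, by = 0.25)
  mk <- function(h855, h835)
    raman_spectrum(x, gauss_curve(x, 855, h855, 8) + gauss_curve(x, 835, h835, 8))
  eq <- tyrosine_doublet_ratio(mk(1, 1))
  expect_equal(eq$ratio, 1, tolerance = 0.02)
  expect_equal(eq$category, "donor_acceptor")
  expect_false(eq$exposed_anionic)

  # ratio seen for the line lacking omega-gliadins: exposed anionic Tyr
  hi <- tyrosine_doublet_ratio(mk(2.53, 1))
  expect_equal(hi$ratio, 2.53, tolerance = 0.03)
  expect_equal(hi$category, "positive_charge_acceptor")
  expect_true(hi$exposed_anionic)

  # control-line ratio: strong acceptor but not anionic
  mid <- tyrosine_doublet_ratio(mk(1.84, 1))
  expect_equal(mid$ratio, 1.84, tolerance = 0.03)
  expect_equal(mid$category, "positive_charge_acceptor")
  expect_false(mid$exposed_anionic)

  lo <- tyrosine_doublet_ratio(mk(0.5, 1))
  expect_equal(lo$category, "below_range")

  flat <- raman_spectrum(x, rep(0.1, length(x)))
  expect_error(tyrosine_doublet_ratio(flat), "not found")
})

test_that("tryptophan height reads the normalized 760 band", {
  x <- seq(700, 1500, by = 0.5)
  raw <- raman_spectrum(x, gauss_curve(x, 760, 0.12 * 1.7, 10) +
                             gauss_curve(x, 1460, 1.7, 20))
  nrm <- normalize_to_band(raw)$spectrum
  got <- tryptophan_intensity(nrm)
  expect_equal(got$height, 0.12, tolerance = 0.005)
  expect_equal(got$center, 760, tolerance = 1)
  # doubling the raw intensities changes nothing after normalization
  raw2 <- raman_spectrum(x, 2 * raw$intensity)
  got2 <- tryptophan_intensity(normalize_to_band(raw2)$spectrum)
  expect_equal(got2$height, got$height, tolerance = 1e-12)

  no_trp <- normalize_to_band(
    raman_spectrum(x, gauss_curve(x, 1460, 1.7, 20)))$spectrum
  expect_error(tryptophan_intensity(no_trp), "maximum")
})

test_that("marker detection flags starch bands and the gauche C-S band", {
  run_markers <- function(include_cs640) {
    tr <- endosperm_truth(seed = 13, noise_sigma = 0.002,
                          include_cs640 = include_cs640)
    s <- generate_spectrum(tr)$spectrum
    s <- crop_spectrum(s, c(300, 2000))
    s <- baseline_correct(s, "polynomial", degree = 3,
                          anchor_windows = list(c(300, 330), c(580, 610),
                                                c(780, 800), c(1150, 1190),
                                                c(1500, 1540), c(1950, 2000)))$spectrum
    detect_marker_bands(normalize_to_band(s)$spectrum)
  }
  tab <- run_markers(TRUE)
  starch <- tab[tab$label %in% c("starch_480", "starch_940"), ]
  expect_true(all(starch$present))
  expect_lt(max(abs(starch$center - c(480, 940))), 3)
  expect_true(tab$present[tab$label == "cs_gauche_640"])
  tab2 <- run_markers(FALSE)
  expect_false(tab2$present[tab2$label == "cs_gauche_640"])

  flat <- raman_spectrum(seq(300, 2000, 1), rep(0, 1701))
  tabf <- detect_marker_bands(flat)
  expect_false(any(tabf$present))
})

test_that("feature rows flatten reports for multivariate export", {
  st <- quantify_amide_i(make_amide_components(c(19, 25, 26, 27, 3)))
  fr <- feature_row(structure = st)
  expect_equal(ncol(fr), 5)
  expect_equal(fr$beta_sheet, 19)
})
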