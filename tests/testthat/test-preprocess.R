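test_that("replicate averaging returns exact mean and sample SD", {
  x <- seq(400, 500, by = 1)
  base <- raman_spectrum(x, gauss_curve(x, 450, 1, 20))
  out <- average_replicates(list(base, base, base))
  expect_equal(out$mean$intensity, base$intensity, tolerance = 1e-12)
  expect_true(all(out$sd == 0))
  expect_false(out$sd_warning)

  # hand arithmetic at every grid point: values 1, 2, 3 -> mean 2, SD 1
  flat <- function(v) raman_spectrum(x, rep(v, length(x)))
  out2 <- suppressWarnings(average_replicates(list(flat(1), flat(2), flat(3))))
  expect_equal(unique(out2$mean$intensity), 2)
  expect_equal(unique(round(out2$sd, 12)), 1)
})

test_that("2% replicate jitter stays under the 5% SD warning threshold", {
  tr <- gliadin_truth(seed = 6, noise_sigma = 0.002, replicate_jitter = 0.02)
  reps <- lapply(1:4, function(r) generate_spectrum(tr, replicate = r)$spectrum)
  out <- average_replicates(reps)
  expect_false(out$sd_warning)
  # a replicate scaled far outside the jitter model must trigger the flag
  reps[[1]]$intensity <- reps[[1]]$intensity * 1.25
  expect_warning(out2 <- average_replicates(reps), "SD exceeds")
  expect_true(out2$sd_warning)
})

test_that("averaging rejects empty and disjoint inputs", {
  expect_error(average_replicates(list()), "empty")
  a <- raman_spectrum(seq(300, 400, 1), rep(1, 101))
  b <- raman_spectrum(seq(500, 600, 1), rep(1, 101))
  expect_error(average_replicates(list(a, b)), "overlap")
})

test_that("cropping keeps the closed interval and is idempotent", {
  x <- seq(300, 4000, by = 2)
  s <- raman_spectrum(x, rexp(length(x)) + 1)
  c1 <- crop_spectrum(s, c(300, 2000))
  expect_lte(max(c1$wavenumber), 2000)
  expect_gte(min(c1$wavenumber), 300)
  expect_equal(crop_spectrum(s, range(s$wavenumber))$intensity, s$intensity)
  c2 <- crop_spectrum(crop_spectrum(s, c(500, 550)), c(500, 550))
  expect_equal(c2$intensity, crop_spectrum(s, c(500, 550))$intensity)
  expect_error(crop_spectrum(s, c(4200, 4300)), "no points")
})

test_that("linear baseline through end anchors cancels a pure line", {
  x <- seq(300, 2000, by = 1)
  s <- raman_spectrum(x, 0.003 * x + 2)
  out <- baseline_correct(s, "linear",
                          anchor_windows = list(c(300, 320), c(1980, 2000)))
  expect_lt(max(abs(out$spectrum$intensity)), 1e-9)
})

test_that("baseline correction recovers a peak riding a ramp", {
  x <- seq(300, 700, by = 0.5)
  truth_h <- 2.5
  s <- raman_spectrum(x, gauss_curve(x, 500, truth_h, 12) + 0.002 * x + 1)
  out <- baseline_correct(s, "linear",
                          anchor_windows = list(c(300, 440), c(560, 700)))
  got <- max(out$spectrum$intensity)
  expect_lt(abs(got - truth_h) / truth_h, 0.005)
  # second application barely changes an already-corrected spectrum
  out2 <- baseline_correct(out$spectrum, "linear",
                           anchor_windows = list(c(300, 440), c(560, 700)))
  expect_lt(max(abs(out2$spectrum$intensity - out$spectrum$intensity)),
            1e-6 * max(out$spectrum$intensity))
})

test_that("degenerate anchors are rejected", {
  s <- raman_spectrum(seq(300, 400, 1), rep(1, 101))
  expect_error(baseline_correct(s, "linear",
                                anchor_windows = list(c(300, 301), c(300, 301))),
               "degenerate|anchor")
})

test_that("normalization divides by the window maximum", {
  x <- seq(1400, 1500, by = 0.5)
  s <- raman_spectrum(x, gauss_curve(x, 1457, 2, 15))
  out <- normalize_to_band(s)
  expect_equal(max(out$spectrum$intensity), 1)
  expect_equal(out$record$divisor, 2, tolerance = 1e-6)
  # scale invariance: c * I normalizes to the identical trace
  s2 <- raman_spectrum(x, 37.5 * s$intensity)
  expect_equal(normalize_to_band(s2)$spectrum$intensity,
               out$spectrum$intensity, tolerance = 1e-12)
  # missing reference band errors
  s3 <- raman_spectrum(x, rep(0, length(x)))
  expect_error(normalize_to_band(s3), "positive")
})

test_that("second derivative is exact for a parabola", {
  x <- seq(0, 100, by = 0.5)
  a <- 0.37
  s <- raman_spectrum(x + 300, a * x^2)
  d2 <- second_derivative(s, smooth_window = 11, poly_order = 3)
  interior <- 10:(length(x) - 10)
  expect_lt(max(abs(d2$intensity[interior] - 2 * a)), 1e-6)
})

test_that("second-derivative minima locate Gaussian centers", {
  x <- seq(900, 1100, by = 0.5)
  s <- raman_spectrum(x, gauss_curve(x, 1000, 1, 12))
  d2 <- second_derivative(s)
  interior <- 6:(length(x) - 6)
  i <- interior[which.min(d2$intensity[interior])]
  expect_lt(abs(d2$wavenumber[i] - 1000), 0.5 + 1e-9)

  # two bands 25 cm-1 apart give two minima, one near each center
  s2 <- raman_spectrum(x, gauss_curve(x, 990, 1, 12) +
                            gauss_curve(x, 1015, 0.8, 12))
  d2b <- second_derivative(s2)
  y <- d2b$intensity
  n <- length(y)
  mins <- which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n] &
                  y[2:(n - 1)] < 0) + 1
  locs <- d2b$wavenumber[mins]
  expect_true(any(abs(locs - 990) < 2))
  expect_true(any(abs(locs - 1015) < 2))
})

test_that("derivative rejects invalid smoothing parameters", {
  s <- raman_spectrum(seq(300, 320, 1), rnorm(21))
  expect_error(second_derivative(s, smooth_window = 10), "odd")
  expect_error(second_derivative(s, smooth_window = 3, poly_order = 3),
               "exceed")
  expect_error(second_derivative(s, smooth_window = 51), "larger")
})

test_that("preprocessing chain is invariant to positive rescaling", {
  tr <- endosperm_truth(seed = 21)
  s <- generate_spectrum(tr)$spectrum
  chain <- function(sp) {
    sp <- crop_spectrum(sp, c(300, 2000))
    sp <- baseline_correct(sp, "polynomial", degree = 3,
                           anchor_windows = list(c(300, 330), c(580, 610),
                                                 c(780, 800), c(1150, 1190),
                                                 c(1500, 1540), c(1950, 2000)))$spectrum
    normalize_to_band(sp)$spectrum
  }
  a <- chain(s)
  s2 <- raman_spectrum(s$wavenumber, 13.7 * s$intensity, meta = s$meta)
  b <- chain(s2)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
})
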