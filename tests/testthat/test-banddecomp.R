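test_that("closed-form areas match the analytic limits", {
  expect_equal(component_area(peak_component(500, 0, 10, 0)), 0)
  # Gaussian h=1, FWHM=10
  expect_equal(component_area(peak_component(500, 1, 10, 0)),
               10 * sqrt(pi / (4 * log(2))), tolerance = 1e-12)
  # Lorentzian h=1, FWHM=10 on infinite support
  expect_equal(component_area(peak_component(500, 1, 10, 1)), pi / 2 * 10,
               tolerance = 1e-12)
})

test_that("closed-form areas agree with adaptive quadrature to 0.1%", {
  set.seed(42)
  for (i in 1:200) {
    c0 <- runif(1, 400, 1800)
    h <- runif(1, 0.01, 5)
    w <- runif(1, 2, 40)
    eta <- runif(1)
    comp <- peak_component(c0, h, w, eta)
    # integrate in band-centered coordinates so the quadrature finds the
    # mass regardless of where the band sits on the axis
    quad <- integrate(function(t) pseudo_voigt(c0 + t, c0, h, w, eta),
                      -Inf, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(comp$area - quad) / quad, 1e-3)
  }
})

test_that("Lorentzian tails carry documented mass beyond +-50 cm-1", {
  h <- 1; w <- 10
  full <- pi / 2 * h * w
  trunc <- integrate(function(x) pseudo_voigt(x, 0, h, w, 1), -50, 50,
                     rel.tol = 1e-10)$value
  tail_frac <- 1 - trunc / full
  # arctan tail: 1 - (2/pi) atan(2*50/w)
  expect_equal(tail_frac, 1 - (2 / pi) * atan(100 / w), tolerance = 1e-8)
  expect_gt(tail_frac, 0.05)
})

test_that("seeding finds a lone Gaussian and fails cleanly on flat input", {
  x <- seq(480, 560, by = 0.25)
  s <- raman_spectrum(x, gauss_curve(x, 520, 1, 12))
  seeds <- seed_components(s, c(500, 550), bin_step = 0)
  expect_equal(nrow(seeds), 1)
  expect_lt(abs(seeds$center - 520), 1 + 1e-9)

  flat <- raman_spectrum(x, rep(0, length(x)))
  expect_error(seed_components(flat, c(500, 550)), "minima")
})

test_that("seeding on averaged 7-band amide spectra hits distinct centers", {
  set.seed(31)
  hits <- replicate(15, {
    sd_ <- sample.int(1e6, 1)
    tr <- gliadin_truth(seed = sd_, noise_sigma = 0.005, min_separation = 10)
    reps <- lapply(1:3, function(r) generate_spectrum(tr, r)$spectrum)
    avg <- suppressWarnings(average_replicates(reps))$mean
    sds <- tryCatch(seed_components(avg, c(1590, 1710)),
                    error = function(e) NULL)
    !is.null(sds) && nrow(sds) >= 4 && nrow(sds) <= 7 &&
      seeds_match_truth(sds$center, tr$components$center)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("noiseless fit from truth seeds recovers parameters exactly", {
  x <- seq(1000, 1200, by = 0.25)
  truth <- peak_component(c(1050, 1100, 1150), c(1, 0.5, 0.8), c(12, 18, 10))
  s <- raman_spectrum(x, pseudo_voigt(x, truth$center, truth$height,
                                      truth$fwhm, 0))
  fit <- fit_bands(s, c(1010, 1190), seeds = truth, baseline = FALSE)
  expect_true(fit$converged)
  expect_gte(fit$pearson_r, 1 - 1e-10)
  expect_equal(fit$components$center, truth$center, tolerance = 1e-6)
  expect_equal(fit$components$height, truth$height, tolerance = 1e-6)
  expect_equal(fit$components$fwhm, truth$fwhm, tolerance = 1e-6)
})

test_that("perturbed seeds still recover areas within 0.5%", {
  x <- seq(1000, 1200, by = 0.25)
  truth <- peak_component(c(1050, 1100, 1150), c(1, 0.5, 0.8), c(12, 18, 10))
  s <- raman_spectrum(x, pseudo_voigt(x, truth$center, truth$height,
                                      truth$fwhm, 0))
  set.seed(8)
  pert <- peak_component(truth$center + runif(3, -3, 3),
                         truth$height * runif(3, 0.7, 1.3),
                         truth$fwhm)
  fit <- fit_bands(s, c(1010, 1190), seeds = pert, baseline = FALSE)
  expect_lt(max(abs(fit$components$area - truth$area) / truth$area), 0.005)
})

test_that("lorentzian shape policy reproduces the closed-form area", {
  x <- seq(400, 800, by = 0.25)
  s <- raman_spectrum(x, pseudo_voigt(x, 600, 1.2, 15, 1))
  fit <- fit_bands(s, c(450, 750), seeds = peak_component(598, 1, 12, 1),
                   shape = "lorentzian", baseline = FALSE)
  expect_equal(fit$components$eta, 1)
  expect_equal(fit$components$area, pi / 2 * 1.2 * 15, tolerance = 1e-3)
})

test_that("noiseless multiband recovery from automatic seeding", {
  # well-separated truths: the decomposition must recover every area
  # within 1% when started from its own second-derivative seeds
  set.seed(97)
  for (rep_i in 1:12) {
    k <- sample(3:7, 1)
    centers <- sort(runif(1, 1590, 1605) + cumsum(runif(k, 14, 18)))
    truth <- peak_component(centers, runif(k, 0.3, 1), runif(k, 10, 16))
    x <- seq(1570, 1730, by = 0.25)
    s <- raman_spectrum(x, pseudo_voigt(x, truth$center, truth$height,
                                        truth$fwhm, 0))
    fit <- fit_bands(s, c(1580, 1720), baseline = FALSE,
                     bin_step = 0, d2_window = 7, min_prominence = 0.02)
    expect_equal(nrow(fit$components), k)
    got <- sort(fit$components$area)
    expect_lt(max(abs(got - sort(truth$area)) / sort(truth$area)), 0.01)
  }
})

test_that("accepted refinement steps never increase the cost", {
  g <- generate_spectrum(gliadin_truth(seed = 77, noise_sigma = 0.005))
  fit <- decompose_amide_i(g$spectrum)
  expect_true(all(diff(fit$rss_trace) <= 1e-12))
})

test_that("fit quality degrades monotonically with noise in expectation", {
  rs <- sapply(c(0, 0.002, 0.01), function(sig) {
    mean(sapply(1:4, function(i) {
      g <- generate_spectrum(gliadin_truth(seed = 1000 + i, noise_sigma = sig))
      decompose_amide_i(g$spectrum)$pearson_r
    }))
  })
  expect_gte(rs[1], 1 - 1e-9)
  expect_true(all(diff(rs) <= 1e-4))
})

test_that("band_fit methods are coherent", {
  g <- generate_spectrum(gliadin_truth(seed = 5, noise_sigma = 0.002))
  fit <- decompose_amide_i(g$spectrum)
  expect_s3_class(fit, "band_fit")
  expect_equal(length(fitted(fit)), length(fit$data$wavenumber))
  expect_equal(fitted(fit) + residuals(fit), fit$data$intensity)
  expect_equal(unname(predict(fit)), fit$fitted_curve)
  cm <- coef(fit)
  expect_equal(colnames(cm), c("center", "height", "fwhm", "eta"))
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_equal(length(sims[[1]]$intensity), length(fit$fitted_curve))
  expect_output(print(fit), "Band decomposition")
  expect_output(print(summary(fit)), "Pearson r")
})
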