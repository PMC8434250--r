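test_that("a noise-free single-band truth equals the closed-form curve", {
  comp <- peak_component(520, 1, 12)
  tr <- synthetic_truth(comp, noise_sigma = 0, grid = c(480, 560, 0.25),
                        seed = 1)
  g <- generate_spectrum(tr)
  x <- g$spectrum$wavenumber
  expect_lt(max(abs(g$spectrum$intensity - gauss_curve(x, 520, 1, 12))),
            1e-12)
})

test_that("generated noise matches the requested sigma", {
  comp <- peak_component(520, 1, 12)
  ratios <- sapply(1:50, function(i) {
    tr <- synthetic_truth(comp, noise_sigma = 0.01, grid = c(480, 560, 0.25),
                          seed = i)
    g <- generate_spectrum(tr)
    clean <- gauss_curve(g$spectrum$wavenumber, 520, 1, 12)
    sqrt(mean((g$spectrum$intensity - clean)^2)) / (0.01 * max(clean))
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("gliadin preset places bands inside the published windows", {
  tr <- gliadin_truth(seed = 99)
  expect_equal(nrow(tr$components), 7)
  ctr <- sort(tr$components$center)
  win <- rbind(c(1607, 1610), c(1620, 1627), c(1634, 1640), c(1649, 1652),
               c(1662, 1664), c(1677, 1678), c(1690, 1692))
  for (i in 1:7) {
    expect_gte(ctr[i], win[i, 1])
    expect_lte(ctr[i], win[i, 2])
  }
  expect_equal(sum(tr$fractions), 100, tolerance = 1e-9)
})

test_that("study sets have the requested shape and are seed-deterministic", {
  set_a <- generate_study_set("gliadin_liquid", n_samples = 2,
                              n_replicates = 3, seed = 7)
  expect_length(set_a, 2)
  expect_length(set_a[[1]]$replicates, 3)
  set_b <- generate_study_set("gliadin_liquid", n_samples = 2,
                              n_replicates = 3, seed = 7)
  expect_identical(serialize(set_a, NULL), serialize(set_b, NULL))
  set_c <- generate_study_set("gliadin_liquid", n_samples = 2,
                              n_replicates = 3, seed = 8)
  expect_false(identical(set_a[[1]]$replicates[[1]]$intensity,
                         set_c[[1]]$replicates[[1]]$intensity))
  expect_error(generate_study_set("gliadin_liquid", n_replicates = 2),
               ">= 3")
})

test_that("flat simplex priors average to equal fractions", {
  frs <- t(sapply(1:400, function(i) gliadin_truth(seed = i)$fractions))
  # CLT: SD of a flat 5-simplex coordinate ~ 16.3pp -> SE ~ 0.82pp
  expect_lt(max(abs(colMeans(frs) - 20)), 3)
})

test_that("replicate jitter is statistically visible in replicate spread", {
  tr <- gliadin_truth(seed = 3, noise_sigma = 0.001, replicate_jitter = 0.03)
  reps <- lapply(1:6, function(r) generate_spectrum(tr, r)$spectrum)
  peak_h <- sapply(reps, function(s) max(s$intensity))
  cv <- sd(peak_h) / mean(peak_h)
  expect_gt(cv, 0.003)
  expect_lt(cv, 0.1)
})

test_that("truth invariants are enforced", {
  comp <- peak_component(520, 1, 12)
  expect_error(synthetic_truth(comp, replicate_jitter = 0.08), "below 0.05")
  expect_error(synthetic_truth(comp, background = rep(1, 6)), "degree")
  expect_error(peak_component(520, 1, -3), "fwhm")
  expect_error(peak_component(520, 1, 10, 1.4), "eta")
})

test_that("a tiny recovery experiment behaves like its oracle", {
  tab <- recovery_experiment("gliadin_liquid", noise_grid = c(0, 0.01),
                             n_per_cell = 4, seed = 42)
  sm <- attr(tab, "summary")
  expect_equal(sm$n_failed, c(0, 0))
  b0 <- tab[tab$sigma == 0, ]
  # 4 truths per cell: the bias estimate itself carries sampling noise
  expect_lt(max(abs(b0$bias)), 1)
  # noiseless cells cannot be outperformed by noisy ones
  r0 <- max(tab$rmse[tab$sigma == 0])
  r1 <- max(tab$rmse[tab$sigma == 0.01])
  expect_lte(r0, r1 + 0.5)
  expect_gte(min(sm$min_pearson_r), 0.999)
})
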