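# shared helpers for building small synthetic inputs in tests

gauss_curve <- function(x, center, height, fwhm) {
  pseudo_voigt(x, center, height, fwhm, 0)
}

# a random valid spectrum for round-trip properties
random_spectrum <- function(n = 50, seed = 1) {
  set.seed(seed)
  raman_spectrum(sort(runif(n, 300, 2000)), runif(n, 0, 5),
                 meta = list(sample_id = paste0("s", seed), laser_power = 0.5))
}

# greedy check: every seed within tol of a distinct truth center
seeds_match_truth <- function(seed_centers, truth_centers, tol = 4) {
  if (length(seed_centers) > length(truth_centers)) return(FALSE)
  d <- abs(outer(seed_centers, truth_centers, "-"))
  used <- rep(FALSE, length(truth_centers))
  for (i in seq_along(seed_centers)) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (d[i, j] > tol) return(FALSE)
    used[j] <- TRUE
  }
  TRUE
}
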