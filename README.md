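# ramandec

Band decomposition and structure quantification for FT-Raman spectra of
proteins and protein-rich plant material (wheat kernel endosperm, gluten
protein extracts).

## What it does

Vibrational spectra of such samples encode protein structure in crowded,
unresolved regions. `ramandec` implements the standard quantitative
workflow as a tested, scriptable pipeline:

* **Preprocessing** — replicate averaging (≥3 acquisitions, SD monitoring
  against the 5% convention), region cropping, fluorescence baseline
  correction through anchor-window minima (linear or polynomial ≤5), and
  normalization to the C–H deformation reference band at 1460 cm⁻¹.
* **Band decomposition** — the core fitting engine `fit_bands()` models a
  region as a sum of pseudo-Voigt components

  *f*(ν) = *h*·[η·L(ν) + (1−η)·G(ν)],  area = η·(π/2)·*h*·*w* + (1−η)·*h*·*w*·√(π/4ln2),

  seeded from local minima of the Savitzky–Golay second derivative and
  refined by bounded Levenberg–Marquardt least squares with an analytic
  Jacobian, deterministic multistart, and F-tested split/prune/merge model
  repair. Returns a classed `band_fit` object with `print`, `summary`,
  `coef`, `fitted`, `residuals`, `predict`, `plot` and `simulate` methods.
* **Quantification** — amide I (1590–1710 cm⁻¹) secondary-structure
  fractions (β-sheet, α-helix, random coil, β-turn, antiparallel β-sheet;
  aromatic side-chain bands fitted but excluded from the denominator);
  disulfide-bridge conformer fractions (g-g-g ~510, t-g-g ~525, t-g-t
  ~545 cm⁻¹) from the 500–550 cm⁻¹ region; tyrosine Fermi doublet ratio
  I(855)/I(835) with hydrogen-bonding categories; tryptophan 760 cm⁻¹
  intensity; marker-band detection (starch 480/940 cm⁻¹, C–S bands, ...).
* **Synthetic data** — seeded generators (`gliadin_truth()`,
  `ss_region_truth()`, `endosperm_truth()`) with known component truth,
  fluorescence background and replicate structure, plus
  `recovery_experiment()` for bias/RMSE characterization.
* **I/O and orchestration** — two-column CSV/TSV and JCAMP-DX readers,
  lossless round-trip writer, YAML-configurable `run_pipeline()` producing
  JSON/CSV reports and a per-sample feature matrix for external
  multivariate tools.

## Worked example

Generate a synthetic gliadin-extract amide I spectrum whose true structural
composition is pinned to 19 / 25 / 26 / 27 / 3 percent, decompose it, and
quantify:

```r
library(ramandec)

tr  <- gliadin_truth(seed = 2024, fractions = c(19, 25, 26, 27, 3),
                     noise_sigma = 0)
fit <- decompose_amide_i(generate_spectrum(tr)$spectrum)
fit
#> Band decomposition over [1590, 1710] cm-1 (gaussian)
#>   7 components, Pearson r = 1.000000, residual RMS = 4e-16
#>   converged: TRUE (343 iterations)
quantify_amide_i(fit)$fractions
#>  beta_sheet alpha_helix random_coil   beta_turn abeta_sheet
#>          19          25          26          27           3
```

On a noise-free spectrum the decomposition recovers the generating
components exactly — centers, widths, heights and therefore the fraction
vector. With measurement noise (default 0.5% of peak intensity) the fitted
composite still tracks the data almost perfectly:

```r
g   <- generate_spectrum(gliadin_truth(seed = 2024, noise_sigma = 0.005))
decompose_amide_i(g$spectrum)$pearson_r
#> [1] 0.999884
```

but individual fractions of strongly overlapped neighbours (α-helix vs
random coil) carry substantial per-spectrum uncertainty; across many
samples the estimates are unbiased to ~1 pp. The methods vignette
(`vignettes/band-decomposition.Rmd`) quantifies this conditioning limit and
documents every default.

A full kernel-endosperm run:

```r
set_ <- generate_study_set("endosperm", n_samples = 1, n_replicates = 3,
                           seed = 11)
cfg <- default_config("endosperm")
cfg$samples <- list(list(id = "kernel01", spectra = set_[[1]]$replicates))
out <- run_pipeline(cfg, outdir = "results")
out$samples$kernel01$regions$ss_conformers$report
out$samples$kernel01$markers$tyr$ratio
```

writes `kernel01_report.json`, component tables and a feature-matrix CSV
under `results/`, each report embedding the config hash and package
version; reruns with the same config and seed are byte-identical.

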