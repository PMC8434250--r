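---
title: "Quantifying protein structure from FT-Raman spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein structure from FT-Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramandec)
```

## The problem

FT-Raman spectra of protein-rich plant material — wheat kernel endosperm and
liquid gliadin extracts are the motivating case — carry quantitative
structural information in a handful of crowded spectral regions:

* the **amide I** band (1590–1710 cm⁻¹), whose sub-band composition reflects
  the secondary structure of the proteins: β-sheet (1634–1640 cm⁻¹),
  α-helix (1649–1652 cm⁻¹), random coil (~1663 cm⁻¹), β-turn
  (1677–1678 cm⁻¹), and antiparallel β-sheet (1690–1692 cm⁻¹), with two
  aromatic side-chain bands (1607–1610 and 1620–1627 cm⁻¹) interleaved;
* the **disulfide stretching** region (500–550 cm⁻¹), where S–S bridge
  rotamers appear as sub-bands near 510 (gauche-gauche-gauche), 525
  (trans-gauche-gauche) and 545 cm⁻¹ (trans-gauche-trans);
* **aromatic markers**: the tyrosine Fermi doublet at 855/835 cm⁻¹, whose
  height ratio reports the hydrogen-bonding state of the phenol OH, and the
  tryptophan indole band at 760 cm⁻¹.

None of these sub-bands is resolved: the information must be extracted by
decomposing each region into overlapping line-shape components and reading
relative **areas** as relative abundances. `ramandec` implements that
workflow end to end, with a seeded synthetic-spectrum generator so every
stage can be validated against a known ground truth.

## The model

Each band is a pseudo-Voigt profile, a linear mix of a Gaussian and a
Lorentzian sharing center $\nu_0$, height $h$ and full width at half
maximum $w$, with mixing fraction $\eta \in [0, 1]$:

$$ f(\nu) = h\left[\eta\,\frac{1}{1 + 4u^2}
  + (1-\eta)\, e^{-4\ln 2\, u^2}\right],
  \qquad u = \frac{\nu - \nu_0}{w}. $$

Its area on infinite support is closed-form,

$$ A = \eta\,\tfrac{\pi}{2} h w + (1-\eta)\, h w \sqrt{\tfrac{\pi}{4\ln 2}}, $$

and the package always reports this closed form rather than a numeric
integral over the finite fit window, so areas are comparable across shapes
and regions (tests verify the closed form against adaptive quadrature to
0.1%). The default shape policy is pure Gaussian ($\eta = 0$): condensed-
phase Raman bands of proteins are close to Gaussian, the original
region-fitting protocols used mixed "Gaussian and Lorentzian functions"
without assigning shapes per band, and fitting $\eta$ per band adds a
poorly determined parameter to an already crowded model. `shape =
"pseudo_voigt"` frees $\eta$ per band where needed.

A region model is the sum of its components plus a **local linear
baseline** fitted concurrently, which absorbs whatever broad background
survives the global correction.

## The preprocessing chain

The kernel (solid-sample) workflow mirrors standard practice:

1. **Replicate averaging** — at least three independent acquisitions are
   interpolated to a common grid and averaged; the pointwise sample SD is
   kept and a warning is raised wherever it exceeds 5% of the local mean
   (the conventional acceptability bound for replicate spread).
2. **Crop** to 300–2000 cm⁻¹, the information-bearing range for these
   samples.
3. **Fluorescence baseline** — kernels fluoresce strongly under 1064 nm
   excitation; the background is broad and smooth. The correction fits a
   linear or low-order (≤5) polynomial through the intensity minima of
   user-chosen anchor windows placed in band-free stretches, then
   subtracts it. Anchor-window minima, rather than a global fit, keep real
   bands from dragging the baseline.
4. **Normalization** to the C–H deformation band at 1460 cm⁻¹, present in
   every sample; all intensities are divided by the maximum found in
   1450–1470 cm⁻¹. Height (not area) is used as the divisor: it is the
   simplest reading of "normalized to the band", and it makes the whole
   chain exactly invariant to multiplication of the raw intensities by any
   positive constant (a property the test suite asserts).

Liquid gliadin extracts skip the global steps: the amide I region is
fitted directly with its local linear baseline.

Derivatives use Savitzky–Golay filtering (`signal::sgolayfilt`), default
window 11 points, polynomial order 3; the second derivative is exact for
quadratics, which the tests exploit as an oracle.

## Seeding, fitting, and model repair

**Seeding.** Overlapped band centers appear as local minima of the
smoothed second derivative. `seed_components()` bins the spectrum to
1 cm⁻¹ (trading grid resolution, which is abundant, for noise
suppression, which is scarce), differentiates with a 13 cm⁻¹ window,
keeps minima with at least 8% of the deepest minimum's depth, and
suppresses minima closer than 4 cm⁻¹. On three-replicate averaged
spectra these defaults place every seed within 4 cm⁻¹ of a distinct true
center in ≳95% of simulated 7-band amide I draws with ≥10 cm⁻¹
separation. Initial widths come from the Gaussian apex relation
$w = \sqrt{8\ln 2\, h / |d_2|}$, clipped to a plausible band.

**Fitting.** `fit_bands()` refines all parameters by bounded
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) with an analytic
Jacobian. Bounds encode prior knowledge: each component's center is
confined to its scheme's *fit window* — the literature band position,
narrower than the assignment window — expanded by ±2 cm⁻¹, which both
prevents label-crossing during refinement and improves the conditioning
of the area estimates; heights are non-negative; widths are bounded per
workflow (6–30 cm⁻¹ for amide I sub-bands, 5–20 cm⁻¹ for the S–S region
— one band may not masquerade as the regional background). Convergence
uses a relative-cost tolerance of 1e-10 with up to 500 iterations, and
the returned object records the monotone accepted-cost trace. In the
kernel workflow the S–S fit window extends to 468–558 cm⁻¹ so the starch
480 cm⁻¹ shoulder is modelled as its own (unassigned) component instead
of leaking into the disulfide sub-bands; quantification still uses only
the 500–550 cm⁻¹ scheme windows.

**Global search and model repair.** The least-squares surface of 5–9
strongly overlapped bands has flat valleys and local minima. The fitter
therefore runs a deterministic multistart (the original seeds, a
seeding-independent start with one band per scheme window, and up to 8
perturbed copies drawn under a seed derived from the region), stopping as
soon as the residual RMS reaches a robust noise floor estimated from
fourth differences of the data — a fit that reaches the floor has
explained everything explainable. If the floor is not reached, the
machinery tries structural repairs: *adding* a band where the smoothed
residual is largest (a band the seeding missed leaves a coherent
residual bump), *splitting* the largest components in two, *pruning*
components the data do not require, and *merging* the most overlapped
adjacent pair — each kept only when the change is overwhelmingly
significant by an extra-sum-of-squares F-test or lets the fit reach the
noise floor — with a few final basin hops (jittered restarts from the
best solution) and a high-precision polish (tolerance 1e-14). The
F-tests make these repairs safe under noise: a spurious extra band
never survives, a genuinely needed one never disappears. With this
machinery, noiseless synthetic amide I envelopes are recovered exactly
— component count, centers, widths and areas — in essentially every
random draw.

## Quantification

`quantify_amide_i()` assigns each fitted component to the window
containing its center (±2 cm⁻¹ for components falling between windows)
and reports 100·area/Σarea over the five structural labels. The two
aromatic bands are fitted — leaving them out would corrupt the β-sheet
estimate — but **excluded from the denominator**; published fraction
tables for this material sum to exactly 100 over the five structural
labels, which is only consistent with aromatic exclusion.
`quantify_ss_conformers()` works the same way over the three rotamer
classes, summing multiple sub-bands per class (curve-fitted kernel
spectra typically show two sub-bands each for t-g-g and t-g-t).

Default windows tile each region around the published positions:
amide I β-sheet [1630, 1644], α-helix [1645, 1656], random coil
[1657, 1670], β-turn [1671, 1683], aβ-sheet [1684, 1696], aromatic
[1603, 1613] and [1616, 1629]; S–S g-g-g [505, 517], t-g-g [517.5, 528],
t-g-t [528.5, 550]. All windows are configurable; fractions are carried
as floats and rounded only for display.

Marker analytics measure peak heights on the baseline-corrected,
1460-normalized spectrum in ±6 cm⁻¹ windows. The tyrosine ratio
I(855)/I(835) is categorized by the classical thresholds: below 0.9,
the phenol OH is a strong donor; 0.9–1.43, tyrosines act as both donors
and acceptors; above 1.43, the phenolic oxygen accepts a positive
charge; ratios ≥2 additionally flag exposed, anionic tyrosine. The
tryptophan 760 cm⁻¹ value is reported as a *height* on the normalized
scale — whether published intensities of this band are heights or areas
is ambiguous, and height is the assumption documented here.

## The synthetic generator

`gliadin_truth()`, `ss_region_truth()` and `endosperm_truth()` draw
ground truths from documented priors and `generate_spectrum()` renders
them: sum of pseudo-Voigt components, plus a smooth polynomial
(degree ≤4) background standing in for kernel fluorescence, plus
additive Gaussian noise at a stated fraction of the peak intensity
(default 0.5%), all deterministic given the seed. Replicates add an
independent noise stream and a multiplicative factor with SD 2%
(constrained below the 5% replicate-spread convention). Amide I truth
centers are drawn inside the published windows; structural fractions
come from a flat simplex prior unless pinned; widths default to
14–22 cm⁻¹ (structural) and 8–12 cm⁻¹ (aromatic), typical
condensed-phase values — the literature gives no widths, so these are
free parameters of the emulation. The endosperm preset adds the full
starch-dominated marker catalog, C–S bands, the tyrosine doublet
(ratio drawn from 1.5–2.6, the range seen in gluten-rich material) and
the tryptophan band (height 0.11–0.15 on the normalized scale).

What the generator does *not* emulate: detector-specific noise
statistics (shot noise, etalonning), cosmic spikes, water-vapor
interference, resonance and polarizability effects on intensities, and
any correlation between band positions and sample chemistry. Passing
recovery tests therefore demonstrate correctness of the *estimator
under the stated noise model*, not robustness to every artifact of real
instruments.

## What recovery can and cannot promise

A point worth stating plainly: with five structural plus two aromatic
bands of free center, height and width overlapping this strongly, the
per-spectrum fraction estimates are ill-conditioned at realistic noise.
A Cramér–Rao computation at 1% noise on the default grid puts the
*per-draw* standard deviation of individual fractions at several
percentage points or worse, because adjacent bands can trade area almost
freely. No fitting algorithm can beat that bound on a single spectrum.
What the decomposition does deliver — and what the recovery experiment
(`recovery_experiment()`) measures — is *unbiasedness*: across many
truths the per-label mean error stays below ~0.1 pp noiseless and
~1–2 pp at 1% noise, so cohort-level comparisons (the use case: comparing
structure between wheat lines) are sound. Per-sample numbers should be
read with the replicate-averaging and the fit-quality thresholds in
mind.

Fit quality itself is tight: on synthetic spectra at 0.5% noise the
Pearson correlation between composite and data stays above 0.9985 in the
S–S region and 0.9991 in amide I — the thresholds used as quality gates
(warnings, not errors) in `run_pipeline()`.

## Numerical choices and degenerate inputs

* Axes are strictly ascending; readers re-sort and collapse duplicates by
  mean. All region bounds are closed intervals.
* Baseline polynomials are fitted on a centered axis for conditioning;
  degenerate (coincident) anchors are an error.
* Normalization fails loudly when the reference window holds no positive
  signal, since silently dividing by noise would poison everything
  downstream.
* A region with no second-derivative minima is an error advising manual
  seeds; a flat-zero region cannot be decomposed.
* Ties in seeding (two minima within 4 cm⁻¹) resolve to the deeper one;
  two fitted components in one assignment window are both kept and their
  areas summed at quantification.
* Problem sizes in the test suite (20-spectrum quality cells, 100-truth
  recovery cells, 0.25 cm⁻¹ grids) match the simulation sizes used
  throughout this vignette's claims.

## Known limitations

* JCAMP-DX support covers AFFN-encoded `XYDATA=(X++(Y..Y))` and
  `XYPOINTS` tables; compressed SQZ/DIF/DUP encodings and proprietary
  instrument binaries (SPC, OPUS) are out of scope.
* No cosmic-ray despiking or scatter correction; spectra are assumed
  despiked upstream.
* No uncertainty quantification on band parameters (no bootstrap/MCMC);
  the recovery experiment characterizes estimator behavior in aggregate.
* Amide III is not analyzed (weak and heavily overlapped in these
  samples); multivariate analysis (PCA, clustering) is deliberately left
  to external tools — the pipeline exports the per-sample feature matrix
  they consume.
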