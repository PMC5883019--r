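# flimcarbon

Fluorescence-lifetime analysis of NAD(P)H for tracking the fate of
glucose carbon.

NAD(P)H is an endogenous fluorophore whose excited-state lifetime depends
on whether it is free in solution or bound to a metabolic enzyme — and
*which* enzyme. Time-correlated single photon counting (TCSPC) FLIM
therefore offers a label-free window on the activity of enzymes that
route carbon toward or away from the TCA cycle (LDH, MDH, G6PDH, PDH).
`flimcarbon` implements the full analysis chain for this kind of
experiment, for microscopists and image analysts who have TCSPC decay
histograms (or want to simulate them) rather than vendor software:

* **Decay modelling and fitting** — multi-exponential decays convolved
  with the instrument response function,
  `I(t) = [Σᵢ αᵢ e^(−t/τᵢ)] ⊗ IRF(t) + C`, fitted by iterative
  reconvolution (Levenberg–Marquardt) with per-component fixed/free
  lifetime masks, Neyman or Poisson-likelihood weighting, reduced-χ²
  model-order selection, and the amplitude-weighted mean lifetime
  `τ_m = Σᵢ αᵢ τᵢ`.
* **Two-enzyme unmixing** — three-component fits with all lifetimes fixed
  (free NADH 0.45 ns, NADH–MDH 1.2 ns, NADH–LDH 1.6 ns), and a
  through-origin regression (uncentered R²) of the FLIM-measured LDH
  fraction of bound signal against the true concentration fraction.
* **Solution design** — binding-equilibrium calculators:
  `[E] = (1−α₁)·[NAD(P)H] / (F·S)` with site occupancy
  `F = α₁[NAD(P)H] / (α₁[NAD(P)H] + K_D)`, plus the exact forward
  solver for the free fraction (single-enzyme closed form, competitive
  two-enzyme bisection).
* **Cell-image pipeline** — 3×3-binned per-pixel two-component fits with
  free τ₁, per-pixel optical redox ratio (NAD(P)H/FAD intensity),
  per-cell cytoplasm aggregation with nucleus/background exclusion,
  control normalization, Welch and ratio-paired t-tests.
* **Synthetic data** — Poisson TCSPC decay, mixture-series and
  two-channel cell-scene generators with ground truth, so the whole
  pipeline is testable end to end without instrument data.

Everything is tidyverse-native: decays and IRFs are tibbles, results have
`tidy()`/`glance()` methods and `autoplot()` figures, and per-cell
summaries come back as tibbles ready for `dplyr`.

Supported file formats are plain-text CSV for decays/IRFs/designs and
multi-page TIFF for FLIM stacks and label masks; vendor binary formats
are not read.

## Worked example

Design a solution, simulate its decay, and fit it back:

```r
library(flimcarbon)

axis <- time_axis(256, 12.5)           # 256 bins over 12.5 ns
irf  <- make_irf(fwhm_ps = 220, axis)  # synthetic Gaussian IRF

# enzyme needed so that half of 50 uM NADH stays free (K_D 25 uM, 2 sites)
required_enzyme_concentration(50, alpha1 = 0.5, kd = 25, sites = 2)
#> [1] 25

# simulate a solution where 40% of the NADH amplitude is MDH-bound ...
truth <- multi_exp_model(alpha = c(0.6, 0.4), tau = c(0.45, 1.2),
                         background = 10)
decay <- simulate_solution_decay(truth, irf, seed = 1)

# ... and fit it with the free lifetime fixed at 450 ps
fit <- fit_decay(decay, irf, fit_config(2, fix_tau = 0.45))
fit
#> <flim_fit: 2 components, reduced chi-squared 1.136, converged>
#> <multi_exp_model>
#>   component 1: alpha = 0.5953, tau = 0.4500 ns (tau fixed)
#>   component 2: alpha = 0.4047, tau = 1.1989 ns
#>   background C = 7.958 counts/bin, shift = 0 bins
```

The fit recovers the bound amplitude (0.405 vs 0.40 true) and the
MDH-bound lifetime (1.199 vs 1.20 ns true) from a decay with ~2×10⁵
photons, with a reduced χ² near 1 as expected for well-specified Poisson
data. Unmixing the four-mixture LDH/MDH series works the same way:

```r
sims <- simulate_mixture_series(replicates = 3, seed = 1)
unmix_mixtures(sims, irf)
#> <unmix_result: 12 decays, m = 1.007, R^2 = 1.000 (p = 4.3e-22)>
```

The slope near 1 and uncentered R² ≈ 1 say that the fitted
`α_LDH/(α_LDH+α_MDH)` tracks the true `[LDH]/([LDH]+[MDH])`
proportionally through the origin. `autoplot()` on the fit, the
parameter maps, or the unmixing result draws the corresponding figures;
see the methods vignette (`vignettes/flim-carbon-methods.Rmd`) for the
models, conventions and limitations.

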