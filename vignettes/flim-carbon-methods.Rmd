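---
title: "Models and methods behind flimcarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flimcarbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimcarbon)
library(dplyr)
```

## The measurement and the model

Time-correlated single photon counting (TCSPC) FLIM records, for every
image pixel, a histogram of photon arrival times relative to the laser
pulse. NAD(P)H autofluorescence decays as a mixture of a short *free*
component and a longer *protein-bound* component, so the decay of a pixel
(or a whole solution) is modelled as

$$I(t) = \Big[\textstyle\sum_{i} \alpha_i\, e^{-t/\tau_i}\Big] \otimes
\mathrm{IRF}(t) + C,$$

with 1–3 components, fractional amplitudes $\alpha_i$ (normalized to sum
to one), lifetimes $\tau_i$, a constant background $C$ per bin, and
convolution with the instrument response function (IRF). The
amplitude-weighted mean lifetime is $\tau_m = \sum_i \alpha_i \tau_i$.
`evaluate_model()` implements this forward model; `fit_decay()` inverts it
by iterative reconvolution.

Key conventions:

* **Time axis.** 256 bins spanning 12.5 ns by default (one 80 MHz
  repetition period, ≈48.8 ps bins). TCSPC hardware rarely reports the bin
  width in its exports, so `time_axis()` makes it explicit and
  configurable. All lifetimes are in ns internally.
* **Convolution.** Linear (zero-padded) discrete convolution by default.
  For lifetimes approaching the repetition period, fluorescence from the
  previous pulse wraps into the record; `periodic = TRUE` switches to
  circular convolution for that "incomplete decay" situation. For the
  lifetimes relevant here (≤ 2.5 ns in solutions) linear is adequate.
* **IRF.** Synthetic IRFs are discrete Gaussians with a 220 ps FWHM,
  peaked at 10% of the window, unit sum. Measured IRFs can be supplied as
  two-column CSV. A fractional-bin shift between IRF and decay can be
  co-fitted (`fit_shift = TRUE`); it defaults to off because the generator
  introduces no shift.
* **Amplitude convention.** $\alpha_i$ are *pre-exponential* amplitude
  fractions (the convention of TCSPC analysis software), not photon-count
  fractions; a component's photon share is $\alpha_i\tau_i / \sum_j
  \alpha_j\tau_j$.

## Fitting

`fit_decay()` uses Levenberg–Marquardt (via `minpack.lm`) on weighted
residuals with box constraints ($\tau \in [0.05, 10]$ ns, amplitudes and
$C \ge 0$). Two weightings are available:

* `neyman` — residuals scaled by $1/\sqrt{\max(\text{counts}, 1)}$, the
  long-standing convention for TCSPC chi-squared fitting. It is the
  default for whole-solution decays, which carry $10^5$–$10^6$ photons and
  where it is effectively unbiased.
* `poisson_mle` — signed square-root Poisson deviance residuals, so that
  the least-squares engine minimizes the exact Poisson negative
  log-likelihood. This is the default inside `fit_image()`: a 3×3-binned
  pixel decay carries only a few thousand photons, and at those counts
  Neyman weighting over-weights downward-fluctuating tail bins and biases
  the bound lifetime low by on the order of 10%, while the likelihood
  weighting shows no measurable bias on synthetic uniform images.

Initial values: free lifetimes start from (0.4, 2.0, 3.5) ns, amplitudes
share the above-background photons equally, $C$ starts from the mean of
the bins before the rising edge, shift from 0. Reported reduced
chi-squared always uses the Neyman definition over all bins, with degrees
of freedom $n_{\text{bins}} - n_{\text{free}}$; after fitting, components
are relabelled in order of increasing lifetime so that component 1 is
always the free-NAD(P)H component. Non-convergence is flagged on the
result rather than raised, so image pipelines can skip bad pixels.

Model order is chosen by `select_model()`: the smallest order whose
reduced chi-squared the next order fails to improve by more than 5%
(configurable). This mirrors the common practice of adopting a
two-exponential model whenever a three-exponential fit does not improve
the goodness of fit. Note that a three-component decay with closely
spaced bound lifetimes (1.2 vs 1.6 ns) is *not* reliably distinguished
from a two-component model at realistic photon counts — which is exactly
why the two-enzyme analysis fixes all three lifetimes instead of letting
the order selection find them.

Two analysis regimes follow the same asymmetry as practice:

* **Solutions** — all pixels binned into one decay (peak counts above
  3000), two components, $\tau_1$ fixed at 0.45 ns (450 ps, the measured
  pure-NADH lifetime); or three components with all lifetimes fixed at
  0.45/1.2/1.6 ns for two-enzyme unmixing.
* **Cells** — 3×3 binning only (peak gate 15) to preserve spatial
  resolution, two components with $\tau_1$ *free*, because pH, O₂ and
  viscosity heterogeneity inside cells shifts the free lifetime.

## Binding-equilibrium solution design

To make solutions with a chosen free fraction $\alpha_1$ of NAD(P)H, the
required enzyme concentration is

$$[E] = \frac{(1-\alpha_1)\,[\mathrm{NAD(P)H}]}{F \cdot S},
\qquad
F = \frac{\alpha_1 [\mathrm{NAD(P)H}]}{\alpha_1 [\mathrm{NAD(P)H}] + K_D},$$

where $S$ is the integer number of binding sites per enzyme molecule and
$F$ the equilibrium occupancy of those sites at the target free-ligand
concentration. The numerator is the bound-ligand concentration
$(1-\alpha_1)L$: this is the only dimensionally consistent reading of the
design formula (a bare fraction cannot be subtracted from a
concentration), and it is the reading under which the design and the
forward equilibrium (`predict_free_fraction()`, the positive root of the
single-site mass-balance quadratic) are exact inverses — a property the
test suite asserts to $10^{-9}$ over a grid of targets and affinities.
Mixtures of two enzymes use a bisection solver for the competitive mass
balance. $K_D$ and $S$ are required inputs;
`enzyme_binding_defaults()` ships clearly non-authoritative placeholder
values for examples only, because published constants vary with buffer,
temperature and assay.

## Two-enzyme unmixing and its regression

For NADH + MDH + LDH mixtures, decays are fitted with three fixed
lifetimes (free 0.45 ns, MDH-bound 1.2 ns, LDH-bound 1.6 ns — the values
measured in single-enzyme titrations), leaving only the amplitude triple
free. The FLIM-measured LDH share of the bound signal,
$\alpha_{\mathrm{LDH}} / (\alpha_{\mathrm{LDH}} +
\alpha_{\mathrm{MDH}})$, is regressed on the true concentration share
$[\mathrm{LDH}]/([\mathrm{LDH}]+[\mathrm{MDH}])$ with the line forced
through the origin. With a forced zero intercept the familiar centered
$R^2$ is not meaningful, so `regress_through_origin()` reports the
**uncentered** definition $1 - \mathrm{SS}_{\mathrm{res}} / \sum y^2$
(the convention of common graphing software for through-origin fits);
a centered $R^2$ computed on the same fit would differ and can even go
negative. Both the slope-test p-value and the correlation-test p-value
are reported, since a lone "p-value of the line" is ambiguous between
the two.

The simulated mixture series takes the free amplitude of each mixture
from the measured free-NADH row of the four-mixture design table and
splits the bound amplitude between MDH and LDH in proportion to their
concentrations — the proportionality that the regression is designed to
validate. A competitive-equilibrium truth rule is available instead
(`truth_rule = "equilibrium"`) for sensitivity analyses.

## The image pipeline

`fit_image()` produces per-pixel maps of $\alpha_1$, $\tau_1$, $\tau_2$,
$\tau_m$, reduced chi-squared and intensity (the integral of the
*unbinned* pixel decay). The optical redox ratio is computed per pixel as
NAD(P)H intensity / FAD intensity, without binning; `per_cell_summary()`
averages maps over each cell's cytoplasm (cell mask minus nucleus mask,
NaN pixels excluded, cells with fewer than 10 valid pixels dropped), and
`normalize_to_control()` expresses group means relative to a control.
Aggregation order is pixel → cell → dish/group, and per-cell values are
the unit of statistical comparison. Background is defined as label 0 in
the cell mask; segmentation itself is an input (ground-truth masks from
the generator, or any labelled segmentation), with a convenience
Otsu-plus-connected-components labeller for exploration only.

Group statistics mirror the study design: Welch's unpaired t-test
(Satterthwaite degrees of freedom) for lifetime variables across
replicates, and a ratio-paired t-test — a one-sample t-test on
$\log(\mathrm{after}/\mathrm{before})$ — for strictly positive,
multiplicatively varying quantities such as redox ratios and intensities.
Degenerate inputs follow documented conventions (identical constant
groups give $p = 1$; an exact constant fold-change gives $p \to 0$).

## The synthetic-data generator

The generator exists so every stage is testable with known ground truth:

* **Solutions** (`simulate_solution_decay()`) — independent Poisson draws
  around the forward-model expectation. The default budget targets an
  expected peak of 10⁴ counts, comfortably above the solution gate of
  3000 and representative of a whole-image binned decay; a constant
  background of ~10 counts/bin stands in for detector/room light and is
  co-fitted, never subtracted.
* **Mixtures** (`simulate_mixture_series()`) — the four-mixture design
  with 3 replicates, lifetimes 0.45/1.2/1.6 ns, per-replicate seeds
  derived from a base seed.
* **Cell scenes** (`simulate_cell_scene()`) — non-overlapping elliptical
  cells (rejection sampling, capped attempts) with concentric nuclei on a
  256×256 grid by default. Per-cell truths are drawn once per cell:
  $\alpha_1 \sim N(0.75, 0.03)$, $\tau_1 \sim N(0.6, 0.1)$ ns,
  $\tau_2 \sim N(2.7, 0.2)$ ns (inside the 2.4–2.9 ns range typical of
  cytoplasmic NAD(P)H), redox ratio $\sim N(1.4, 0.15)$, all truncated to
  physical ranges. These are plausible stand-ins; joint cellular
  $(\alpha, \tau)$ distributions are not published numerically. The
  default cytoplasm budget of 300 photons/pixel puts ≈2700 photons in
  each 3×3-binned decay — enough for a stable free-$\tau_1$
  two-component fit — with nuclei at half brightness and near-zero
  background. The FAD channel is scaled so each cell's expected
  NAD(P)H/FAD ratio equals its drawn truth.

What the generator does *not* emulate: optical point-spread blur,
photobleaching, drift, detector afterpulsing/dead-time, spatial gain
variation, or autofluorescence from anything but the two modelled
channels. Tests passing on synthetic scenes therefore validate the
*analysis* (fitting, unmixing, aggregation, statistics), not robustness
to those instrumental effects.

All randomness is seed-local: generator functions take a `seed` argument,
restore the caller's RNG state, and identical (config, seed) pairs
reproduce outputs bit for bit.

## Problem sizes and numerical choices

The shipped tests run titrations and mixture series at full 256-bin
resolution with 10⁶-photon decays, and exercise the image pipeline on
48×48-pixel scenes with 128 bins and 3–4 cells — large enough for
per-cell recovery within a few percent, small enough that the whole
suite runs in well under a minute. Degenerate inputs are contracted
explicitly: all-zero histograms and empty images raise errors; photon-
starved pixels yield NaN maps; unplaceable cell packings fail with
advice to change seed or geometry. FFT round-off in the convolution is
clipped at zero so expected counts are always non-negative.

## Known limitations

* The reconvolution fit is model-equivalent to, but not bit-identical
  with, commercial TCSPC analysis software, whose deconvolution internals
  and fit-range defaults are undocumented.
* The SNR gates (3000 for solutions, 15 for cells) are implemented as
  peak-bin counts — the binned-decay convention — because no formula
  accompanies the thresholds in the source material.
* Amplitude standard errors are reported for the optimizer's raw
  parameters; uncertainties of the *normalized* amplitude fractions are
  not propagated.
* Reading of vendor binary TCSPC files (e.g. SDT) is out of scope; use
  CSV decays and TIFF stacks.
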