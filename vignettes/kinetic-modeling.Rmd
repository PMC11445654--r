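---
title: "Kinetic modeling of homogeneous mixed-acid nitration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of homogeneous mixed-acid nitration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrokinetics)
```

## The model

`nitrokinetics` implements the kinetic-modeling workflow for homogeneous
nitration of an isourea substrate (IO) by nitric acid in concentrated
sulfuric acid, as run in continuous-flow microreactors. The chemistry is
electrophilic nitration: H2SO4 protonates HNO3 to the nitronium ion NO2+,
which is the species that actually attacks the substrate. The workflow has
four layers.

**1. Apparent second-order kinetics.** With rate law
$-dc_{IO}/dt = k\,c_{IO}\,c_{HNO_3}$ and molar excess
$M = c_{HNO_3,0}/c_{IO,0} > 1$, the integrated law linearizes as

$$\ln\!\left[\frac{M - x}{M(1 - x)}\right] = (M-1)\,c_{IO,0}\,k\,t,$$

where $x$ is the conversion of IO. `fit_apparent_k()` regresses this
transform on time (ordinary least squares, free intercept) and reads $k$
off the slope. The reaction orders themselves are established first by the
classical integral method (`infer_orders()`): candidate integrated forms
are fitted and the pair with the highest $R^2$ wins.

**2. Intrinsic decomposition.** The apparent $k$ depends strongly on acid
strength because both the nitronium fraction and the medium activity do.
The decomposition

$$\lg k = \lg\frac{c_{NO_2^+}}{c_{HNO_3}} + n\,M_c + \lg k_0$$

(all $\lg$ base 10) separates a medium term (the nitronium fraction), a
Marziano-type activity-coefficient function $M_c$ scaled by a
compound-specific parameter $n$, and the intrinsic nitronium-based rate
constant $k_0$, which is independent of acid strength. Per temperature,
`fit_intrinsic()` regresses $\lg k - \lg(c_{NO_2^+}/c_{HNO_3})$ on $M_c$:
slope $n$, intercept $\lg k_0$.

**3. Arrhenius extraction.** `fit_arrhenius()` fits
$\ln k_0 = -E_a/(RT) + \ln A$ by OLS of $\ln k_0$ on $1/T$ across all
temperatures simultaneously, with $R = 8.314$ J/(mol K) (configurable).
Base-10 and natural logs are kept strictly separate: the decomposition is
base 10, the Arrhenius fit natural.

**4. Prediction and optimization.** `predict_k()` recomposes $\lg k$ at any
(acid strength, temperature), `predict_conversion()` inverts the integrated
law, `response_surface()` evaluates grids, and `optimize_conditions()`
performs an exhaustive grid search, with every prediction carrying a
three-state calibration flag (interior / extrapolated / rejected).

## Medium model: from mass fraction to Mc

The $M_c$ correlation takes H2SO4 molarity, but operating conditions are
stated as mass fractions. The bridge is a bundled room-temperature density
table (80-100 wt %, 1-point steps, linear interpolation):
$c = \rho(w)\cdot 1000\cdot(w/100)/98.08$. Density's own temperature
dependence is ignored; the temperature correction enters only through

$$M_c(T) = M_c(298\,\mathrm{K})\left[\frac{200}{T} + 0.3292\right],$$

whose bracket equals 1 at 298.15 K to within $10^{-5}$. At 298 K, $M_c$ is
the negative of a quintic in molarity, calibrated for 15.2-18.4 mol/L
(88-98 wt % maps inside this window). Outside the window the package
evaluates anyway with a warning; a strict flag turns that into an error.
All public interfaces traffic in the signed $M_c$ (negative over the
calibrated range); the negation in the published correlation is internal.

## Nitronium model: a two-stage empirical surface

The nitronium fraction $\lg(c_{NO_2^+}/c_{HNO_3})$ is not computed from
first principles; it is fitted from a user-supplied literature-style table
(`fit_nitronium()`). Stage 1 fits a straight line in mass fraction within
each tabulated temperature; stage 2 evaluates those lines on a 1-point
mass-fraction grid and fits each grid point linearly in $1/T$. Evaluation
interpolates linearly between the bracketing grid lines, which reproduces
the discrete-curves construction of the original procedure while giving a
continuous surface. Queries outside the calibrated (w, T) ranges are
evaluated and flagged, never silently truncated, because validation and
extrapolation studies deliberately probe beyond calibration.

The package cannot ship the literature data behind this surface. The
bundled `inst/extdata/nitronium_synthetic.csv` is generated by
`generate_nitronium_table()` from the package's own ground truth and is
labeled synthetic in its header; treat it as plumbing for examples and
tests, not as data.

## The synthetic-data generator

`ground_truth()` fixes a generating model: Arrhenius parameters
$E_a = 192.57$ kJ/mol and $\ln A = 102.55$, $n(T)$ affine in temperature
(1.0764 at 303.15 K, slope $8.13\times 10^{-3}$ per K), the bundled $M_c$
correlation, and a nitronium surface affine in mass fraction and linear in
$1/T$ ($a(w) = 20w - 610$, $b(w) = 0.214w - 23.86$). The nitronium
coefficients are a package convention, chosen once so that the generated
apparent rate constants show the structure characteristic of mixed-acid
nitration — a mild apparent temperature dependence despite the large
intrinsic activation energy (the medium terms partially cancel the
Arrhenius term), and an interior maximum of $k$ over acid strength near
91-94 wt % — and so that conversions over the default campaign stay in an
informative range (roughly 0.15-0.95).

The default campaign mirrors the study design: 30/35/40 °C crossed with
88-98 wt % H2SO4 (2-point steps) and residence times of 1-4.7 min, at
$M = 4.4$ and $c_{IO,0} = 0.5$ mol/L. Noise is additive Gaussian on
conversion (default sd 0.01, a repository convention — replicate variance
is rarely reported for such campaigns), truncated to $[0, 0.999]$. Every
stochastic generator takes an explicit seed and embeds it, with all truth
values, in the emitted object's metadata.

What the generator does *not* emulate: mass-transfer-limited regimes,
heteroscedastic or autocorrelated measurement error, drift between runs,
and any systematic bias of the HPLC readout. Passing recovery tests
therefore demonstrate the correctness and noise behavior of the fitting
pipeline, not the adequacy of the second-order rate law for any particular
real reaction.

## Numerical choices

- **Integrated-form candidates.** As commonly printed, the second-order
  pseudo form and the mixed form carry sign/constant inconsistencies; the
  package implements the standard self-consistent forms
  ($1/(1-x) = 1 + c_{IO,0}K t$ for the pseudo-second-order candidate, the
  excess transform above for the mixed form). For order inference with an
  inferred substrate order of 2, the HNO3-order candidates are the
  second-order-in-IO integrated form ($\beta = 0$) and the exact
  partial-fraction integral of $dx/[(1-x)^2(M-x)]$ ($\beta = 1$), so all
  four candidate pairs are generated and selected self-consistently.
- **Order identifiability.** Orders are only distinguishable when the
  experiment spans curvature. The test-suite design uses a 14-fold excess
  pseudo run to high conversion and a near-stoichiometric mixed run
  ($M = 1.05$, $x$ up to 0.98) whose HNO3 depletion separates the
  $\beta$ candidates; at $M = 4.4$ and moderate conversions the candidates
  are nearly collinear and selection is declared ambiguous
  ($\Delta R^2 < 0.005$, a threshold slightly under the margin such
  studies report).
- **Free intercepts.** Apparent fits use a free intercept with a
  $|b| > 0.05$ warning rather than forcing the origin: robust to
  quench-delay offsets, and the intercept is a useful diagnostic.
- **Overflow.** `predict_conversion()` evaluates the algebraically
  equivalent form $(1-e^{-z})/(1-e^{-z}/M)$, stable for all $z \ge 0$, and
  clamps to the largest double below 1 to keep the $x \in [0,1)$ contract.
- **Intercept leverage.** $\lg k_0$ is the regression intercept at
  $M_c = 0$, roughly 13 units outside the observed $M_c$ range; noise in
  the per-temperature fits is therefore amplified into $\lg k_0$ and
  onwards into $E_a$ (slope over a 10 K span). With conversion noise of
  sd 0.01 the median $E_a$ recovery error is around 8-12 %. This leverage
  is a property of the decomposition method itself; reported uncertainties
  for such fits should be read accordingly.
- **Ties in optimization** are broken by shorter residence time, then
  lower temperature, then lower mass fraction — preferring the cheaper,
  safer operating point among equals.

## Problem sizes

The shipped tests and the acceptance script use the study-scale campaign
(3 temperatures x 6 mass fractions x 5-6 residence times, 18 series), 20
noise replicates for the noisy-recovery summary, 1000 random pairs for the
inversion oracle, and a 1001-point grid for the $M_c$ oracle; the full
suite runs in a few seconds.

## Known limitations

- The decomposition is treated formally: no physical bound is asserted on
  the fitted $\lg(c_{NO_2^+}/c_{HNO_3})$ term. Combining literature-style
  apparent rate tables with this $M_c$ convention can imply nominal
  nitronium ratios above 1; the published convention that would resolve
  the scaling is not available, so the package does not pretend to
  resolve it.
- $n(T)$ is interpolated linearly between fitted temperatures and mildly
  extrapolated beyond them (it is nearly constant in practice); wide
  temperature extrapolation is flagged but not prevented below the hard
  envelope limit.
- The reported per-temperature intrinsic constants of the motivating
  study are not exactly collinear in $1/T$ (their Arrhenius fit has
  $R^2 \approx 0.996$, residuals up to 0.04 log units); forward
  re-evaluation of a fitted Arrhenius line reproduces its own inputs only
  to that accuracy, which is an honest property of the data, not of the
  fit.
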