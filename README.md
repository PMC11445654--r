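# nitrokinetics

Kinetic modeling of homogeneous mixed-acid nitration in continuous flow.

Nitration of activated substrates (here an isourea pesticide intermediate)
with HNO3 in concentrated H2SO4 is fast, strongly exothermic, and —
because H2SO4 controls how much of the nitric acid is present as the
actual electrophile NO2+ — has an apparent rate constant that depends
sharply and non-monotonically on acid strength. This package implements
the full modeling workflow a flow-chemistry kineticist runs on such a
system:

1. **Reaction-order inference** by the classical integral method: candidate
   integrated rate forms are linearized against time and the orders with
   the highest R² win (`infer_orders()`).
2. **Apparent rate constants** from conversion–time series via the
   excess-reagent transform of the mixed second-order law,
   ln[(M−x)/(M(1−x))] = (M−1)·c₀·k·t (`fit_apparent_k()`).
3. **Intrinsic NO2+-based kinetics** by the decomposition
   lg k = lg(c_NO2+/c_HNO3) + n·Mc + lg k0, with Mc a Marziano-type
   activity-coefficient function of the sulfuric-acid medium
   (`fit_intrinsic()`, `mc_at_298()`, `fit_nitronium()`).
4. **Arrhenius parameters** from ln k0 = −Ea/(RT) + ln A
   (`fit_arrhenius()`).
5. **Forward prediction, response surfaces, validation, and grid-search
   optimization** of (temperature, acid strength, residence time), with
   calibration-envelope flags on every prediction (`predict_conversion()`,
   `response_surface()`, `optimize_conditions()`, `validate_predictions()`).
6. **A synthetic-data generator** (`ground_truth()`, `generate_campaign()`,
   `generate_nitronium_table()`) that produces every input the pipeline
   consumes from known parameters, so the whole chain is testable
   end-to-end by parameter recovery.

See the methods vignette (`vignettes/kinetic-modeling.Rmd`) for the model,
its assumptions, and the numerical choices.

## Worked example

Generate a noisy synthetic campaign (3 temperatures × 6 acid strengths ×
5 residence times, conversion noise sd 0.01), fit it end to end, and
optimize the operating point:

```r
library(nitrokinetics)

truth    <- ground_truth(noise_sd = 0.01)
campaign <- generate_campaign(truth, seed = 42)
nitro    <- fit_nitronium(read_nitronium_table(
  system.file("extdata", "nitronium_synthetic.csv", package = "nitrokinetics")))

rate <- apparent_rate_table(campaign$series)
head(rate, 3)
#>   temperature w_h2so4           k        r2    intercept
#> 1      303.15      88 0.002518533 0.9956246  0.001286596
#> 2      308.15      88 0.003472814 0.9964412 -0.012929733
#> 3      313.15      88 0.004319277 0.9973157  0.047849995

intr <- intrinsic_table(rate, nitro)
intr[, 1:4]
#>   temperature        n    lg_k0        r2
#> 1      303.15 1.078965 11.38753 0.9999292
#> 2      308.15 1.113046 11.84986 0.9999745
#> 3      313.15 1.152319 12.35297 0.9994563

arr <- fit_arrhenius(intr)
arr
#> <arrhenius_fit> Ea = 175.40 kJ/mol, lnA = 95.79 (R2 = 0.9989)

model <- nitration_model(intr, arr, nitro)
optimize_conditions(model)
#> <optimization_result> x = 0.911 at T = 313.15 K, w = 89.0%, t = 282.0 s [boundary: time,temperature]
```

Reading the output: each campaign cell yields an apparent `k` in
L/(mol·s) with its fit diagnostics; the per-temperature intrinsic fits
give the medium-independent `lg k0` (increasing with temperature) and the
nearly constant compound parameter `n`; the Arrhenius fit condenses these
into an activation energy near the generating 192.57 kJ/mol (the ~9 %
gap here is ordinary noise amplification through the decomposition's
intercept — see the vignette); and the optimizer reports the best grid
cell, flagging that this optimum sits on the time and temperature
boundaries of the calibrated envelope.

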