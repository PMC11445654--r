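## Synthetic-data generation: conversion-time series, full multi-condition
## campaigns, and nitronium-fraction tables from known ground truth, so the
## whole pipeline can be exercised and scored without any external data.

#' Ground truth for synthetic campaigns
#'
#' Defines the generating model of the synthetic-data module. Defaults
#' emulate the study conditions of the modeled nitration: Arrhenius
#' parameters Ea = 192.57 kJ/mol and lnA = 102.55, a compound parameter
#' n(T) affine in temperature (1.0764 at 303.15 K, slope 8.13e-3 per K),
#' the bundled Mc correlation, and a synthetic nitronium lg-ratio surface
#' that is affine in mass fraction and linear in 1/T,
#' `lg_ratio = (a0 + a1 w)/T + (b0 + b1 w)`. The default coefficients are a
#' package convention chosen so generated apparent rate constants show the
#' study's qualitative structure (mild temperature dependence, interior
#' mass-fraction maximum) and conversions over the default campaign grid
#' stay informative; they are not literature values.
#'
#' @param ea activation energy, J/mol.
#' @param ln_a natural log pre-exponential factor.
#' @param n_ref n at `t_ref`; `n_slope` its change per kelvin.
#' @param t_ref reference temperature for `n_ref`, kelvin.
#' @param n_slope per-kelvin slope of n(T).
#' @param nitronium_coefs named numeric `c(a0, a1, b0, b1)` of the lg-ratio
#'   surface.
#' @param noise_sd additive Gaussian noise sd on conversion.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(ea = 192570, ln_a = 102.55,
                         n_ref = 1.0764, t_ref = 303.15, n_slope = 8.13e-3,
                         nitronium_coefs = c(a0 = -610, a1 = 20,
                                             b0 = -23.86, b1 = 0.214),
                         noise_sd = 0.01) {
  stopifnot(noise_sd >= 0,
            all(c("a0", "a1", "b0", "b1") %in% names(nitronium_coefs)))
  structure(
    list(ea = ea, ln_a = ln_a, n_ref = n_ref, t_ref = t_ref,
         n_slope = n_slope, nitronium_coefs = nitronium_coefs,
         noise_sd = noise_sd),
    class = "ground_truth"
  )
}

#' True lg-ratio surface of a ground truth
#' @param truth a [ground_truth()].
#' @param w mass fraction, percent.
#' @param temperature kelvin.
#' @return lg(c_NO2+/c_HNO3) under the truth structure.
#' @export
truth_lg_ratio <- function(truth, w, temperature) {
  cf <- truth$nitronium_coefs
  (cf[["a0"]] + cf[["a1"]] * w) / temperature + cf[["b0"]] + cf[["b1"]] * w
}

#' True n(T) of a ground truth
#' @inheritParams truth_lg_ratio
#' @return the compound thermodynamic parameter n at `temperature`.
#' @export
truth_n <- function(truth, temperature) {
  truth$n_ref + truth$n_slope * (temperature - truth$t_ref)
}

#' True apparent rate constant of a ground truth
#'
#' Composes the decomposition forward:
#' `lg k = lg_ratio(w, T) + n(T) Mc(w, T) + lg k0(T)` with `lg k0` from the
#' truth's Arrhenius parameters and Mc from the bundled correlation.
#'
#' @inheritParams truth_lg_ratio
#' @return apparent rate constant, L/(mol s).
#' @export
truth_k <- function(truth, w, temperature) {
  mc <- mc_at_temperature(mc_at_298(mass_fraction_to_molarity(w)),
                          temperature)
  lg_k0 <- (truth$ln_a - truth$ea / (GAS_CONSTANT * temperature)) / log(10)
  10^(truth_lg_ratio(truth, w, temperature) +
        truth_n(truth, temperature) * mc + lg_k0)
}

#' Generate one conversion-time series
#'
#' Forward-evaluates the integrated excess-reagent law at `t_grid` and adds
#' truncated Gaussian noise: `x_i = clamp(x(t_i) + e_i, 0, 0.999)` with
#' `e_i ~ N(0, noise_sd^2)` from the seeded generator. All truth values are
#' embedded in the series metadata.
#'
#' @param k_true generating rate constant, L/(mol s).
#' @param m molar excess ratio.
#' @param c_io0 initial substrate concentration, mol/L.
#' @param t_grid strictly increasing times, seconds.
#' @param noise_sd Gaussian noise sd on conversion (>= 0).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @param temperature,w_h2so4 condition labels stored on the series.
#' @return a [conversion_series()].
#' @export
generate_series <- function(k_true, m, c_io0, t_grid, noise_sd = 0,
                            seed = NULL, temperature = 303.15,
                            w_h2so4 = 94) {
  if (any(diff(t_grid) <= 0)) {
    nk_stop("nk_value_error", "t_grid must be strictly increasing")
  }
  if (noise_sd < 0) nk_stop("nk_value_error", "noise_sd must be >= 0")
  x <- predict_conversion(k_true, m, c_io0, t_grid)
  if (noise_sd > 0) {
    if (is.null(seed)) nk_stop("nk_value_error", "seed required for noise")
    set.seed(seed)
    x <- x + stats::rnorm(length(t_grid), 0, noise_sd)
  }
  x <- pmin(pmax(x, 0), 0.999)
  conversion_series(
    t_grid, x, temperature, w_h2so4, c_io0, m * c_io0,
    metadata = list(k_true = k_true, noise_sd = noise_sd, seed = seed)
  )
}

#' Generate a multi-condition measurement campaign
#'
#' One conversion-time series per (temperature, mass fraction) design cell,
#' with the generating rate constant taken from the ground truth, plus the
#' noise-free truth rate table for recovery scoring. Defaults reproduce the
#' study design: 30/35/40 degC crossed with 88-98 wt % H2SO4 and residence
#' times of 1-4.7 min at M = 4.4 and c_IO0 = 0.5 mol/L.
#'
#' @param truth a [ground_truth()].
#' @param temperatures kelvin.
#' @param mass_fractions percent.
#' @param t_grid seconds.
#' @param m,c_io0 campaign-wide ratio and initial concentration.
#' @param noise_sd noise sd on conversion; default taken from `truth`.
#' @param seed integer seed; per-series seeds are derived from it.
#' @return list of class `campaign`: `series` (list of
#'   [conversion_series()]), `truth_table` (data.frame `temperature`,
#'   `w_h2so4`, `k_true`), `truth`.
#' @export
generate_campaign <- function(truth,
                              temperatures = celsius_to_kelvin(c(30, 35, 40)),
                              mass_fractions = c(88, 90, 92, 94, 96, 98),
                              t_grid = c(1, 2, 3, 4, 4.7) * 60,
                              m = 4.4, c_io0 = 0.5,
                              noise_sd = NULL, seed = 1) {
  if (length(temperatures) == 0 || length(mass_fractions) == 0) {
    nk_stop("nk_value_error", "empty campaign design")
  }
  if (is.null(noise_sd)) noise_sd <- truth$noise_sd
  design <- expand.grid(temperature = temperatures, w_h2so4 = mass_fractions,
                        KEEP.OUT.ATTRS = FALSE)
  k_true <- truth_k(truth, design$w_h2so4, design$temperature)
  series <- lapply(seq_len(nrow(design)), function(i) {
    generate_series(
      k_true[i], m, c_io0, t_grid, noise_sd,
      seed = if (noise_sd > 0) seed * 10000L + i else NULL,
      temperature = design$temperature[i], w_h2so4 = design$w_h2so4[i]
    )
  })
  structure(
    list(series = series,
         truth_table = data.frame(temperature = design$temperature,
                                  w_h2so4 = design$w_h2so4, k_true = k_true),
         truth = truth),
    class = "campaign"
  )
}

#' Generate a synthetic nitronium-fraction table
#'
#' Evaluates the truth's lg-ratio surface on a (w, T) grid and adds Gaussian
#' noise. The result is labeled synthetic in its metadata; it stands in for
#' literature nitronium-fraction measurements, which the package cannot
#' ship.
#'
#' @param truth a [ground_truth()].
#' @param w_points mass fractions, percent (>= 2 distinct).
#' @param t_points temperatures, kelvin (>= 2 distinct).
#' @param noise_sd Gaussian noise sd on lg-ratio.
#' @param seed integer seed (required when `noise_sd > 0`).
#' @return a [nitronium_table()] with attribute `synthetic = TRUE`.
#' @export
generate_nitronium_table <- function(truth,
                                     w_points = seq(88, 98, by = 2),
                                     t_points = celsius_to_kelvin(c(23, 40, 60)),
                                     noise_sd = 0, seed = NULL) {
  if (length(unique(w_points)) < 2 || length(unique(t_points)) < 2) {
    nk_stop("nk_value_error",
            "need >= 2 distinct mass fractions and temperatures")
  }
  grid <- expand.grid(w_h2so4 = w_points, temperature = t_points,
                      KEEP.OUT.ATTRS = FALSE)
  lgr <- truth_lg_ratio(truth, grid$w_h2so4, grid$temperature)
  if (noise_sd > 0) {
    if (is.null(seed)) nk_stop("nk_value_error", "seed required for noise")
    set.seed(seed)
    lgr <- lgr + stats::rnorm(nrow(grid), 0, noise_sd)
  }
  tab <- nitronium_table(data.frame(temperature = grid$temperature,
                                    w_h2so4 = grid$w_h2so4, lg_ratio = lgr))
  attr(tab, "synthetic") <- TRUE
  attr(tab, "seed") <- seed
  tab
}

#' Generate a series from explicit reaction orders
#'
#' Forward closed-form (or, for the mixed third-order case, numerically
#' inverted) trajectories for each candidate order pair, used to exercise
#' order inference. For pseudo-order experiments (`pseudo = TRUE`) the rate
#' coefficient is `K = k c_HNO3,0^beta` and the trajectory depends on
#' `alpha` only; for mixed experiments the full (alpha, beta) law is
#' integrated.
#'
#' @param alpha order in the substrate (1 or 2).
#' @param beta order in nitric acid (0 or 1).
#' @param k rate constant in the units implied by the orders.
#' @param m molar ratio `c_HNO3,0 / c_IO,0`.
#' @param c_io0 initial substrate concentration, mol/L.
#' @param t_grid strictly increasing times, seconds.
#' @param pseudo generate under pseudo-order excess (HNO3 effectively
#'   constant)?
#' @param noise_sd,seed optional additive conversion noise.
#' @param temperature,w_h2so4 condition labels.
#' @return a [conversion_series()].
#' @export
generate_order_series <- function(alpha, beta, k, m, c_io0, t_grid,
                                  pseudo = FALSE, noise_sd = 0, seed = NULL,
                                  temperature = 273.15, w_h2so4 = 98) {
  if (any(diff(t_grid) <= 0)) {
    nk_stop("nk_value_error", "t_grid must be strictly increasing")
  }
  c_hno3_0 <- m * c_io0
  x <- if (pseudo) {
    kb <- k * c_hno3_0^beta
    switch(as.character(alpha),
           "1" = -expm1(-kb * t_grid),
           "2" = 1 - 1 / (1 + c_io0 * kb * t_grid),
           nk_stop("nk_value_error", "alpha must be 1 or 2"))
  } else if (alpha == 1 && beta == 0) {
    -expm1(-k * t_grid)
  } else if (alpha == 2 && beta == 0) {
    1 - 1 / (1 + c_io0 * k * t_grid)
  } else if (alpha == 1 && beta == 1) {
    predict_conversion(k, m, c_io0, t_grid)
  } else if (alpha == 2 && beta == 1) {
    ## invert the partial-fraction integral g(x) = k c0^2 t numerically;
    ## g is strictly increasing so uniroot on [0, 1) is safe
    vapply(t_grid, function(tt) {
      rhs <- k * c_io0^2 * tt
      if (rhs == 0) return(0)
      stats::uniroot(function(xx) order_transform(xx, 2, 1, m) - rhs,
                     lower = 0, upper = 1 - 1e-12, tol = 1e-14)$root
    }, numeric(1))
  } else {
    nk_stop("nk_value_error", "unsupported orders (%g, %g)", alpha, beta)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) nk_stop("nk_value_error", "seed required for noise")
    set.seed(seed)
    x <- x + stats::rnorm(length(x), 0, noise_sd)
  }
  x <- pmin(pmax(x, 0), 0.999)
  conversion_series(t_grid, x, temperature, w_h2so4, c_io0, c_hno3_0,
                    metadata = list(alpha = alpha, beta = beta, k_true = k,
                                    pseudo = pseudo, noise_sd = noise_sd,
                                    seed = seed))
}

#' Run the full recovery pipeline on a campaign
#'
#' Convenience wrapper: fits every series of a campaign, decomposes the
#' apparent rate table with a nitronium model fitted from the truth's
#' (noise-free) synthetic table, and extracts Arrhenius parameters. Returns
#' everything needed to score recovery against the generating truth.
#'
#' @param campaign a [generate_campaign()] result.
#' @param nitronium optional pre-fitted nitronium model; default is fitted
#'   from the truth's noise-free synthetic table.
#' @return list: `rate_table`, `intrinsic`, `arrhenius`, `nitronium`.
#' @export
recover_campaign <- function(campaign, nitronium = NULL) {
  stopifnot(inherits(campaign, "campaign"))
  if (is.null(nitronium)) {
    nitronium <- fit_nitronium(generate_nitronium_table(campaign$truth))
  }
  rate_table <- apparent_rate_table(campaign$series)
  intrinsic <- intrinsic_table(rate_table, nitronium)
  arrhenius <- fit_arrhenius(intrinsic)
  list(rate_table = rate_table, intrinsic = intrinsic,
       arrhenius = arrhenius, nitronium = nitronium)
}
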