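## Decomposition of apparent rate constants into nitronium-based intrinsic
## kinetics and Arrhenius parameter extraction.
##
## The decomposition is lg k = lg(c_NO2+/c_HNO3) + n * Mc + lg k0 (all lg
## are base 10); per temperature, regressing lg k - lg_ratio on Mc gives n
## (slope) and lg k0 (intercept). Across temperatures ln k0 = -Ea/(R T) +
## ln A (natural log).

#' Fit intrinsic parameters (n, lg k0) at one temperature
#'
#' For each acid mass fraction in the apparent rate table at the given
#' temperature, computes `y = lg k - lg(c_NO2+/c_HNO3)` and `x = Mc(w, T)`
#' (mass fraction -> molarity -> Mc at 298 K -> temperature-corrected Mc),
#' then fits `y = n x + lg k0` by ordinary least squares.
#'
#' @param rate_table data.frame with columns `temperature` (kelvin),
#'   `w_h2so4` (percent), `k` (L/(mol s)); see [apparent_rate_table()].
#' @param nitronium a fitted [fit_nitronium()] model.
#' @param temperature the temperature (kelvin) whose rows are fitted.
#' @param density_table optional density table override.
#' @param strict if `TRUE`, rows whose nitronium evaluation is extrapolated
#'   are excluded from the fit (default: included, flag reported).
#' @return list of class `intrinsic_fit`: `temperature`, `n`, `lg_k0`, `r2`,
#'   `n_rows`, `any_extrapolated`.
#' @export
fit_intrinsic <- function(rate_table, nitronium, temperature,
                          density_table = NULL, strict = FALSE) {
  rows <- rate_table[abs(rate_table$temperature - temperature) < 1e-6, ,
                     drop = FALSE]
  lgr <- lg_ratio(nitronium, rows$w_h2so4, temperature)
  if (strict) {
    rows <- rows[!lgr$extrapolated, , drop = FALSE]
    lgr <- lgr[!lgr$extrapolated, , drop = FALSE]
  }
  if (nrow(rows) < 3) {
    nk_stop("nk_fit_error",
            "need >= 3 acid mass fractions at %g K (got %d)",
            temperature, nrow(rows))
  }
  if (any(rows$k <= 0)) nk_stop("nk_value_error", "rate constants must be > 0")
  mc <- mc_at_temperature(
    mc_at_298(mass_fraction_to_molarity(rows$w_h2so4, density_table)),
    temperature)
  y <- log10(rows$k) - lgr$lg_ratio
  fit <- stats::lm(y ~ mc)
  structure(
    list(temperature = temperature,
         n = unname(stats::coef(fit)[2]),
         lg_k0 = unname(stats::coef(fit)[1]),
         r2 = suppressWarnings(summary(fit))$r.squared,
         n_rows = nrow(rows),
         any_extrapolated = any(lgr$extrapolated)),
    class = "intrinsic_fit"
  )
}

#' Fit intrinsic parameters at every temperature of a rate table
#'
#' @inheritParams fit_intrinsic
#' @return data.frame with one row per temperature: `temperature`, `n`,
#'   `lg_k0`, `r2`, `n_rows`, `any_extrapolated`.
#' @export
intrinsic_table <- function(rate_table, nitronium, density_table = NULL,
                            strict = FALSE) {
  temps <- sort(unique(rate_table$temperature))
  rows <- lapply(temps, function(tt) {
    f <- fit_intrinsic(rate_table, nitronium, tt, density_table, strict)
    data.frame(temperature = f$temperature, n = f$n, lg_k0 = f$lg_k0,
               r2 = f$r2, n_rows = f$n_rows,
               any_extrapolated = f$any_extrapolated)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Arrhenius parameters from per-temperature intrinsic rate constants
#'
#' Converts `lg k0` (base 10) to `ln k0` and fits `ln k0 = -Ea/(R T) + ln A`
#' by ordinary least squares of `ln k0` on `1/T` across all supplied
#' temperatures. The activation energy is `-slope * R` and `ln A` is the
#' intercept.
#'
#' @param rows data.frame with columns `temperature` (kelvin) and `lg_k0`
#'   (base-10 log of the intrinsic rate constant), one row per temperature
#'   (>= 2 distinct temperatures).
#' @param r_gas molar gas constant, J/(mol K); default 8.314.
#' @return list of class `arrhenius_fit`: `ea` (J/mol), `ln_a`, `r2`,
#'   `residuals_lg` (per-input residual of lg k0 about the fitted line),
#'   `r_gas`.
#' @export
fit_arrhenius <- function(rows, r_gas = GAS_CONSTANT) {
  stopifnot(is.data.frame(rows),
            all(c("temperature", "lg_k0") %in% names(rows)))
  if (length(unique(rows$temperature)) < 2) {
    nk_stop("nk_fit_error",
            "Arrhenius extraction needs >= 2 distinct temperatures")
  }
  inv_t <- 1 / rows$temperature
  ln_k0 <- rows$lg_k0 * log(10)
  fit <- stats::lm(ln_k0 ~ inv_t)
  ea <- -unname(stats::coef(fit)[2]) * r_gas
  ln_a <- unname(stats::coef(fit)[1])
  pred_lg <- (ln_a - ea / (r_gas * rows$temperature)) / log(10)
  structure(
    list(ea = ea, ln_a = ln_a,
         r2 = if (nrow(rows) > 2) suppressWarnings(summary(fit))$r.squared else 1,
         residuals_lg = rows$lg_k0 - pred_lg,
         r_gas = r_gas),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.2f kJ/mol, lnA = %.2f (R2 = %.4f)\n",
              x$ea / 1000, x$ln_a, x$r2))
  invisible(x)
}

#' Intrinsic rate constant at a temperature
#'
#' Forward Arrhenius evaluation: `k0 = exp(ln A - Ea / (R T))`.
#'
#' @param ea activation energy, J/mol.
#' @param ln_a natural log of the pre-exponential factor.
#' @param temperature kelvin (positive).
#' @param r_gas molar gas constant, J/(mol K).
#' @return k0 in the unit convention of the fitted table (L/(mol s)).
#' @export
k0_at_temperature <- function(ea, ln_a, temperature, r_gas = GAS_CONSTANT) {
  if (any(temperature <= 0)) {
    nk_stop("nk_value_error", "temperature must be positive (kelvin)")
  }
  exp(ln_a - ea / (r_gas * temperature))
}
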