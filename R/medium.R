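## Sulfuric-acid medium properties: mass fraction <-> molarity and the
## Marziano-type activity-coefficient function Mc.

#' Bundled sulfuric-acid density table
#'
#' Returns the handbook-style density table (g/mL vs wt % H2SO4, 80-100 %,
#' 1-point steps) shipped with the package, used to bridge acid mass fraction
#' to molarity. Supply your own table of the same shape to any function that
#' takes a `density_table` argument to override it.
#'
#' @return data.frame with columns `mass_fraction_percent`, `density_g_per_ml`.
#' @export
h2so4_density_table <- function() {
  path <- system.file("extdata", "h2so4_density_298K.csv",
                      package = "nitrokinetics", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}

check_density_table <- function(density_table) {
  if (is.null(density_table)) density_table <- h2so4_density_table()
  stopifnot(
    is.data.frame(density_table),
    all(c("mass_fraction_percent", "density_g_per_ml") %in% names(density_table))
  )
  density_table[order(density_table$mass_fraction_percent), ]
}

#' Convert H2SO4 mass fraction to molarity
#'
#' Molarity is `density(w) * 1000 * (w/100) / 98.08` with the density
#' linearly interpolated from a bundled room-temperature table covering
#' 80-100 wt %. The temperature dependence of density is deliberately
#' ignored; the temperature correction of the medium enters only through
#' [mc_at_temperature()].
#'
#' @param w_h2so4 mass fraction of H2SO4 in percent.
#' @param density_table optional replacement density table
#'   (see [h2so4_density_table()]).
#' @return molarity in mol/L.
#' @seealso [molarity_to_mass_fraction()]
#' @export
mass_fraction_to_molarity <- function(w_h2so4, density_table = NULL) {
  tab <- check_density_table(density_table)
  lo <- min(tab$mass_fraction_percent); hi <- max(tab$mass_fraction_percent)
  if (any(!is.finite(w_h2so4)) || any(w_h2so4 < lo) || any(w_h2so4 > hi)) {
    nk_stop("nk_range_error",
            "mass fraction must lie in the density-table range [%g, %g] wt %%",
            lo, hi)
  }
  dens <- stats::approx(tab$mass_fraction_percent, tab$density_g_per_ml,
                        xout = w_h2so4)$y
  dens * 1000 * (w_h2so4 / 100) / MW_H2SO4
}

#' Convert H2SO4 molarity back to mass fraction
#'
#' Inverse of [mass_fraction_to_molarity()] by inverse interpolation of the
#' (strictly increasing) molarity implied by the bundled density table.
#'
#' @param c_h2so4 molarity in mol/L.
#' @inheritParams mass_fraction_to_molarity
#' @return mass fraction in percent.
#' @export
molarity_to_mass_fraction <- function(c_h2so4, density_table = NULL) {
  tab <- check_density_table(density_table)
  ## molarity at the table nodes; piecewise-linear in density hence smooth and
  ## monotone in w over the supported range, so invert on a fine grid
  wg <- seq(min(tab$mass_fraction_percent), max(tab$mass_fraction_percent),
            by = 0.01)
  cg <- mass_fraction_to_molarity(wg, tab)
  if (any(c_h2so4 < min(cg)) || any(c_h2so4 > max(cg))) {
    nk_stop("nk_range_error",
            "molarity must lie in [%0.3f, %0.3f] mol/L (density-table range)",
            min(cg), max(cg))
  }
  stats::approx(cg, wg, xout = c_h2so4)$y
}

#' Activity-coefficient function Mc at 298 K
#'
#' Evaluates the empirical fifth-degree polynomial correlation for the
#' activity-coefficient function of concentrated sulfuric acid at 298 K.
#' The correlation defines the negative of Mc,
#' `-Mc = 2.16e-4 c^5 - 1.27e-2 c^4 + 0.28 c^3 - 2.73 c^2 + 10.6 c`
#' (c in mol/L); this function returns Mc itself, which is negative over the
#' calibrated range. The correlation was calibrated for c between 15.2 and
#' 18.4 mol/L; outside that range the value is an extrapolation and a warning
#' is issued (or an error if `enforce_range = TRUE`).
#'
#' @param c_h2so4 H2SO4 molarity in mol/L (positive).
#' @param enforce_range if `TRUE`, out-of-range molarities are an error
#'   instead of a warning.
#' @return Mc (dimensionless, typically negative).
#' @export
mc_at_298 <- function(c_h2so4, enforce_range = FALSE) {
  if (any(!is.finite(c_h2so4)) || any(c_h2so4 < 0)) {
    nk_stop("nk_value_error", "H2SO4 molarity must be finite and non-negative")
  }
  out_of_range <- c_h2so4 < 15.2 | c_h2so4 > 18.4
  if (any(out_of_range)) {
    if (enforce_range) {
      nk_stop("nk_range_error",
              "Mc correlation calibrated for c in [15.2, 18.4] mol/L; got %g",
              c_h2so4[out_of_range][1])
    }
    warning("Mc correlation evaluated outside its calibrated range ",
            "[15.2, 18.4] mol/L", call. = FALSE)
  }
  c <- c_h2so4
  ## Horner form of the quintic correlation (coefficients of -Mc)
  neg_mc <- c * (10.6 + c * (-2.73 + c * (0.28 + c * (-1.27e-2 + c * 2.16e-4))))
  -neg_mc
}

#' Temperature correction of Mc
#'
#' Scales an Mc value at 298 K to another temperature:
#' `Mc(T) = Mc(298 K) * (200/T + 0.3292)`. The bracket equals 1 at 298.15 K
#' to within 1e-5, so the correction is a pure reshaping around room
#' temperature.
#'
#' @param mc_298 Mc evaluated at 298 K (see [mc_at_298()]).
#' @param temperature temperature in kelvin (positive).
#' @return Mc at `temperature`.
#' @export
mc_at_temperature <- function(mc_298, temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    nk_stop("nk_value_error", "temperature must be positive (kelvin)")
  }
  mc_298 * (200 / temperature + 0.3292)
}

#' Sulfuric-acid medium state
#'
#' Bundles mass fraction, molarity, temperature and the Mc value of a
#' sulfuric-acid medium into an `acid_medium` object.
#'
#' @param w_h2so4 mass fraction of H2SO4 in percent.
#' @param temperature temperature in kelvin.
#' @inheritParams mass_fraction_to_molarity
#' @param enforce_range passed to [mc_at_298()].
#' @return an object of class `acid_medium`: list with `w_h2so4`, `c_h2so4`,
#'   `temperature`, `mc`.
#' @examples
#' m <- acid_medium(94, celsius_to_kelvin(30))
#' m$c_h2so4   # ~17.55 mol/L
#' m$mc        # negative
#' @export
acid_medium <- function(w_h2so4, temperature, density_table = NULL,
                        enforce_range = FALSE) {
  if (temperature <= 0) nk_stop("nk_value_error", "temperature must be > 0 K")
  c_h2so4 <- mass_fraction_to_molarity(w_h2so4, density_table)
  mc <- mc_at_temperature(mc_at_298(c_h2so4, enforce_range), temperature)
  structure(
    list(w_h2so4 = w_h2so4, c_h2so4 = c_h2so4,
         temperature = temperature, mc = mc),
    class = "acid_medium"
  )
}

#' @export
print.acid_medium <- function(x, ...) {
  cat(sprintf(
    "<acid_medium> %.1f wt %% H2SO4 (%.3f mol/L), T = %.2f K, Mc = %.4f\n",
    x$w_h2so4, x$c_h2so4, x$temperature, x$mc))
  invisible(x)
}
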