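## Conversion/residence-time preprocessing, integral-method reaction-order
## inference, and apparent rate-constant estimation from conversion-time
## series. Times are seconds internally; conversions are dimensionless in
## [0, 1).

#' Conversion-time series under one condition set
#'
#' The atomic unit of kinetic fitting: conversions of the limiting reagent
#' (IO) at strictly increasing reaction/residence times, under a fixed
#' (temperature, acid strength, initial concentrations) condition.
#'
#' @param times reaction or residence times in seconds, strictly increasing,
#'   non-negative.
#' @param conversions conversions in `[0, 1)`.
#' @param temperature kelvin.
#' @param w_h2so4 H2SO4 mass fraction in percent.
#' @param c_io0 initial IO concentration, mol/L.
#' @param c_hno3_0 initial HNO3 concentration, mol/L.
#' @param metadata optional named list carried along (e.g. generator truth).
#' @return object of class `conversion_series`.
#' @export
conversion_series <- function(times, conversions, temperature, w_h2so4,
                              c_io0, c_hno3_0, metadata = list()) {
  if (length(times) != length(conversions)) {
    nk_stop("nk_schema_error", "times and conversions differ in length")
  }
  if (any(diff(times) <= 0) || any(times < 0)) {
    nk_stop("nk_schema_error",
            "times must be non-negative and strictly increasing")
  }
  if (any(conversions < 0) || any(conversions >= 1)) {
    bad <- which(conversions < 0 | conversions >= 1)[1]
    nk_stop("nk_schema_error",
            "conversion out of [0, 1) at row %d (x = %g)",
            bad, conversions[bad])
  }
  if (c_io0 <= 0 || c_hno3_0 <= 0) {
    nk_stop("nk_value_error", "initial concentrations must be positive")
  }
  structure(
    list(times = as.numeric(times), conversions = as.numeric(conversions),
         temperature = temperature, w_h2so4 = w_h2so4,
         c_io0 = c_io0, c_hno3_0 = c_hno3_0,
         m_ratio = c_hno3_0 / c_io0, metadata = metadata),
    class = "conversion_series"
  )
}

#' @export
print.conversion_series <- function(x, ...) {
  cat(sprintf(
    "<conversion_series> %d points, T = %.2f K, %.0f%% H2SO4, M = %.2f\n",
    length(x$times), x$temperature, x$w_h2so4, x$m_ratio))
  invisible(x)
}

#' Conversion from chromatographic signals
#'
#' Conversion of the substrate from concentration-proportional HPLC signals
#' of residual substrate (`c_io`) and nitrated product (`c_nio`):
#' `x = 1 - c_io / (c_io + c_nio)`.
#'
#' @param c_io substrate signal (>= 0).
#' @param c_nio product signal (>= 0).
#' @return conversion in `[0, 1]`.
#' @export
conversion_from_hplc <- function(c_io, c_nio) {
  if (any(c_io < 0) || any(c_nio < 0)) {
    nk_stop("nk_value_error", "signals must be non-negative")
  }
  tot <- c_io + c_nio
  if (any(tot == 0)) {
    nk_stop("nk_value_error", "no analyte detected (both signals zero)")
  }
  1 - c_io / tot
}

#' Residence time of a flow reactor
#'
#' `t = V / (Q_IO + Q_HNO3)`, with the reactor volume in mL and flow rates
#' in mL/min; returned in seconds.
#'
#' @param volume_ml reactor (microchannel) volume, mL.
#' @param q_io_ml_min,q_hno3_ml_min volumetric flow rates of the two feeds,
#'   mL/min.
#' @return residence time in seconds.
#' @export
residence_time <- function(volume_ml, q_io_ml_min, q_hno3_ml_min) {
  if (volume_ml <= 0) nk_stop("nk_value_error", "volume must be positive")
  q <- q_io_ml_min + q_hno3_ml_min
  if (q <= 0) nk_stop("nk_value_error", "total flow rate must be positive")
  volume_ml / q * 60
}

#' Excess-reagent second-order transform
#'
#' The linearizing transform of the mixed second-order integrated rate law
#' with excess nitric acid: `ln[(M - x) / (M (1 - x))]`, where
#' `M = c_HNO3,0 / c_IO,0 > 1`. It is 0 at `x = 0`, strictly increasing in
#' `x`, and equals `(M - 1) c_IO0 k t` along an exact second-order
#' trajectory.
#'
#' @param x conversion in `[0, 1)`, with `x < M`.
#' @param m molar excess ratio `M > 1`.
#' @return the transform value (dimensionless).
#' @seealso [predict_conversion()] for the exact inverse.
#' @export
transform_excess <- function(x, m) {
  if (any(m <= 1)) nk_stop("nk_domain_error", "M must exceed 1")
  if (any(x < 0) || any(x >= 1) || any(x >= m)) {
    nk_stop("nk_domain_error", "conversion must satisfy 0 <= x < 1 and x < M")
  }
  log((m - x) / (m * (1 - x)))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares about the mean
#' of the observations.
#'
#' @param observed,fitted numeric vectors of equal length (>= 2).
#' @return R-squared.
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2) {
    nk_stop("nk_value_error", "need equal-length vectors of length >= 2")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    nk_stop("nk_value_error", "R^2 undefined for a constant observed vector")
  }
  1 - sum((observed - fitted)^2) / ss_tot
}

## Integrated-law linearizing transforms for the candidate orders
## (alpha in IO, beta in HNO3). Each returns a vector linear in t when the
## generating orders match; the slope interpretation is documented where the
## candidates are fitted. The (2,1) transform is the partial-fraction
## integral of dx / ((1-x)^2 (M-x)).
order_transform <- function(x, alpha, beta, m = NULL) {
  if (alpha == 1 && beta == 0) return(-log(1 - x))
  if (alpha == 2 && beta == 0) return(1 / (1 - x) - 1)
  if (is.null(m)) nk_stop("nk_value_error", "M required for beta = 1")
  if (alpha == 1 && beta == 1) return(transform_excess(x, m))
  if (alpha == 2 && beta == 1) {
    return((1 / (m - 1)) * (1 / (1 - x) - 1) -
             (1 / (m - 1)^2) * transform_excess(x, m))
  }
  nk_stop("nk_value_error", "unsupported candidate orders (%g, %g)",
          alpha, beta)
}

fit_linear_through_t <- function(y, t) {
  fit <- stats::lm(y ~ t)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = suppressWarnings(summary(fit))$r.squared)
}

#' Infer reaction orders by the integral method
#'
#' The order in the substrate (`alpha`, candidates 1 and 2) is read from a
#' pseudo-order experiment with a large nitric-acid excess, by comparing the
#' linearity (R-squared) of the first-order transform `-ln(1 - x)` against
#' the second-order transform `1/(1 - x) - 1` versus time. The order in
#' nitric acid (`beta`, candidates 0 and 1) is then read from a mixed-ratio
#' experiment by comparing, conditionally on the inferred `alpha`, the
#' constant-rate-coefficient integrated form against the mixed second-order
#' form. The candidate pair with the highest R-squared wins; a winning
#' margin below `delta_r2` sets the `ambiguous` flag.
#'
#' @param pseudo_series a [conversion_series()] with
#'   `c_hno3_0 / c_io0 >= min_excess`.
#' @param mixed_series a [conversion_series()] at a moderate molar ratio.
#' @param delta_r2 ambiguity threshold on the winning R-squared margin.
#' @param min_excess minimum pseudo-order excess ratio (default 10).
#' @return list of class `reaction_orders`: `alpha`, `beta`,
#'   `r2_by_candidate` (named numeric), `ambiguous`.
#' @export
infer_orders <- function(pseudo_series, mixed_series, delta_r2 = 0.005,
                         min_excess = 10) {
  stopifnot(inherits(pseudo_series, "conversion_series"),
            inherits(mixed_series, "conversion_series"))
  if (length(pseudo_series$times) < 4 || length(mixed_series$times) < 4) {
    nk_stop("nk_fit_error", "order inference needs series of >= 4 points")
  }
  if (pseudo_series$m_ratio < min_excess) {
    nk_stop("nk_precondition_error",
            "pseudo-order series needs c_HNO3,0/c_IO,0 >= %g (got %.2f)",
            min_excess, pseudo_series$m_ratio)
  }
  tp <- pseudo_series$times; xp <- pseudo_series$conversions
  a1 <- fit_linear_through_t(order_transform(xp, 1, 0), tp)
  a2 <- fit_linear_through_t(order_transform(xp, 2, 0), tp)
  alpha <- if (a1$r2 >= a2$r2) 1 else 2
  ambiguous_a <- abs(a1$r2 - a2$r2) < delta_r2

  tm <- mixed_series$times; xm <- mixed_series$conversions
  m <- mixed_series$m_ratio
  b0 <- fit_linear_through_t(order_transform(xm, alpha, 0), tm)
  b1 <- fit_linear_through_t(order_transform(xm, alpha, 1, m), tm)
  beta <- if (b1$r2 > b0$r2) 1 else 0
  ambiguous_b <- abs(b1$r2 - b0$r2) < delta_r2

  r2 <- c(a1$r2, a2$r2, b0$r2, b1$r2)
  names(r2) <- c("alpha1", "alpha2",
                 sprintf("alpha%d_beta0", alpha), sprintf("alpha%d_beta1", alpha))
  structure(
    list(alpha = alpha, beta = beta, r2_by_candidate = r2,
         ambiguous = ambiguous_a || ambiguous_b),
    class = "reaction_orders"
  )
}

#' @export
print.reaction_orders <- function(x, ...) {
  cat(sprintf("<reaction_orders> alpha = %d, beta = %d%s\n", x$alpha, x$beta,
              if (x$ambiguous) " (ambiguous)" else ""))
  print(round(x$r2_by_candidate, 4))
  invisible(x)
}

#' Fit the apparent second-order rate constant
#'
#' Ordinary least squares of the excess-reagent transform
#' `ln[(M - x)/(M (1 - x))]` on time, with a free intercept. The slope of
#' the exact law is `(M - 1) c_IO0 k`, so `k = slope / ((M - 1) c_IO0)`.
#' The intercept is a diagnostic: along an ideal trajectory it is 0, and
#' `|intercept| > 0.05` triggers a warning (e.g. quench-delay offsets).
#'
#' @param series a [conversion_series()] with `M > 1` and at least 3 points.
#' @return list of class `apparent_fit`: `k` (L/(mol s)), `r2`, `intercept`,
#'   `slope`, plus the series condition columns.
#' @export
fit_apparent_k <- function(series) {
  stopifnot(inherits(series, "conversion_series"))
  if (length(series$times) < 3) {
    nk_stop("nk_fit_error", "need >= 3 points to fit the rate constant")
  }
  if (series$m_ratio <= 1) {
    nk_stop("nk_domain_error", "excess-reagent fit requires M > 1")
  }
  y <- transform_excess(series$conversions, series$m_ratio)
  fit <- fit_linear_through_t(y, series$times)
  if (fit$slope <= 0) {
    nk_stop("nk_fit_error",
            "non-positive slope (%.3g): no measurable reaction rate",
            fit$slope)
  }
  if (abs(fit$intercept) > 0.05) {
    warning(sprintf("apparent-fit intercept %.3f exceeds 0.05 in magnitude",
                    fit$intercept), call. = FALSE)
  }
  structure(
    list(k = fit$slope / ((series$m_ratio - 1) * series$c_io0),
         r2 = fit$r2, intercept = fit$intercept, slope = fit$slope,
         temperature = series$temperature, w_h2so4 = series$w_h2so4,
         c_io0 = series$c_io0, m_ratio = series$m_ratio),
    class = "apparent_fit"
  )
}

#' Assemble an apparent rate-constant table
#'
#' Applies [fit_apparent_k()] to a list of series and stacks the results
#' into the apparent rate table consumed by the intrinsic decomposition.
#'
#' @param series_list list of [conversion_series()] objects.
#' @return data.frame with columns `temperature`, `w_h2so4`, `k`, `r2`,
#'   `intercept`.
#' @export
apparent_rate_table <- function(series_list) {
  rows <- lapply(series_list, function(s) {
    f <- fit_apparent_k(s)
    data.frame(temperature = f$temperature, w_h2so4 = f$w_h2so4,
               k = f$k, r2 = f$r2, intercept = f$intercept)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
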