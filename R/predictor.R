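## Forward conversion prediction, response surfaces, validation against
## experiments, and grid-search optimization of reaction conditions, with a
## calibration envelope that flags or rejects extrapolated predictions.

#' Calibration envelope for predictions
#'
#' Defines the region of operating conditions inside which the kinetic model
#' was calibrated (`soft`) and the outer region beyond which predictions are
#' refused (`hard`). Predictions between the two are evaluated and flagged
#' as extrapolated. Defaults mirror the model-construction campaign:
#' 30-40 degC, 88-98 wt % H2SO4, residence times up to 4.7 min (soft), with
#' hard limits at 45 degC and 15 min.
#'
#' @param t_soft,t_hard temperature ranges in kelvin, `c(min, max)`.
#' @param w_soft,w_hard mass-fraction ranges in percent.
#' @param time_soft,time_hard residence-time ranges in seconds.
#' @return object of class `calibration_envelope`.
#' @export
calibration_envelope <- function(t_soft = c(303.15, 313.15),
                                 t_hard = c(273.15, 318.15),
                                 w_soft = c(88, 98),
                                 w_hard = c(80, 100),
                                 time_soft = c(0, 282),
                                 time_hard = c(0, 900)) {
  chk <- function(soft, hard, what) {
    if (soft[1] < hard[1] || soft[2] > hard[2]) {
      nk_stop("nk_value_error", "soft %s range must lie inside hard range",
              what)
    }
  }
  chk(t_soft, t_hard, "temperature")
  chk(w_soft, w_hard, "mass-fraction")
  chk(time_soft, time_hard, "residence-time")
  structure(
    list(t_soft = t_soft, t_hard = t_hard, w_soft = w_soft, w_hard = w_hard,
         time_soft = time_soft, time_hard = time_hard),
    class = "calibration_envelope"
  )
}

## Three-state classification: "interior", "extrapolated", "rejected".
classify_conditions <- function(envelope, temperature, w, time_s) {
  inside <- function(v, rng) v >= rng[1] & v <= rng[2]
  hard_ok <- inside(temperature, envelope$t_hard) &
    inside(w, envelope$w_hard) & inside(time_s, envelope$time_hard)
  soft_ok <- inside(temperature, envelope$t_soft) &
    inside(w, envelope$w_soft) & inside(time_s, envelope$time_soft)
  ifelse(!hard_ok, "rejected", ifelse(soft_ok, "interior", "extrapolated"))
}

#' Predict conversion from the integrated rate law
#'
#' Exact inverse of [transform_excess()]: with `z = (M - 1) c_IO0 k t`,
#' `x = M (e^z - 1) / (M e^z - 1)`, evaluated in the overflow-safe form
#' `x = (1 - e^-z) / (1 - e^-z / M)` so arbitrarily large `z` saturates
#' cleanly at 1.
#'
#' @param k apparent rate constant, L/(mol s) (>= 0).
#' @param m molar excess ratio `M > 1`.
#' @param c_io0 initial substrate concentration, mol/L (> 0).
#' @param t residence time, seconds (>= 0).
#' @return predicted conversion in `[0, 1)`.
#' @export
predict_conversion <- function(k, m, c_io0, t) {
  if (any(m <= 1)) nk_stop("nk_domain_error", "M must exceed 1")
  if (any(k < 0) || any(c_io0 <= 0) || any(t < 0)) {
    nk_stop("nk_value_error", "k, t must be >= 0 and c_io0 > 0")
  }
  z <- (m - 1) * c_io0 * k * t
  x <- -expm1(-z) / (1 - exp(-z) / m)
  ## mathematically x < 1 for finite z, but the quotient can round to 1;
  ## keep the [0, 1) contract so the transform stays invertible
  pmin(x, 1 - .Machine$double.eps / 2)
}

## piecewise-linear evaluation of n(T) through per-temperature fits, with
## linear extrapolation from the outer segments
interp_n <- function(intrinsic, temperature) {
  it <- intrinsic[order(intrinsic$temperature), ]
  tt <- it$temperature; nn <- it$n
  if (length(tt) == 1) return(rep(nn, length(temperature)))
  vapply(temperature, function(T1) {
    if (T1 <= tt[1]) {
      nn[1] + (T1 - tt[1]) * (nn[2] - nn[1]) / (tt[2] - tt[1])
    } else if (T1 >= tt[length(tt)]) {
      m <- length(tt)
      nn[m] + (T1 - tt[m]) * (nn[m] - nn[m - 1]) / (tt[m] - tt[m - 1])
    } else {
      stats::approx(tt, nn, xout = T1)$y
    }
  }, numeric(1))
}

#' Predict the apparent rate constant from the fitted decomposition
#'
#' Recomposes `lg k = lg(c_NO2+/c_HNO3) + n(T) Mc(w, T) + lg k0(T)`:
#' the nitronium term from the fitted two-stage model, `n(T)` linearly
#' interpolated (and mildly extrapolated) through the per-temperature
#' intrinsic fits, and `lg k0(T)` from the Arrhenius parameters.
#'
#' @param w H2SO4 mass fraction, percent.
#' @param temperature kelvin.
#' @param intrinsic data.frame of per-temperature intrinsic fits
#'   (see [intrinsic_table()]), columns `temperature`, `n`.
#' @param arrhenius an [fit_arrhenius()] result (or list with `ea`, `ln_a`).
#' @param nitronium a fitted [fit_nitronium()] model.
#' @param density_table optional density-table override.
#' @param envelope optional [calibration_envelope()]; rejected conditions
#'   raise an error (time is not checked here - no time is involved).
#' @return data.frame with columns `w_h2so4`, `temperature`, `lg_k`, `k`,
#'   `extrapolated`.
#' @export
predict_k <- function(w, temperature, intrinsic, arrhenius, nitronium,
                      density_table = NULL, envelope = NULL) {
  n <- max(length(w), length(temperature))
  w <- rep_len(w, n); temperature <- rep_len(temperature, n)
  if (!is.null(envelope)) {
    state <- classify_conditions(envelope, temperature, w,
                                 mean(envelope$time_soft))
    if (any(state == "rejected")) {
      nk_stop("nk_envelope_error",
              "conditions outside the hard calibration envelope")
    }
  }
  lgr <- lg_ratio(nitronium, w, temperature)
  mc <- mc_at_temperature(
    suppressWarnings(mc_at_298(mass_fraction_to_molarity(w, density_table))),
    temperature)
  n_t <- interp_n(intrinsic, temperature)
  lg_k0 <- (arrhenius$ln_a -
              arrhenius$ea / (GAS_CONSTANT * temperature)) / log(10)
  lg_k <- lgr$lg_ratio + n_t * mc + lg_k0
  t_rng <- range(intrinsic$temperature)
  data.frame(
    w_h2so4 = w, temperature = temperature, lg_k = lg_k, k = 10^lg_k,
    extrapolated = lgr$extrapolated |
      temperature < t_rng[1] | temperature > t_rng[2]
  )
}

#' Fitted nitration model bundle
#'
#' Convenience container tying together the pieces [predict_k()] needs, so
#' downstream prediction and optimization take one object.
#'
#' @param intrinsic per-temperature intrinsic fits ([intrinsic_table()]).
#' @param arrhenius an [fit_arrhenius()] result.
#' @param nitronium a fitted [fit_nitronium()] model.
#' @param m_ratio default molar excess ratio for predictions.
#' @param c_io0 default initial substrate concentration, mol/L.
#' @param envelope a [calibration_envelope()].
#' @param density_table optional density-table override.
#' @return object of class `nitration_model`.
#' @export
nitration_model <- function(intrinsic, arrhenius, nitronium,
                            m_ratio = 4.4, c_io0 = 0.5,
                            envelope = calibration_envelope(),
                            density_table = NULL) {
  structure(
    list(intrinsic = intrinsic, arrhenius = arrhenius, nitronium = nitronium,
         m_ratio = m_ratio, c_io0 = c_io0, envelope = envelope,
         density_table = density_table),
    class = "nitration_model"
  )
}

## single-point conversion prediction through the full model
predict_point <- function(model, w, temperature, time_s,
                          m_ratio = NULL, c_io0 = NULL, strict = FALSE) {
  m_ratio <- if (is.null(m_ratio)) model$m_ratio else m_ratio
  c_io0 <- if (is.null(c_io0)) model$c_io0 else c_io0
  state <- classify_conditions(model$envelope, temperature, w, time_s)
  if (any(state == "rejected")) {
    nk_stop("nk_envelope_error",
            "conditions outside the hard calibration envelope")
  }
  if (strict && any(state == "extrapolated")) {
    nk_stop("nk_envelope_error",
            "extrapolated conditions refused in strict mode")
  }
  kk <- predict_k(w, temperature, model$intrinsic, model$arrhenius,
                  model$nitronium, model$density_table)
  x <- predict_conversion(kk$k, m_ratio, c_io0, time_s)
  data.frame(w_h2so4 = kk$w_h2so4, temperature = kk$temperature,
             time_s = time_s, k = kk$k, conversion = x,
             flag = ifelse(kk$extrapolated & state == "interior",
                           "extrapolated", state))
}

#' Response surface of predicted conversion
#'
#' Dense evaluation of the fitted model over a grid of residence times
#' crossed with either temperatures (fixed `w`) or mass fractions (fixed
#' temperature), the two surface types used for validation and
#' optimization.
#'
#' @param model a [nitration_model()].
#' @param time_s vector of residence times, seconds.
#' @param temperature vector of temperatures (kelvin), or a scalar when
#'   `w` is the swept axis.
#' @param w vector of mass fractions (percent), or a scalar.
#' @param m_ratio,c_io0 optional overrides of the model defaults.
#' @param strict refuse (error) rather than flag soft extrapolation.
#' @return data.frame with one row per grid cell: `w_h2so4`, `temperature`,
#'   `time_s`, `k`, `conversion`, `flag`.
#' @export
response_surface <- function(model, time_s, temperature, w,
                             m_ratio = NULL, c_io0 = NULL, strict = FALSE) {
  grid <- expand.grid(time_s = time_s, temperature = temperature,
                      w_h2so4 = w, KEEP.OUT.ATTRS = FALSE)
  state <- classify_conditions(model$envelope, grid$temperature,
                               grid$w_h2so4, grid$time_s)
  if (any(state == "rejected")) {
    bad <- utils::head(which(state == "rejected"), 5)
    nk_stop("nk_envelope_error",
            "grid cells outside the hard envelope (first offenders: %s)",
            paste(sprintf("(T=%.2f, w=%.1f, t=%.0f)", grid$temperature[bad],
                          grid$w_h2so4[bad], grid$time_s[bad]),
                  collapse = ", "))
  }
  out <- predict_point(model, grid$w_h2so4, grid$temperature, grid$time_s,
                       m_ratio, c_io0, strict = strict)
  rownames(out) <- NULL
  out
}

#' Compare predicted and observed conversions
#'
#' Positional pairing of predictions with experimental observations;
#' discrepancies are reported in absolute percentage points of conversion.
#'
#' @param predicted,observed conversion vectors of equal length in `[0, 1]`.
#' @return list of class `validation_report`: `per_point` (data.frame with
#'   `predicted`, `observed`, `abs_error_pct`), `mean_abs_error_pct`,
#'   `max_abs_error_pct`, `worst_index`.
#' @export
validate_predictions <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1) {
    nk_stop("nk_value_error",
            "predicted and observed must have equal length >= 1")
  }
  err <- abs(predicted - observed) * 100
  structure(
    list(per_point = data.frame(predicted = predicted, observed = observed,
                                abs_error_pct = err),
         mean_abs_error_pct = mean(err),
         max_abs_error_pct = max(err),
         worst_index = which.max(err)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d points, mean |error| = %.2f pp, max = %.2f pp (point %d)\n",
    nrow(x$per_point), x$mean_abs_error_pct, x$max_abs_error_pct,
    x$worst_index))
  invisible(x)
}

#' Grid-search optimization of reaction conditions
#'
#' Exhaustive search over a (temperature, mass fraction, residence time)
#' grid inside the envelope. The objective is either maximal predicted
#' conversion or the shortest-time attainment of a target conversion. Ties
#' (within `tie_tol` in conversion) are broken by shorter time, then lower
#' temperature, then lower mass fraction. Optima on a grid boundary are
#' flagged.
#'
#' @param model a [nitration_model()].
#' @param temperature,w,time_s grid vectors (kelvin, percent, seconds);
#'   defaults span the soft envelope.
#' @param target optional target conversion in (0, 1); when supplied the
#'   optimizer returns the cheapest (by the tie-break order) grid cell whose
#'   predicted conversion reaches the target, erroring if none does.
#' @param allow_extrapolation include soft-extrapolated cells (still inside
#'   the hard envelope).
#' @param m_ratio,c_io0 optional overrides.
#' @param tie_tol conversions within this of the best count as ties.
#' @return list of class `optimization_result`: `best` (one-row data.frame),
#'   `on_boundary` (named logical for t/T/w), `n_evaluated`, `surface`.
#' @export
optimize_conditions <- function(model, temperature = NULL, w = NULL,
                                time_s = NULL, target = NULL,
                                allow_extrapolation = FALSE,
                                m_ratio = NULL, c_io0 = NULL,
                                tie_tol = 1e-9) {
  env <- model$envelope
  if (is.null(temperature)) {
    temperature <- seq(env$t_soft[1], env$t_soft[2], length.out = 5)
  }
  if (is.null(w)) w <- seq(env$w_soft[1], env$w_soft[2], by = 1)
  if (is.null(time_s)) {
    time_s <- seq(max(env$time_soft[1], 30), env$time_soft[2],
                  length.out = 10)
  }
  surface <- response_surface(model, time_s, temperature, w,
                              m_ratio = m_ratio, c_io0 = c_io0)
  if (!allow_extrapolation) {
    surface <- surface[surface$flag == "interior", , drop = FALSE]
  }
  if (nrow(surface) == 0) nk_stop("nk_value_error", "empty feasible grid")
  feasible <- if (is.null(target)) {
    best_x <- max(surface$conversion)
    surface[surface$conversion >= best_x - tie_tol, , drop = FALSE]
  } else {
    hit <- surface[surface$conversion >= target, , drop = FALSE]
    if (nrow(hit) == 0) {
      nk_stop("nk_fit_error",
              "target conversion %.3f not reached anywhere on the grid",
              target)
    }
    hit
  }
  ord <- order(feasible$time_s, feasible$temperature, feasible$w_h2so4)
  best <- feasible[ord[1], , drop = FALSE]
  rownames(best) <- NULL
  structure(
    list(best = best,
         on_boundary = c(
           time = best$time_s %in% range(time_s),
           temperature = best$temperature %in% range(temperature),
           w = best$w_h2so4 %in% range(w)),
         n_evaluated = nrow(surface),
         surface = surface),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<optimization_result> x = %.3f at T = %.2f K, w = %.1f%%, t = %.1f s%s\n",
    b$conversion, b$temperature, b$w_h2so4, b$time_s,
    if (any(x$on_boundary)) {
      paste0(" [boundary: ",
             paste(names(x$on_boundary)[x$on_boundary], collapse = ","), "]")
    } else ""))
  invisible(x)
}
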