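## Two-stage empirical model of the nitronium fraction lg(c_NO2+/c_HNO3)
## as a function of H2SO4 mass fraction and temperature, fitted from a
## literature-style table: stage 1 regresses lg-ratio on mass fraction
## within each temperature, stage 2 regresses the stage-1 lines, evaluated
## on a mass-fraction grid, on 1/T.

#' Validate a nitronium-fraction table
#'
#' A nitronium table holds literature-style observations of the base-10 log
#' of the nitronium-to-nitric-acid concentration ratio by temperature and
#' sulfuric-acid mass fraction.
#'
#' @param x data.frame with columns `temperature` (kelvin), `w_h2so4`
#'   (percent), `lg_ratio` (dimensionless).
#' @return the validated data.frame, classed `nitronium_table`.
#' @export
nitronium_table <- function(x) {
  req <- c("temperature", "w_h2so4", "lg_ratio")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    nk_stop("nk_schema_error",
            "nitronium table needs columns: %s", paste(req, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(x[req])))) {
    nk_stop("nk_schema_error", "nitronium table contains non-finite values")
  }
  if (any(x$temperature <= 0) || any(x$w_h2so4 <= 0)) {
    nk_stop("nk_schema_error",
            "temperatures and mass fractions must be positive")
  }
  n_per_t <- tapply(x$w_h2so4, x$temperature, function(w) length(unique(w)))
  if (length(n_per_t) < 2) {
    nk_stop("nk_schema_error",
            "need at least 2 distinct temperatures for the two-stage fit")
  }
  if (any(n_per_t < 2)) {
    bad <- names(n_per_t)[n_per_t < 2][1]
    nk_stop("nk_schema_error",
            "temperature group %s K has fewer than 2 distinct mass fractions",
            bad)
  }
  class(x) <- unique(c("nitronium_table", class(x)))
  x
}

#' Stage 1: per-temperature lines of lg-ratio versus mass fraction
#'
#' Ordinary least squares of `lg_ratio` on `w_h2so4` within each temperature
#' group of the table.
#'
#' @param table a [nitronium_table()] (or coercible data.frame).
#' @return data.frame with one row per temperature: `temperature`, `slope`,
#'   `intercept`, `r2`, `n_points`, `w_min`, `w_max`.
#' @export
fit_stage1 <- function(table) {
  table <- nitronium_table(as.data.frame(table))
  groups <- split(as.data.frame(table), table$temperature)
  rows <- lapply(groups, function(g) {
    if (length(unique(g$w_h2so4)) < 2) {
      nk_stop("nk_fit_error",
              "temperature group %g K is underdetermined (single w)",
              g$temperature[1])
    }
    fit <- stats::lm(lg_ratio ~ w_h2so4, data = g)
    data.frame(
      temperature = g$temperature[1],
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = if (nrow(g) > 2) suppressWarnings(summary(fit))$r.squared else 1,
      n_points = nrow(g),
      w_min = min(g$w_h2so4), w_max = max(g$w_h2so4)
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$temperature), , drop = FALSE]
}

#' Stage 2: per-mass-fraction lines of lg-ratio versus 1/T
#'
#' Evaluates each stage-1 line at every mass fraction of `w_grid` and
#' regresses the values on 1/T (kelvin) by ordinary least squares, giving
#' one line per grid mass fraction.
#'
#' @param stage1 output of [fit_stage1()].
#' @param w_grid numeric vector of mass fractions (percent) at which to fit
#'   the inverse-temperature lines.
#' @return data.frame with one row per grid point: `w_h2so4`, `slope`
#'   (coefficient of 1/T), `intercept`, `extrapolated` (TRUE where the grid
#'   point lies outside some stage-1 fitted w span).
#' @export
fit_stage2 <- function(stage1, w_grid) {
  if (length(w_grid) == 0) nk_stop("nk_value_error", "empty w grid")
  if (nrow(stage1) < 2) {
    nk_stop("nk_fit_error", "need stage-1 lines at >= 2 temperatures")
  }
  inv_t <- 1 / stage1$temperature
  rows <- lapply(w_grid, function(w) {
    y <- stage1$intercept + stage1$slope * w
    fit <- stats::lm(y ~ inv_t)
    data.frame(
      w_h2so4 = w,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      extrapolated = any(w < stage1$w_min | w > stage1$w_max)
    )
  })
  do.call(rbind, rows)
}

#' Fit the two-stage nitronium-fraction model
#'
#' Runs [fit_stage1()] and [fit_stage2()] and packages the result with its
#' calibration ranges into a `nitronium_model`.
#'
#' @inheritParams fit_stage1
#' @param w_grid mass-fraction grid for stage 2; default a 1-point grid over
#'   the table's w span.
#' @return an object of class `nitronium_model`.
#' @export
fit_nitronium <- function(table, w_grid = NULL) {
  table <- nitronium_table(as.data.frame(table))
  stage1 <- fit_stage1(table)
  if (is.null(w_grid)) {
    w_grid <- seq(floor(min(table$w_h2so4)), ceiling(max(table$w_h2so4)),
                  by = 1)
  }
  stage2 <- fit_stage2(stage1, w_grid)
  structure(
    list(stage1 = stage1, stage2 = stage2,
         w_min = min(table$w_h2so4), w_max = max(table$w_h2so4),
         t_min = min(table$temperature), t_max = max(table$temperature)),
    class = "nitronium_model"
  )
}

#' Evaluate lg(c_NO2+/c_HNO3) from a fitted model
#'
#' Evaluates the stage-2 lines at the requested temperature and linearly
#' interpolates between the bracketing grid mass fractions. Queries outside
#' the model's calibrated (w, T) ranges are evaluated anyway and flagged.
#'
#' @param model a fitted [fit_nitronium()] model.
#' @param w mass fraction of H2SO4 in percent (vectorized).
#' @param temperature temperature in kelvin (vectorized or scalar).
#' @return data.frame with columns `lg_ratio` and `extrapolated`.
#' @export
lg_ratio <- function(model, w, temperature) {
  if (!inherits(model, "nitronium_model")) {
    nk_stop("nk_state_error", "model is not a fitted nitronium_model")
  }
  n <- max(length(w), length(temperature))
  w <- rep_len(w, n); temperature <- rep_len(temperature, n)
  s2 <- model$stage2
  val <- vapply(seq_len(n), function(i) {
    line_vals <- s2$intercept + s2$slope / temperature[i]
    if (length(s2$w_h2so4) == 1) return(line_vals[1])
    ## linear interpolation between bracketing grid lines; linear
    ## extrapolation from the outermost pair outside the grid
    stats::approx(s2$w_h2so4, line_vals, xout = w[i], rule = 2)$y +
      if (w[i] < min(s2$w_h2so4)) {
        (w[i] - min(s2$w_h2so4)) * (line_vals[2] - line_vals[1]) /
          (s2$w_h2so4[2] - s2$w_h2so4[1])
      } else if (w[i] > max(s2$w_h2so4)) {
        m <- length(line_vals)
        (w[i] - max(s2$w_h2so4)) * (line_vals[m] - line_vals[m - 1]) /
          (s2$w_h2so4[m] - s2$w_h2so4[m - 1])
      } else 0
  }, numeric(1))
  data.frame(
    lg_ratio = val,
    extrapolated = w < model$w_min | w > model$w_max |
      temperature < model$t_min | temperature > model$t_max
  )
}

#' @export
print.nitronium_model <- function(x, ...) {
  cat(sprintf(
    "<nitronium_model> %d temperatures (%.1f-%.1f K), w in [%.1f, %.1f] %%\n",
    nrow(x$stage1), x$t_min, x$t_max, x$w_min, x$w_max))
  cat(sprintf("  stage-1 R2: %s\n",
              paste(sprintf("%.4f", x$stage1$r2), collapse = ", ")))
  invisible(x)
}

#' Serialize a nitronium model to JSON
#'
#' @param model a fitted `nitronium_model`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
nitronium_model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "nitronium_model"))
  js <- jsonlite::toJSON(unclass(model), dataframe = "columns",
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a nitronium model from JSON
#'
#' @param path file path or JSON string produced by
#'   [nitronium_model_to_json()].
#' @return a `nitronium_model`.
#' @export
nitronium_model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$stage1 <- as.data.frame(obj$stage1)
  obj$stage2 <- as.data.frame(obj$stage2)
  structure(obj, class = "nitronium_model")
}
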