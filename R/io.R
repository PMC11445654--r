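## Readers/writers for the package's CSV and JSON schemas plus run-config
## loading. CSV dialect: comma separator, dot decimal, UTF-8, mandatory
## header, '#'-prefixed comment lines carrying key=value metadata.

read_metadata_comments <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.+)\\s*$",
                           meta_lines))
  kv <- Filter(function(m) length(m) == 3, kv)
  out <- lapply(kv, function(m) {
    v <- suppressWarnings(as.numeric(m[3]))
    if (is.na(v)) m[3] else v
  })
  names(out) <- vapply(kv, `[`, character(1), 2)
  out
}

#' Read a conversion-time series from CSV
#'
#' Expects columns `time_s` (or `time_min` with `time_unit = "min"`) and
#' `x_io`, with the condition metadata (`temperature_C`, `w_h2so4_percent`,
#' `c_io0_M`, `c_hno3_0_M`) either in `#`-prefixed `key = value` comment
#' lines at the top of the file or supplied through `condition`.
#'
#' @param path CSV file path.
#' @param time_unit `"s"` or `"min"`; minute inputs are converted to
#'   seconds on ingest.
#' @param condition optional named list overriding/supplying the metadata
#'   keys above.
#' @return a [conversion_series()].
#' @export
read_conversion_series <- function(path, time_unit = c("s", "min"),
                                   condition = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) nk_stop("nk_schema_error", "no such file: %s", path)
  meta <- utils::modifyList(read_metadata_comments(path),
                            as.list(condition %||% list()))
  df <- utils::read.csv(path, comment.char = "#")
  time_col <- if (time_unit == "s") "time_s" else "time_min"
  for (col in c(time_col, "x_io")) {
    if (!col %in% names(df)) {
      nk_stop("nk_schema_error", "missing column '%s' in %s", col, path)
    }
  }
  need <- c("temperature_C", "w_h2so4_percent", "c_io0_M", "c_hno3_0_M")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    nk_stop("nk_schema_error", "missing condition metadata: %s",
            paste(missing, collapse = ", "))
  }
  bad <- which(df$x_io < 0 | df$x_io >= 1)
  if (length(bad) > 0) {
    nk_stop("nk_schema_error",
            "conversion out of [0, 1) at row %d, column x_io", bad[1])
  }
  times <- df[[time_col]] * if (time_unit == "min") 60 else 1
  if (any(diff(times) <= 0)) {
    nk_stop("nk_schema_error",
            "times must be strictly increasing (violated at row %d)",
            which(diff(times) <= 0)[1] + 1)
  }
  conversion_series(
    times, df$x_io,
    temperature = celsius_to_kelvin(meta$temperature_C),
    w_h2so4 = meta$w_h2so4_percent,
    c_io0 = meta$c_io0_M, c_hno3_0 = meta$c_hno3_0_M,
    metadata = meta
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a conversion-time series to CSV
#'
#' Inverse of [read_conversion_series()]: condition metadata goes into
#' `#`-prefixed comment lines, data into `time_s`, `x_io` columns.
#'
#' @param series a [conversion_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_conversion_series <- function(series, path) {
  stopifnot(inherits(series, "conversion_series"))
  meta <- c(
    sprintf("# temperature_C = %.10g", series$temperature - KELVIN_OFFSET),
    sprintf("# w_h2so4_percent = %.10g", series$w_h2so4),
    sprintf("# c_io0_M = %.10g", series$c_io0),
    sprintf("# c_hno3_0_M = %.10g", series$c_hno3_0)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(
    data.frame(time_s = series$times, x_io = series$conversions),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an apparent rate-constant table from CSV
#'
#' Columns: `temperature_C`, `w_h2so4_percent`, `k_L_per_mol_s`, optionally
#' `r2` and `intercept`.
#'
#' @param path CSV file path.
#' @return data.frame with internal columns `temperature` (kelvin),
#'   `w_h2so4`, `k`, `r2`, `intercept`.
#' @export
read_apparent_rate_table <- function(path) {
  if (!file.exists(path)) nk_stop("nk_schema_error", "no such file: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("temperature_C", "w_h2so4_percent", "k_L_per_mol_s")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    nk_stop("nk_schema_error", "missing columns: %s",
            paste(missing, collapse = ", "))
  }
  if (any(df$k_L_per_mol_s <= 0)) {
    nk_stop("nk_schema_error", "non-positive k at row %d",
            which(df$k_L_per_mol_s <= 0)[1])
  }
  data.frame(
    temperature = celsius_to_kelvin(df$temperature_C),
    w_h2so4 = df$w_h2so4_percent,
    k = df$k_L_per_mol_s,
    r2 = df$r2 %||% rep(NA_real_, nrow(df)),
    intercept = df$intercept %||% rep(NA_real_, nrow(df))
  )
}

#' Write an apparent rate-constant table to CSV
#'
#' Deterministic column order and formatting; `k` is written to 4
#' significant figures (the conventional presentation of such tables),
#' `r2` and `intercept` to 4 decimals.
#'
#' @param table data.frame as produced by [apparent_rate_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_apparent_rate_table <- function(table, path) {
  out <- data.frame(
    temperature_C = table$temperature - KELVIN_OFFSET,
    w_h2so4_percent = table$w_h2so4,
    k_L_per_mol_s = signif(table$k, 4),
    r2 = round(table$r2 %||% NA_real_, 4),
    intercept = round(table$intercept %||% NA_real_, 4)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a nitronium-fraction table from CSV
#'
#' Columns: `temperature_C`, `w_h2so4_percent`, `lg_ratio`.
#'
#' @param path CSV file path.
#' @return a [nitronium_table()] (temperatures converted to kelvin).
#' @export
read_nitronium_table <- function(path) {
  if (!file.exists(path)) nk_stop("nk_schema_error", "no such file: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("temperature_C", "w_h2so4_percent", "lg_ratio")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    nk_stop("nk_schema_error", "missing columns: %s",
            paste(missing, collapse = ", "))
  }
  nitronium_table(data.frame(
    temperature = celsius_to_kelvin(df$temperature_C),
    w_h2so4 = df$w_h2so4_percent,
    lg_ratio = df$lg_ratio
  ))
}

#' Write the intrinsic-kinetics report
#'
#' JSON report with the per-temperature (n, lg k0, R2) table and the global
#' Arrhenius parameters, mirroring the package's CSV conventions: `lg_k0`
#' to 4 decimals, activation energy in kJ/mol to 2 decimals.
#'
#' @param intrinsic per-temperature table from [intrinsic_table()].
#' @param arrhenius an [fit_arrhenius()] result.
#' @param path output file path; omit to get the JSON string.
#' @return the JSON string, invisibly when written.
#' @export
write_intrinsic_report <- function(intrinsic, arrhenius, path = NULL) {
  report <- list(
    per_temperature = data.frame(
      temperature_C = intrinsic$temperature - KELVIN_OFFSET,
      n = round(intrinsic$n, 4),
      lg_k0 = round(intrinsic$lg_k0, 4),
      r2 = round(intrinsic$r2, 4)
    ),
    arrhenius = list(
      ea_kJ_per_mol = round(arrhenius$ea / 1000, 2),
      ln_a = round(arrhenius$ln_a, 2),
      r2 = round(arrhenius$r2, 4)
    )
  )
  js <- jsonlite::toJSON(report, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Load and validate a run configuration
#'
#' Flat key-value YAML file. Recognized keys (all optional, defaults shown
#' by [default_run_config()]): `gas_constant`, `density_table_path`,
#' `delta_r2_threshold`, `time_unit`, `strict_extrapolation`, and envelope
#' bounds `t_soft_C`, `t_hard_C`, `w_soft`, `w_hard`, `time_soft_s`,
#' `time_hard_s` (each a 2-vector). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) nk_stop("nk_schema_error", "no such file: %s", path)
  user <- yaml::read_yaml(path)
  defaults <- default_run_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    nk_stop("nk_schema_error", "unknown config keys: %s",
            paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  if (cfg$gas_constant <= 0) {
    nk_stop("nk_schema_error", "gas_constant must be positive")
  }
  if (!cfg$time_unit %in% c("s", "min")) {
    nk_stop("nk_schema_error", "time_unit must be 's' or 'min'")
  }
  structure(cfg, class = "run_config")
}

#' Default run configuration
#' @return list of documented defaults (see [read_run_config()]).
#' @export
default_run_config <- function() {
  list(
    gas_constant = GAS_CONSTANT,
    density_table_path = NULL,
    delta_r2_threshold = 0.005,
    time_unit = "s",
    strict_extrapolation = FALSE,
    t_soft_C = c(30, 40), t_hard_C = c(0, 45),
    w_soft = c(88, 98), w_hard = c(80, 100),
    time_soft_s = c(0, 282), time_hard_s = c(0, 900)
  )
}

#' Build a calibration envelope from a run configuration
#' @param config a [read_run_config()] result or [default_run_config()].
#' @return a [calibration_envelope()].
#' @export
envelope_from_config <- function(config = default_run_config()) {
  calibration_envelope(
    t_soft = celsius_to_kelvin(config$t_soft_C),
    t_hard = celsius_to_kelvin(config$t_hard_C),
    w_soft = config$w_soft, w_hard = config$w_hard,
    time_soft = config$time_soft_s, time_hard = config$time_hard_s
  )
}
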