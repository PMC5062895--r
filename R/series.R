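#' Temperature-yield series
#'
#' One analyte's yield (GC-area counts) across pyrolysis temperatures —
#' the input to the destruction pipeline. Temperatures are stored in kelvin;
#' use [read_temperature_series()] for Celsius input files.
#'
#' @param temperature numeric vector of temperatures in kelvin, strictly
#'   increasing, at least 3 values.
#' @param yield numeric vector of nonnegative yields (GC-area counts).
#' @param sample_id cigarette/sample label, e.g. `"ES1"`.
#' @param analyte analyte label, e.g. `"nicotine"`.
#' @param residence_time reaction time in seconds used when converting
#'   yield ratios into rate constants; default 2.0 s (average puff time).
#' @return A data.frame of class `temperature_yield_series` with columns
#'   `temperature` and `yield`; labels and residence time are attributes.
#' @export
temperature_yield_series <- function(temperature, yield,
                                     sample_id = "sample",
                                     analyte = "nicotine",
                                     residence_time = 2.0) {
  stopifnot(is.numeric(temperature), is.numeric(yield),
            length(temperature) == length(yield))
  if (length(temperature) < 3L) {
    stop("a temperature-yield series needs at least 3 points", call. = FALSE)
  }
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperatures must be finite positive kelvin values", call. = FALSE)
  }
  if (is.unsorted(temperature, strictly = TRUE)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(yield)) || any(yield < 0)) {
    stop("yields must be finite and nonnegative", call. = FALSE)
  }
  if (!is.numeric(residence_time) || residence_time <= 0) {
    stop("`residence_time` must be positive", call. = FALSE)
  }
  structure(
    data.frame(temperature = as.numeric(temperature),
               yield = as.numeric(yield)),
    sample_id = as.character(sample_id),
    analyte = as.character(analyte),
    residence_time = as.numeric(residence_time),
    class = c("temperature_yield_series", "data.frame")
  )
}

#' @export
print.temperature_yield_series <- function(x, ...) {
  cat(sprintf("Temperature-yield series: %s / %s (%d points, t = %g s)\n",
              attr(x, "sample_id"), attr(x, "analyte"), nrow(x),
              attr(x, "residence_time")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Puff-time yield series
#'
#' Yields of an analyte at increasing puff (smoking) times — the input to
#' the formation pipeline.
#'
#' @param puff_time numeric vector of puff durations in seconds, strictly
#'   increasing and positive, at least 2 values.
#' @param yield numeric vector of positive yields (GC-area counts); the
#'   log-linear fit requires strictly positive values.
#' @return A data.frame of class `puff_series` with columns `puff_time`
#'   and `yield`.
#' @export
puff_series <- function(puff_time, yield) {
  stopifnot(is.numeric(puff_time), is.numeric(yield),
            length(puff_time) == length(yield))
  if (length(puff_time) < 2L) {
    stop("a puff series needs at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(puff_time)) || any(puff_time <= 0)) {
    stop("puff times must be finite and positive", call. = FALSE)
  }
  if (is.unsorted(puff_time, strictly = TRUE)) {
    stop("puff times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(yield)) || any(yield <= 0)) {
    stop("yields must be finite and positive", call. = FALSE)
  }
  structure(
    data.frame(puff_time = as.numeric(puff_time), yield = as.numeric(yield)),
    class = c("puff_series", "data.frame")
  )
}

validate_numeric_column <- function(raw, column, path) {
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) | !nzchar(trimws(raw)))
  if (length(bad) > 0) {
    # +1 for the header line
    stop(sprintf("%s: non-numeric `%s` values on line(s) %s", path, column,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  vals
}

read_two_column_csv <- function(path, columns) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE, check.names = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(columns, function(cn) validate_numeric_column(df[[cn]], cn,
                                                              path))
  names(out) <- columns
  out
}

#' Read a temperature-yield CSV
#'
#' Reads a CSV with columns `temperature,yield` (header required). The
#' temperature unit is declared per file and converted to kelvin at this
#' I/O boundary (Celsius conversion uses +273.15). Malformed rows are
#' reported with their line numbers; duplicate temperatures are an error.
#'
#' @param path path to the CSV file.
#' @param temp_unit `"celsius"` (default, matching a 200-700 degC pyrolysis
#'   axis) or `"kelvin"`.
#' @param sample_id,analyte,residence_time passed to
#'   [temperature_yield_series()].
#' @return A [temperature_yield_series()].
#' @export
read_temperature_series <- function(path, temp_unit = c("celsius", "kelvin"),
                                    sample_id = "sample",
                                    analyte = "nicotine",
                                    residence_time = 2.0) {
  temp_unit <- match.arg(temp_unit)
  cols <- read_two_column_csv(path, c("temperature", "yield"))
  temp <- cols$temperature
  if (temp_unit == "celsius") temp <- temp + 273.15
  if (anyDuplicated(temp)) {
    dup <- which(duplicated(temp) | duplicated(temp, fromLast = TRUE))
    stop(sprintf("%s: duplicate temperature rows on line(s) %s", path,
                 paste(dup + 1L, collapse = ", ")), call. = FALSE)
  }
  ord <- order(temp)
  temperature_yield_series(temp[ord], cols$yield[ord],
                           sample_id = sample_id, analyte = analyte,
                           residence_time = residence_time)
}

#' Read a puff-time yield CSV
#'
#' Reads a CSV with columns `puff_time_s,yield` (header required).
#'
#' @param path path to the CSV file.
#' @return A [puff_series()].
#' @export
read_puff_series <- function(path) {
  cols <- read_two_column_csv(path, c("puff_time_s", "yield"))
  if (anyDuplicated(cols$puff_time_s)) {
    dup <- which(duplicated(cols$puff_time_s) |
                   duplicated(cols$puff_time_s, fromLast = TRUE))
    stop(sprintf("%s: duplicate puff-time rows on line(s) %s", path,
                 paste(dup + 1L, collapse = ", ")), call. = FALSE)
  }
  ord <- order(cols$puff_time_s)
  puff_series(cols$puff_time_s[ord], cols$yield[ord])
}

#' Write a temperature-yield series to CSV
#'
#' Writes the `temperature,yield` dialect read by
#' [read_temperature_series()]. Values are written at full precision so a
#' kelvin-declared file round-trips unchanged.
#'
#' @param series a [temperature_yield_series()].
#' @param path output path.
#' @param temp_unit unit to write temperatures in.
#' @return `path`, invisibly.
#' @export
write_temperature_series <- function(series, path,
                                     temp_unit = c("kelvin", "celsius")) {
  stopifnot(inherits(series, "temperature_yield_series"))
  temp_unit <- match.arg(temp_unit)
  temp <- series$temperature
  if (temp_unit == "celsius") temp <- temp - 273.15
  df <- data.frame(temperature = format(temp, digits = 15, trim = TRUE),
                   yield = format(series$yield, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a puff series to CSV
#'
#' Writes the `puff_time_s,yield` dialect read by [read_puff_series()].
#'
#' @param series a [puff_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_puff_series <- function(series, path) {
  stopifnot(inherits(series, "puff_series"))
  df <- data.frame(puff_time_s = format(series$puff_time, digits = 15,
                                        trim = TRUE),
                   yield = format(series$yield, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
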