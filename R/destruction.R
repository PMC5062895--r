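#' Locate the yield peak of a temperature series
#'
#' The maximum yield marks the temperature where the rates of formation and
#' destruction balance; that peak yield is taken as the reference
#' concentration C0 for the destruction analysis. Ties on the maximum are
#' broken toward the lowest temperature (earliest formation).
#'
#' @param series a [temperature_yield_series()].
#' @return A list with `temperature` (kelvin) and `yield` (counts, = C0).
#' @export
find_peak <- function(series) {
  stopifnot(inherits(series, "temperature_yield_series"))
  if (all(series$yield == 0)) {
    stop("peak detection: all yields are zero, no peak exists", call. = FALSE)
  }
  i <- which.max(series$yield)  # which.max takes the first (lowest-T) tie
  list(temperature = series$temperature[i], yield = series$yield[i])
}

#' Per-temperature destruction rate constants
#'
#' Applies the integrated first-order rate law over the destruction window:
#' for every point above the peak temperature with `0 < yield < C0`,
#' \eqn{k(T) = \ln(C_0/\mathrm{yield})/t} with `t` the series residence
#' time. Post-peak points with `yield >= C0` (noise) or zero yield are
#' excluded and logged rather than clamped — clamping would fabricate
#' k = 0 and bias the Arrhenius fit.
#'
#' @param series a [temperature_yield_series()].
#' @param peak optional precomputed [find_peak()] result.
#' @param strict if `TRUE`, any excluded point is an error instead.
#' @return A [rate_constant_table()] with an `excluded` attribute: a
#'   data.frame of (temperature, yield, reason) for dropped post-peak
#'   points.
#' @export
compute_rate_constants <- function(series, peak = NULL, strict = FALSE) {
  stopifnot(inherits(series, "temperature_yield_series"))
  if (is.null(peak)) peak <- find_peak(series)
  t_res <- attr(series, "residence_time")
  post <- series[series$temperature > peak$temperature, , drop = FALSE]
  if (nrow(post) == 0L) {
    stop("empty destruction window: no points above the peak temperature",
         call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(post))
  reason[post$yield >= peak$yield] <- "yield >= C0 (not a destruction regime)"
  reason[post$yield <= 0] <- "zero yield (infinite rate)"
  keep <- is.na(reason)
  if (strict && any(!keep)) {
    stop(sprintf("strict mode: %d post-peak point(s) violate 0 < yield < C0",
                 sum(!keep)), call. = FALSE)
  }
  if (!any(keep)) {
    stop("empty destruction window: every post-peak point was excluded",
         call. = FALSE)
  }
  tab <- rate_constant_table(
    post$temperature[keep],
    k_from_yield_ratio(peak$yield, post$yield[keep], t_res)
  )
  attr(tab, "excluded") <- data.frame(
    temperature = post$temperature[!keep],
    yield = post$yield[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  tab
}

#' Average destruction rate constant
#'
#' Arithmetic mean of the per-temperature rate constants over the
#' destruction window, invariant to entry order.
#'
#' @param table a [rate_constant_table()].
#' @return Mean rate constant, s^-1.
#' @export
average_rate_constant <- function(table) {
  stopifnot(inherits(table, "rate_constant_table"))
  if (nrow(table) == 0L) stop("empty rate-constant table", call. = FALSE)
  mean(table$k)
}

#' End-to-end destruction analysis
#'
#' Composes the full destruction pipeline on one temperature-yield series:
#' peak detection (C0 convention), per-temperature rate constants over the
#' destruction window, the Arrhenius regression of ln k on 1/T, the
#' modified-Arrhenius temperature exponent solved at every window
#' temperature, and the window-average rate constant. Deterministic for a
#' fixed input.
#'
#' @param series a [temperature_yield_series()].
#' @param gas_constant molar gas constant, J K^-1 mol^-1.
#' @param strict passed to [compute_rate_constants()].
#' @return An object of class `destruction_result`: a list with fields
#'   `sample_id`, `analyte`, `peak_temperature`, `c0`, `rate_constants`,
#'   `arrhenius`, `exponents` (data.frame of temperature and n),
#'   `k_average`, `excluded_points`, `residence_time`.
#' @examples
#' cfg <- fixture_es1(noise_sd = 0)
#' run_destruction_analysis(generate_yield_curve(cfg))
#' @export
run_destruction_analysis <- function(series, gas_constant = GAS_CONSTANT,
                                     strict = FALSE) {
  stopifnot(inherits(series, "temperature_yield_series"))
  peak <- withCallingHandlers(
    find_peak(series),
    error = function(e) stop(paste0("[peak detection] ", conditionMessage(e)),
                             call. = FALSE)
  )
  tab <- tryCatch(
    compute_rate_constants(series, peak = peak, strict = strict),
    error = function(e) stop(paste0("[rate constants] ", conditionMessage(e)),
                             call. = FALSE)
  )
  arr <- tryCatch(
    fit_arrhenius(tab, gas_constant = gas_constant),
    error = function(e) stop(paste0("[Arrhenius fit] ", conditionMessage(e)),
                             call. = FALSE)
  )
  exponents <- data.frame(
    temperature = tab$temperature,
    n = solve_temperature_exponent(tab$k, arr, tab$temperature,
                                   gas_constant = gas_constant)
  )
  structure(
    list(
      sample_id = attr(series, "sample_id"),
      analyte = attr(series, "analyte"),
      peak_temperature = peak$temperature,
      c0 = peak$yield,
      rate_constants = tab,
      arrhenius = arr,
      exponents = exponents,
      k_average = average_rate_constant(tab),
      excluded_points = attr(tab, "excluded"),
      residence_time = attr(series, "residence_time")
    ),
    class = "destruction_result"
  )
}

#' @export
print.destruction_result <- function(x, ...) {
  cat(sprintf("Destruction analysis: %s / %s\n", x$sample_id, x$analyte))
  cat(sprintf("  peak: %.4g counts at %.4g K (C0)\n", x$c0,
              x$peak_temperature))
  cat(sprintf("  window: %d points, %d excluded\n", nrow(x$rate_constants),
              nrow(x$excluded_points)))
  cat(sprintf("  Ea = %.2f kJ/mol, A = %.3g 1/s, r^2 = %.6f\n",
              x$arrhenius$Ea / 1000, x$arrhenius$A, x$arrhenius$r_squared))
  cat(sprintf("  average k over window = %.4g 1/s\n", x$k_average))
  invisible(x)
}
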