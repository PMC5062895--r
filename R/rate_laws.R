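#' Universal gas constant
#'
#' Default value of the molar gas constant used throughout the package,
#' in J K^-1 mol^-1. Activation energies are therefore carried internally
#' in J mol^-1; only the report layer rescales to kJ mol^-1.
#'
#' @export
GAS_CONSTANT <- 8.314

#' Arrhenius parameters
#'
#' Container for the parameters of the Arrhenius rate expression
#' \eqn{k = A e^{-E_a/(RT)}}: the activation energy \eqn{E_a} (J mol^-1),
#' the pre-exponential factor \eqn{A} (s^-1), and, when the parameters come
#' from a regression, the coefficient of determination and the number of
#' (T, k) pairs fitted.
#'
#' @param Ea activation energy in J mol^-1 (finite; may be zero or negative
#'   for a purely empirical fit, though physically it is positive here).
#' @param A pre-exponential factor in s^-1; must be > 0.
#' @param r_squared goodness of fit of the underlying `ln k` vs `1/T`
#'   regression, in `[0, 1]`; `NA` for parameters not obtained by regression.
#' @param n_points number of (temperature, rate-constant) pairs fitted;
#'   `NA` for externally supplied parameters.
#'
#' @return An object of class `arrhenius_parameters`.
#' @seealso [fit_arrhenius()], [arrhenius_k()]
#' @examples
#' arrhenius_parameters(Ea = 108850, A = 2.1e6)
#' @export
arrhenius_parameters <- function(Ea, A, r_squared = NA_real_,
                                 n_points = NA_integer_) {
  stopifnot(is.numeric(Ea), length(Ea) == 1L, is.finite(Ea))
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0) {
    stop("pre-exponential factor `A` must be a single positive number",
         call. = FALSE)
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1 + 1e-12)) {
    stop("`r_squared` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.na(n_points) && n_points < 2) {
    stop("`n_points` must be at least 2", call. = FALSE)
  }
  structure(
    list(Ea = as.numeric(Ea), A = as.numeric(A),
         r_squared = as.numeric(r_squared),
         n_points = if (is.na(n_points)) NA_integer_ else as.integer(n_points)),
    class = "arrhenius_parameters"
  )
}

#' @export
print.arrhenius_parameters <- function(x, ...) {
  cat("Arrhenius parameters\n")
  cat(sprintf("  Ea: %.2f kJ/mol\n", x$Ea / 1000))
  cat(sprintf("  A : %.3g 1/s\n", x$A))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  fit: r^2 = %.6f over %d points\n", x$r_squared, x$n_points))
  }
  invisible(x)
}

#' Table of per-temperature rate constants
#'
#' Ordered (temperature, rate constant) pairs, the input to the Arrhenius
#' regression. Temperatures are in kelvin and must be strictly increasing;
#' rate constants are in s^-1 and must be positive.
#'
#' @param temperature numeric vector of temperatures, kelvin.
#' @param k numeric vector of pseudo-first-order rate constants, s^-1.
#' @return A data.frame of class `rate_constant_table` with columns
#'   `temperature` and `k`.
#' @examples
#' rate_constant_table(c(673, 973), c(0.31, 2.12))
#' @export
rate_constant_table <- function(temperature, k) {
  stopifnot(is.numeric(temperature), is.numeric(k),
            length(temperature) == length(k))
  if (length(temperature) < 1L) {
    stop("rate-constant table must contain at least one entry", call. = FALSE)
  }
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("all temperatures must be finite and positive (kelvin)", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("all rate constants must be finite and positive", call. = FALSE)
  }
  if (is.unsorted(temperature, strictly = TRUE)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(temperature = as.numeric(temperature), k = as.numeric(k)),
    class = c("rate_constant_table", "data.frame")
  )
}

#' First-order integrated rate law
#'
#' Concentration remaining after time `t` of a species decaying with
#' pseudo-first-order rate constant `k`: \eqn{C = C_0 e^{-kt}}.
#'
#' @param c0 initial concentration (GC-area counts or any nonnegative unit).
#' @param k rate constant, s^-1, nonnegative.
#' @param t time, seconds, nonnegative; may be a vector.
#' @return Concentration(s) at `t`, same unit as `c0`.
#' @examples
#' first_order_concentration(8.0e8, k = 0.31, t = 2)
#' @export
first_order_concentration <- function(c0, k, t) {
  stopifnot(is.numeric(c0), is.numeric(k), is.numeric(t))
  if (any(c0 < 0)) stop("`c0` must be nonnegative", call. = FALSE)
  if (any(k < 0)) stop("`k` must be nonnegative", call. = FALSE)
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  c0 * exp(-k * t)
}

#' Rate constant from a concentration ratio
#'
#' Inverts the integrated first-order rate law for the rate constant:
#' \eqn{k = \ln(C_0 / C) / t}. Used per post-peak temperature in the
#' destruction pipeline, where `c0` is the peak yield and `c` the yield at
#' that temperature.
#'
#' @param c0 reference (initial/peak) concentration, > 0.
#' @param c remaining concentration; must satisfy `0 < c <= c0` — a value
#'   above `c0` is not a destruction regime and raises an error.
#' @param t reaction time, seconds, > 0.
#' @return Rate constant in s^-1; zero iff `c == c0`.
#' @examples
#' k_from_yield_ratio(8.0e8, 4.303556e8, t = 2)  # ~0.31 1/s
#' @export
k_from_yield_ratio <- function(c0, c, t) {
  stopifnot(is.numeric(c0), is.numeric(c), is.numeric(t))
  if (any(c0 <= 0)) stop("`c0` must be positive", call. = FALSE)
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  if (any(c <= 0)) {
    stop("`c` must be positive (zero concentration implies an infinite rate)",
         call. = FALSE)
  }
  if (any(c > c0)) {
    stop("`c` exceeds `c0`: not a destruction regime", call. = FALSE)
  }
  log(c0 / c) / t
}

#' Arrhenius rate constant
#'
#' Evaluates \eqn{k(T) = A e^{-E_a/(RT)}}.
#'
#' @param params an [arrhenius_parameters()] object (Ea in J mol^-1).
#' @param temperature temperature(s) in kelvin, > 0.
#' @param gas_constant molar gas constant, J K^-1 mol^-1.
#' @return Rate constant(s) in s^-1.
#' @examples
#' arrhenius_k(arrhenius_parameters(108850, 2.1e6), 973)  # ~3.0 1/s
#' @export
arrhenius_k <- function(params, temperature, gas_constant = GAS_CONSTANT) {
  stopifnot(inherits(params, "arrhenius_parameters"), is.numeric(temperature))
  if (any(temperature <= 0)) {
    stop("`temperature` must be positive (kelvin)", call. = FALSE)
  }
  if (gas_constant <= 0) stop("`gas_constant` must be positive", call. = FALSE)
  params$A * exp(-params$Ea / (gas_constant * temperature))
}

#' Modified (Kooij-type) Arrhenius rate constant
#'
#' Evaluates \eqn{k(T) = A T^{n} e^{-E_a/(RT)}}, the modified Arrhenius
#' form with a power-law temperature factor. With `n = 0` this reduces to
#' [arrhenius_k()].
#'
#' @inheritParams arrhenius_k
#' @param n temperature exponent (unitless).
#' @return Rate constant(s) in s^-1.
#' @export
modified_arrhenius_k <- function(params, n, temperature,
                                 gas_constant = GAS_CONSTANT) {
  stopifnot(is.numeric(n), all(is.finite(n)))
  arrhenius_k(params, temperature, gas_constant) * temperature^n
}

#' Solve the modified-Arrhenius temperature exponent
#'
#' Given an experimentally determined rate constant at temperature `T` and
#' Arrhenius parameters fitted over the whole destruction window, solves
#' \eqn{k = A T^{n} e^{-E_a/(RT)}} for the exponent in closed form:
#' \deqn{n = \frac{\ln k - \ln A + E_a/(RT)}{\ln T}.}
#' The expression is monotone in `n` at fixed `T`, so no iteration is needed.
#'
#' @param k observed rate constant, s^-1, > 0.
#' @param params an [arrhenius_parameters()] object.
#' @param temperature temperature in kelvin; must exceed 1 K so that
#'   \eqn{\ln T \neq 0}.
#' @param gas_constant molar gas constant, J K^-1 mol^-1.
#' @return The exponent `n` (unitless).
#' @examples
#' # SM1 cigarette at 673 K: printed k = 0.74 1/s
#' solve_temperature_exponent(0.74, arrhenius_parameters(136520, 3.0e7), 673)
#' @export
solve_temperature_exponent <- function(k, params, temperature,
                                       gas_constant = GAS_CONSTANT) {
  stopifnot(inherits(params, "arrhenius_parameters"), is.numeric(k))
  if (any(k <= 0)) stop("`k` must be positive", call. = FALSE)
  if (any(temperature <= 1)) {
    stop("`temperature` must exceed 1 K", call. = FALSE)
  }
  (log(k) - log(params$A) + params$Ea / (gas_constant * temperature)) /
    log(temperature)
}

#' Fit Arrhenius parameters by linear regression
#'
#' Ordinary least squares of \eqn{\ln k} on \eqn{1/T} (the Arrhenius plot):
#' \eqn{\ln k = \ln A - E_a/(RT)}, so \eqn{E_a = -\mathrm{slope} \cdot R}
#' and \eqn{A = e^{\mathrm{intercept}}}. The regression is unweighted.
#'
#' @param table a [rate_constant_table()] with at least two entries at
#'   distinct temperatures.
#' @param gas_constant molar gas constant, J K^-1 mol^-1.
#' @return An [arrhenius_parameters()] object with `r_squared` and
#'   `n_points` filled in. A table of identical rate constants yields a
#'   flat line: `Ea = 0`, `A = k`, `r_squared = 1`.
#' @export
fit_arrhenius <- function(table, gas_constant = GAS_CONSTANT) {
  stopifnot(inherits(table, "rate_constant_table"))
  if (nrow(table) < 2L) {
    stop("insufficient data: Arrhenius fit needs at least 2 (T, k) pairs",
         call. = FALSE)
  }
  if (length(unique(table$temperature)) < 2L) {
    stop("insufficient data: all temperatures are equal", call. = FALSE)
  }
  inv_t <- 1 / table$temperature
  ln_k <- log(table$k)
  fit <- stats::lm(ln_k ~ inv_t)
  slope <- stats::coef(fit)[["inv_t"]]
  intercept <- stats::coef(fit)[["(Intercept)"]]
  # a perfectly flat response has zero total sum of squares; the fit is exact,
  # and noise-free data legitimately fit perfectly
  r2 <- if (stats::var(ln_k) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  arrhenius_parameters(
    Ea = -slope * gas_constant,
    A = exp(intercept),
    r_squared = min(max(r2, 0), 1),
    n_points = nrow(table)
  )
}
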