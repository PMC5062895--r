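#' Consecutive two-step reaction model
#'
#' The series mechanism Nic \out{&rarr;}(k1) I \out{&rarr;}(k2) Product used
#' to describe the thermal destruction of nicotine via an unobservable
#' pyridinyl-radical intermediate that decays to pyridine. All three species
#' obey coupled linear first-order rate laws; the model carries the two rate
#' constants, the initial nicotine amount and the reference reaction
#' (residence) time.
#'
#' @param k1 destruction rate constant of nicotine, s^-1, > 0.
#' @param k2 conversion rate constant of the intermediate, s^-1, > 0.
#' @param nic0 initial nicotine amount, GC-area counts, > 0.
#' @param t reference residence time, seconds, >= 0. Defaults to 2.0 s, the
#'   average puff duration in cigarette smoking.
#' @return An object of class `consecutive_model`.
#' @examples
#' consecutive_model(k1 = 1.11, k2 = 0.13, nic0 = 8.0e8)
#' @export
consecutive_model <- function(k1, k2, nic0, t = 2.0) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(nic0), is.numeric(t))
  if (k1 <= 0 || k2 <= 0) {
    stop("rate constants `k1` and `k2` must be positive", call. = FALSE)
  }
  if (nic0 <= 0) stop("`nic0` must be positive", call. = FALSE)
  if (t < 0) stop("residence time `t` must be nonnegative", call. = FALSE)
  structure(list(k1 = as.numeric(k1), k2 = as.numeric(k2),
                 nic0 = as.numeric(nic0), t = as.numeric(t)),
            class = "consecutive_model")
}

#' @export
print.consecutive_model <- function(x, ...) {
  cat("Consecutive reaction model  Nic -> I -> Product\n")
  cat(sprintf("  k1 = %.4g 1/s, k2 = %.4g 1/s\n", x$k1, x$k2))
  cat(sprintf("  [Nic]0 = %.3g counts, t = %.3g s\n", x$nic0, x$t))
  invisible(x)
}

check_nonneg_time <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time `t` must be finite and nonnegative", call. = FALSE)
  }
}

# relative switch to the equal-rate analytic limit; the naive intermediate
# formula divides by (k2 - k1)
EQUAL_RATE_TOL <- 1e-6

#' Nicotine concentration at time t
#'
#' \eqn{[\mathrm{Nic}](t) = [\mathrm{Nic}]_0 e^{-k_1 t}}.
#'
#' @param model a [consecutive_model()].
#' @param t time(s) in seconds; defaults to the model's residence time.
#' @return Concentration in counts.
#' @export
nic_at <- function(model, t = model$t) {
  stopifnot(inherits(model, "consecutive_model"))
  check_nonneg_time(t)
  model$nic0 * exp(-model$k1 * t)
}

#' Intermediate (pyridinyl radical) concentration at time t
#'
#' Analytic solution of the series mechanism for the intermediate:
#' \deqn{[I](t) = \frac{k_1 [\mathrm{Nic}]_0}{k_2 - k_1}
#'   \left(e^{-k_1 t} - e^{-k_2 t}\right),}
#' with the analytic limit \eqn{[\mathrm{Nic}]_0 k t e^{-kt}} used when the
#' two rate constants are equal to within a relative threshold of 1e-6.
#' This is how the unobservable radical concentration is inferred from the
#' two measurable rate constants.
#'
#' @inheritParams nic_at
#' @return Concentration in counts.
#' @examples
#' m <- consecutive_model(k1 = 1.11, k2 = 0.13, nic0 = 8.0e8)
#' intermediate_at(m)  # ~6.0e8 counts at t = 2 s
#' @export
intermediate_at <- function(model, t = model$t) {
  stopifnot(inherits(model, "consecutive_model"))
  check_nonneg_time(t)
  k1 <- model$k1
  k2 <- model$k2
  if (abs(k1 - k2) <= EQUAL_RATE_TOL * max(k1, k2)) {
    k <- (k1 + k2) / 2
    return(model$nic0 * k * t * exp(-k * t))
  }
  k1 * model$nic0 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
}

#' Product (pyridine) concentration at time t
#'
#' Mass-conserving closed form for the final product of the series
#' mechanism:
#' \deqn{[\mathrm{Product}](t) = [\mathrm{Nic}]_0
#'   \left[1 + \frac{k_2 e^{-k_1 t} - k_1 e^{-k_2 t}}{k_1 - k_2}\right].}
#' It satisfies \eqn{[\mathrm{Product}](0) = 0}, is nondecreasing, tends to
#' \eqn{[\mathrm{Nic}]_0}, and together with [nic_at()] and
#' [intermediate_at()] conserves mass exactly. (A commonly printed variant
#' with an extra \eqn{k_1} factor inside the bracket violates the t = 0
#' boundary condition; the form used here is the standard one and is the one
#' whose \eqn{k_2 \ll k_1} limit gives [product_simplified()].)
#'
#' @inheritParams nic_at
#' @return Concentration in counts.
#' @export
product_at <- function(model, t = model$t) {
  stopifnot(inherits(model, "consecutive_model"))
  check_nonneg_time(t)
  k1 <- model$k1
  k2 <- model$k2
  if (abs(k1 - k2) <= EQUAL_RATE_TOL * max(k1, k2)) {
    k <- (k1 + k2) / 2
    return(model$nic0 * (1 - (1 + k * t) * exp(-k * t)))
  }
  model$nic0 * (1 + (k2 * exp(-k1 * t) - k1 * exp(-k2 * t)) / (k1 - k2))
}

#' Product concentration in the rate-determining-step limit
#'
#' When the second step is rate determining (\eqn{k_2 \ll k_1}) the product
#' solution reduces to \eqn{[\mathrm{Product}](t) =
#' [\mathrm{Nic}]_0 (1 - e^{-k_2 t})}; the fast first step makes the
#' \eqn{e^{-k_1 t}} term decay away.
#'
#' @inheritParams nic_at
#' @return Concentration in counts.
#' @export
product_simplified <- function(model, t = model$t) {
  stopifnot(inherits(model, "consecutive_model"))
  check_nonneg_time(t)
  model$nic0 * (1 - exp(-model$k2 * t))
}

#' Invert the simplified product solution for k2
#'
#' Solves \eqn{P = N_0 (1 - e^{-k_2 t})} for \eqn{k_2 =
#' -\ln(1 - P/N_0)/t}. Exact inverse of [product_simplified()].
#'
#' @param nic0 precursor amount, counts, > 0.
#' @param product_max observed maximum product amount, counts, in
#'   `[0, nic0)` — a product yield at or above the precursor amount cannot
#'   come from this mechanism and raises an error.
#' @param t reaction time, seconds, > 0.
#' @return Rate constant k2 in s^-1; zero iff `product_max == 0`.
#' @examples
#' invert_k2_from_product(8.0e8, 4.4e8, t = 2)  # ~0.40 1/s
#' @export
invert_k2_from_product <- function(nic0, product_max, t) {
  stopifnot(is.numeric(nic0), is.numeric(product_max), is.numeric(t))
  if (nic0 <= 0) stop("`nic0` must be positive", call. = FALSE)
  if (t <= 0) stop("`t` must be positive", call. = FALSE)
  if (product_max < 0) stop("`product_max` must be nonnegative", call. = FALSE)
  if (product_max >= nic0) {
    stop("`product_max` >= `nic0`: product yield exceeds its precursor",
         call. = FALSE)
  }
  -log(1 - product_max / nic0) / t
}

#' Time of maximum intermediate concentration
#'
#' Stationarity of the intermediate solution gives
#' \eqn{t_{max} = \ln(k_1/k_2)/(k_1 - k_2)} (symmetric in the two rate
#' constants); in the equal-rate limit \eqn{t_{max} = 1/k}.
#'
#' @param model a [consecutive_model()].
#' @return Time in seconds.
#' @export
time_of_max_intermediate <- function(model) {
  stopifnot(inherits(model, "consecutive_model"))
  k1 <- model$k1
  k2 <- model$k2
  if (abs(k1 - k2) <= EQUAL_RATE_TOL * max(k1, k2)) {
    return(2 / (k1 + k2))
  }
  log(k1 / k2) / (k1 - k2)
}

#' Numerically integrated species trajectory
#'
#' Integrates the coupled differential rate laws of the series mechanism
#' (d\[Nic\]/dt = -k1\[Nic\]; d\[I\]/dt = k1\[Nic\] - k2\[I\];
#' d\[Product\]/dt = k2\[I\]) from the initial state
#' (\[Nic\]0, 0, 0) with `deSolve::lsoda` at tight tolerances. Serves as an
#' independent numerical check on the closed-form solutions; the two routes
#' agree to better than 1e-6 relative.
#'
#' @param model a [consecutive_model()].
#' @param times ascending numeric grid of nonnegative times, seconds.
#' @return A data.frame of class `species_trajectory` with columns `time`,
#'   `nic`, `intermediate`, `product`.
#' @export
consecutive_trajectory <- function(model, times) {
  stopifnot(inherits(model, "consecutive_model"), is.numeric(times))
  if (length(times) < 2L) {
    stop("`times` must contain at least two points", call. = FALSE)
  }
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be a strictly ascending nonnegative grid",
         call. = FALSE)
  }
  rhs <- function(t, y, p) {
    list(c(-p$k1 * y[1],
           p$k1 * y[1] - p$k2 * y[2],
           p$k2 * y[2]))
  }
  y0 <- c(nic = model$nic0, intermediate = 0, product = 0)
  sol <- deSolve::lsoda(y0, times, rhs,
                        parms = list(k1 = model$k1, k2 = model$k2),
                        rtol = 1e-10, atol = model$nic0 * 1e-12)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  class(out) <- c("species_trajectory", "data.frame")
  out
}

#' Derived summary of the destruction model
#'
#' The headline quantities of the consecutive-model analysis: the inferred
#' intermediate concentration at the residence time, the ratio of the
#' original nicotine to the sum of intermediate and product (values below 1
#' indicate pyridine routes other than nicotine destruction), the
#' product-to-nicotine ratio, and the percentage of nicotine transferred
#' intact to the smoker, \eqn{100 (1 - P_{max}/N_0)}.
#'
#' @param model a [consecutive_model()].
#' @param product_max observed maximum product (pyridine) yield, counts,
#'   >= 0.
#' @return An object of class `derived_summary`: a list with fields
#'   `intermediate_at_t`, `product_max`, `ratio_nic_to_sum`,
#'   `ratio_product_to_nic`, `pct_transferred_intact`.
#' @examples
#' m <- consecutive_model(k1 = 1.11, k2 = 0.13, nic0 = 8.0e8)
#' derived_summary(m, product_max = 4.4e8)
#' @export
derived_summary <- function(model, product_max) {
  stopifnot(inherits(model, "consecutive_model"), is.numeric(product_max))
  if (product_max < 0) stop("`product_max` must be nonnegative", call. = FALSE)
  inter <- intermediate_at(model, model$t)
  denom <- inter + product_max
  if (denom <= 0) {
    stop("intermediate + product is zero: ratio undefined", call. = FALSE)
  }
  ratio_pn <- product_max / model$nic0
  structure(
    list(
      intermediate_at_t = inter,
      product_max = product_max,
      ratio_nic_to_sum = model$nic0 / denom,
      ratio_product_to_nic = ratio_pn,
      pct_transferred_intact = 100 * max(0, 1 - ratio_pn)
    ),
    class = "derived_summary"
  )
}

#' @export
print.derived_summary <- function(x, ...) {
  cat("Derived destruction summary\n")
  cat(sprintf("  intermediate at t      : %.3g counts\n", x$intermediate_at_t))
  cat(sprintf("  product maximum        : %.3g counts\n", x$product_max))
  cat(sprintf("  [Nic]0 / (I + product) : %.2f\n", x$ratio_nic_to_sum))
  cat(sprintf("  product / [Nic]0       : %.2f\n", x$ratio_product_to_nic))
  cat(sprintf("  transferred intact     : %.0f%%\n", x$pct_transferred_intact))
  invisible(x)
}
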