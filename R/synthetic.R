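#' Configuration for the synthetic yield-curve generator
#'
#' Describes a simulated pyrolysis experiment with known ground truth for
#' parameter-recovery studies. The generated curve is unimodal: below the
#' peak temperature the yield follows a saturating first-order formation
#' ramp (formation prevails); at the peak, formation and destruction
#' balance and the yield equals `y_scale` (the C0 convention); above the
#' peak the yield is the peak pool surviving first-order destruction,
#' \eqn{C_0 e^{-k_d(T) t}}, with \eqn{k_d} given by the destruction
#' Arrhenius parameters (destruction overwhelms formation).
#'
#' @param y_scale peak (precursor-pool) yield in GC-area counts; default
#'   8.0e8, the ES1 nicotine value.
#' @param formation_params [arrhenius_parameters()] of the formation rate
#'   constant controlling the sub-peak ramp. Default Ea = 60 kJ/mol with A
#'   chosen so the ramp rises visibly across 473-673 K.
#' @param destruction_params [arrhenius_parameters()] of the destruction
#'   rate constant; default the ES1 values (Ea = 108.85 kJ/mol,
#'   A = 2.1e6 1/s).
#' @param peak_temperature nominal peak position in kelvin; snapped to the
#'   nearest grid temperature. Default 673 K (~400 degC, where ES1
#'   nicotine peaks).
#' @param temperatures kelvin grid, at least 3 strictly increasing values;
#'   default 473-973 K in 50 K steps, mirroring a 200-700 degC sweep.
#' @param residence_time reaction time in seconds; default 2.0.
#' @param noise_sd relative standard deviation of multiplicative lognormal
#'   noise (median 1); default 0.02. GC-area counts are positive and
#'   heteroscedastic, which multiplicative noise reproduces and additive
#'   noise does not.
#' @param seed integer RNG seed; mandatory whenever `noise_sd > 0`
#'   (default 1, so noisy configurations are reproducible out of the box;
#'   pass `NULL` only for noise-free curves).
#' @param replicates number of replicate curves the configuration is meant
#'   to produce; each replicate uses the documented sub-seed
#'   `seed + 7919 * (replicate - 1)`.
#' @param sample_id,analyte labels carried into the generated series.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_yield_curve()], [fixture_es1()], [fixture_sm1()]
#' @export
synthetic_config <- function(y_scale = 8.0e8,
                             formation_params = arrhenius_parameters(
                               Ea = 60000, A = 4.5e4),
                             destruction_params = arrhenius_parameters(
                               Ea = 108850, A = 2.1e6),
                             peak_temperature = 673,
                             temperatures = seq(473, 973, by = 50),
                             residence_time = 2.0,
                             noise_sd = 0.02,
                             seed = 1L,
                             replicates = 1L,
                             sample_id = "synthetic",
                             analyte = "nicotine") {
  stopifnot(inherits(formation_params, "arrhenius_parameters"),
            inherits(destruction_params, "arrhenius_parameters"))
  if (!is.numeric(y_scale) || y_scale <= 0) {
    stop("`y_scale` must be positive", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be nonnegative", call. = FALSE)
  }
  if (length(temperatures) < 3L ||
      is.unsorted(temperatures, strictly = TRUE) || any(temperatures <= 0)) {
    stop("`temperatures` must be >= 3 strictly increasing kelvin values",
         call. = FALSE)
  }
  if (residence_time <= 0) {
    stop("`residence_time` must be positive", call. = FALSE)
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("a `seed` is mandatory when `noise_sd` > 0", call. = FALSE)
  }
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  peak_temperature <-
    temperatures[which.min(abs(temperatures - peak_temperature))]
  structure(
    list(y_scale = as.numeric(y_scale),
         formation_params = formation_params,
         destruction_params = destruction_params,
         peak_temperature = as.numeric(peak_temperature),
         temperatures = as.numeric(temperatures),
         residence_time = as.numeric(residence_time),
         noise_sd = as.numeric(noise_sd),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         replicates = as.integer(replicates),
         sample_id = as.character(sample_id),
         analyte = as.character(analyte)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic pyrolysis config: %s / %s\n", x$sample_id, x$analyte))
  cat(sprintf("  y_scale %.3g counts, peak at %g K, grid %g-%g K (%d pts)\n",
              x$y_scale, x$peak_temperature, min(x$temperatures),
              max(x$temperatures), length(x$temperatures)))
  cat(sprintf("  destruction Ea = %.2f kJ/mol, A = %.3g 1/s\n",
              x$destruction_params$Ea / 1000, x$destruction_params$A))
  cat(sprintf("  t = %g s, noise_sd = %g, seed = %s\n", x$residence_time,
              x$noise_sd, if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

lognormal_noise <- function(n, noise_sd, seed) {
  # median-1 multiplicative noise whose relative sd equals noise_sd
  sdlog <- sqrt(log1p(noise_sd^2))
  withr::with_seed(seed, exp(stats::rnorm(n, mean = 0, sd = sdlog)))
}

replicate_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) + 7919 * (replicate - 1)) %% 2147483647)
}

#' Generate a synthetic temperature-yield curve
#'
#' Produces one unimodal yield curve from a [synthetic_config()] (see that
#' help page for the curve's functional form), optionally multiplied by
#' seeded lognormal noise. Deterministic given the configuration seed and
#' replicate index. The generating parameters are attached as the `truth`
#' attribute so recovery tests can compare against ground truth.
#'
#' @param config a [synthetic_config()].
#' @param replicate replicate index, >= 1; perturbs the seed by the
#'   documented sub-seed rule.
#' @return A [temperature_yield_series()] with a `truth` attribute.
#' @examples
#' curve <- generate_yield_curve(fixture_es1(noise_sd = 0))
#' run_destruction_analysis(curve)$arrhenius
#' @export
generate_yield_curve <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (replicate < 1L || replicate > config$replicates) {
    stop("`replicate` must lie in 1..config$replicates", call. = FALSE)
  }
  temps <- config$temperatures
  t_res <- config$residence_time
  kf <- arrhenius_k(config$formation_params, temps)
  kd <- arrhenius_k(config$destruction_params, temps)
  kf_peak <- arrhenius_k(config$formation_params, config$peak_temperature)
  ramp <- (1 - exp(-kf * t_res)) / (1 - exp(-kf_peak * t_res))
  survival <- exp(-kd * t_res)
  y <- config$y_scale * ifelse(temps <= config$peak_temperature,
                               ramp, survival)
  if (config$noise_sd > 0) {
    y <- y * lognormal_noise(length(y), config$noise_sd,
                             replicate_seed(config$seed, replicate))
  }
  series <- temperature_yield_series(
    temps, y,
    sample_id = config$sample_id,
    analyte = config$analyte,
    residence_time = t_res
  )
  attr(series, "truth") <- list(
    y_scale = config$y_scale,
    formation_params = config$formation_params,
    destruction_params = config$destruction_params,
    peak_temperature = config$peak_temperature,
    noise_sd = config$noise_sd,
    seed = config$seed,
    replicate = as.integer(replicate)
  )
  series
}

#' Generate a synthetic puff-time series
#'
#' First-order decay with puff time, \eqn{y(t) = N_0 e^{-kt}}, with
#' optional seeded multiplicative lognormal noise — the structure the
#' formation pipeline assumes.
#'
#' @param n0 initial amount, counts, > 0.
#' @param k formation rate constant, s^-1, >= 0.
#' @param puff_times puff durations in seconds; default the experimental
#'   2, 5 and 10 s.
#' @param noise_sd relative sd of multiplicative lognormal noise; default 0.
#' @param seed integer seed, mandatory when `noise_sd > 0`.
#' @return A [puff_series()].
#' @export
generate_puff_series <- function(n0, k, puff_times = c(2, 5, 10),
                                 noise_sd = 0, seed = NULL) {
  if (!is.numeric(n0) || n0 <= 0) stop("`n0` must be positive", call. = FALSE)
  if (!is.numeric(k) || k < 0) stop("`k` must be nonnegative", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a `seed` is mandatory when `noise_sd` > 0", call. = FALSE)
  }
  y <- first_order_concentration(n0, k, puff_times)
  if (noise_sd > 0) {
    y <- y * lognormal_noise(length(y), noise_sd, as.integer(seed))
  }
  puff_series(puff_times, y)
}

#' ES1-like synthetic configuration
#'
#' Configuration whose destruction Arrhenius parameters equal the ES1
#' values (Ea = 108.85 kJ/mol, A = 2.1e6 1/s), with the ES1 peak pool of
#' 8.0e8 counts and the nicotine peak at 673 K (~400 degC).
#'
#' @param ... overrides passed on to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
fixture_es1 <- function(...) {
  args <- list(
    y_scale = 8.0e8,
    destruction_params = arrhenius_parameters(Ea = 108850, A = 2.1e6),
    peak_temperature = 673,
    sample_id = "ES1"
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

#' SM1-like synthetic configuration
#'
#' Configuration with the SM1 destruction parameters (Ea = 136.52 kJ/mol,
#' A = 3.0e7 1/s) and the SM1 nicotine peak at 773 K (~500 degC). SM1's
#' own peak pool is never reported; one tenth of the ES1 pool is used,
#' matching the ~10-fold nicotine difference between the two cigarettes —
#' an approximation, flagged as such.
#'
#' @param ... overrides passed on to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
fixture_sm1 <- function(...) {
  args <- list(
    y_scale = 8.0e7,
    destruction_params = arrhenius_parameters(Ea = 136520, A = 3.0e7),
    peak_temperature = 773,
    sample_id = "SM1"
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}
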