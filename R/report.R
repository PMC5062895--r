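REPORT_SCHEMA_VERSION <- "1.0"

destruction_to_report <- function(x) {
  list(
    sample_id = x$sample_id,
    analyte = x$analyte,
    peak = list(temperature_K = x$peak_temperature, yield = x$c0),
    c0 = x$c0,
    rate_constants = data.frame(temperature_K = x$rate_constants$temperature,
                                k_per_s = x$rate_constants$k),
    arrhenius = list(Ea_kJ_per_mol = x$arrhenius$Ea / 1000,
                     A_per_s = x$arrhenius$A,
                     r_squared = x$arrhenius$r_squared,
                     n_points = x$arrhenius$n_points),
    exponents = data.frame(temperature_K = x$exponents$temperature,
                           n = x$exponents$n),
    k_average = x$k_average,
    excluded_points = x$excluded_points,
    residence_time_s = x$residence_time
  )
}

#' Build the consolidated report list
#'
#' Assembles destruction results (and optionally a formation fit and a
#' consecutive-model derived summary) into the versioned report structure
#' serialized by [write_report()].
#'
#' @param results a `destruction_result` or a list of them; may be empty
#'   only if `formation` or `summary` is supplied.
#' @param formation optional [fit_formation()] result.
#' @param summary optional [derived_summary()] result.
#' @return A list with `schema_version`, `samples`, and optional
#'   `formation` and `derived_summary` entries.
#' @export
build_report <- function(results = list(), formation = NULL, summary = NULL) {
  if (inherits(results, "destruction_result")) results <- list(results)
  stopifnot(is.list(results))
  if (!all(vapply(results, inherits, logical(1), "destruction_result"))) {
    stop("`results` must contain only destruction_result objects",
         call. = FALSE)
  }
  if (length(results) == 0 && is.null(formation) && is.null(summary)) {
    stop("refusing to write an empty report", call. = FALSE)
  }
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    samples = lapply(results, destruction_to_report)
  )
  if (!is.null(formation)) {
    stopifnot(inherits(formation, "formation_fit"))
    report$formation <- list(
      slope_per_s = formation$slope,
      intercept_ln_counts = formation$intercept,
      k_formation_per_s = formation$k_formation,
      initial_amount = formation$initial_amount,
      r_squared = formation$r_squared,
      n_points = formation$n_points,
      non_decaying = formation$non_decaying
    )
  }
  if (!is.null(summary)) {
    stopifnot(inherits(summary, "derived_summary"))
    report$derived_summary <- unclass(summary)
  }
  report
}

#' Render the markdown report
#'
#' Human-readable companion to the JSON report, with a per-cigarette
#' Arrhenius-parameter table (label, Ea in kJ/mol to 2 decimals, A in 1/s
#' to 2 significant figures). Deterministic: the same report list always
#' renders byte-identically.
#'
#' @param report a report list from [build_report()] or parsed back from a
#'   report JSON with `jsonlite::read_json(..., simplifyVector = TRUE)`.
#' @return Character vector of markdown lines.
#' @export
format_report_markdown <- function(report) {
  stopifnot(is.list(report))
  lines <- c("# Nicotine kinetics report", "")
  samples <- report$samples
  if (!is.null(samples) && length(samples)) {
    # read_json(simplifyVector=TRUE) may turn the sample list into a df
    if (is.data.frame(samples)) {
      samples <- lapply(seq_len(nrow(samples)),
                        function(i) as.list(samples[i, ]))
    }
    lines <- c(lines, "## Arrhenius parameters (destruction)", "",
               "Cigarette | Ea (kJ/mol) | A (1/s)",
               "--- | --- | ---")
    for (s in samples) {
      arr <- as.list(s$arrhenius)
      lines <- c(lines, sprintf("%s | %.2f | %.1e", s$sample_id,
                                as.numeric(arr$Ea_kJ_per_mol),
                                as.numeric(arr$A_per_s)))
    }
    lines <- c(lines, "")
    for (s in samples) {
      arr <- as.list(s$arrhenius)
      lines <- c(lines, sprintf(
        "- %s: peak C0 = %.2e counts at %.4g K; average k = %.4g 1/s; r^2 = %.6f",
        s$sample_id, as.numeric(s$c0),
        as.numeric(as.list(s$peak)$temperature_K),
        as.numeric(s$k_average), as.numeric(arr$r_squared)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$formation)) {
    f <- report$formation
    lines <- c(lines, "## Formation kinetics", "",
               sprintf("- slope = %.4f 1/s; k_formation = %.2f 1/s",
                       as.numeric(f$slope_per_s),
                       as.numeric(f$k_formation_per_s)),
               sprintf("- initial amount (zero-puff intercept) = %.2e counts",
                       as.numeric(f$initial_amount)),
               sprintf("- r^2 = %.6f", as.numeric(f$r_squared)), "")
  }
  if (!is.null(report$derived_summary)) {
    d <- report$derived_summary
    lines <- c(lines, "## Consecutive-model summary", "",
               sprintf("- intermediate at t = %.2e counts",
                       as.numeric(d$intermediate_at_t)),
               sprintf("- [Nic]0 / (I + product) = %.2f",
                       as.numeric(d$ratio_nic_to_sum)),
               sprintf("- product / [Nic]0 = %.2f",
                       as.numeric(d$ratio_product_to_nic)),
               sprintf("- transferred intact = %.0f%%",
                       as.numeric(d$pct_transferred_intact)), "")
  }
  lines
}

#' Write the consolidated JSON (and optional markdown) report
#'
#' Serializes analysis results to a versioned JSON report; numbers are
#' written at full internal precision (rounding happens only in the
#' markdown layer). Output is byte-stable for identical inputs.
#'
#' @inheritParams build_report
#' @param path output path for the JSON report.
#' @param markdown_path optional output path for the markdown rendering.
#' @return The report list, invisibly.
#' @export
write_report <- function(results, path, markdown_path = NULL,
                         formation = NULL, summary = NULL) {
  report <- build_report(results, formation = formation, summary = summary)
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = 2)
  writeLines(json, path)
  if (!is.null(markdown_path)) {
    writeLines(format_report_markdown(report), markdown_path)
  }
  invisible(report)
}
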