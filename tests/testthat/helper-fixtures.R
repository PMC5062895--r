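# shared fixture helpers; all data built in code

es1_model <- function() consecutive_model(k1 = 1.11, k2 = 0.13, nic0 = 8.0e8,
                                          t = 2.0)

es1_params <- function() arrhenius_parameters(Ea = 108850, A = 2.1e6)
sm1_params <- function() arrhenius_parameters(Ea = 136520, A = 3.0e7)

# noise-free Arrhenius-exact rate table on a kelvin grid
exact_rate_table <- function(params, temps = seq(673, 973, by = 50)) {
  rate_constant_table(temps, arrhenius_k(params, temps))
}

tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
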