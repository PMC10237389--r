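# Shared fixtures for the test suite. Everything is built in code; nothing
# is read from disk except the shipped protocol configs under inst/extdata.

fitted <- nfkb_params("fitted")
onoff <- make_on_off()

# Limit-cycle and feedback-variant parameter sets used across tests
params_limit_cycle <- nfkb_params("fitted", a2 = 0.02, c5a = 1e-5, i1a = 1e-4)
params_spiky <- nfkb_params("fitted", a2 = 0.01, c5a = 1e-5, i1a = 1e-4)
params_no_a20 <- nfkb_params("fitted", k2 = 0)
params_adaptation <- nfkb_params("fitted", k2 = 3.57, i1a = 0.01)

# Build a measurement-set data.frame directly (bypassing simulation) for
# formula-level tests of the objective and AMD.
manual_measurements <- function(values, normalized = TRUE,
                                observable = "NFkBn", genotype = "WT",
                                protocol = "manual") {
  df <- data.frame(protocol = protocol, genotype = genotype,
                   observable = observable,
                   time_min = seq_along(values), value = values)
  structure(df, class = c("nfkb_measurements", "data.frame"),
            normalized = normalized)
}

# Random parameter sets within a fold-range of the fitted values
random_params <- function(fold = 3) {
  f <- exp(runif(13, -log(fold), log(fold)))
  as_nfkb_params(setNames(unclass(fitted) * f, nfkb_param_names))
}
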