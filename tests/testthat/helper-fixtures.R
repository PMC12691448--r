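# Shared fixtures: prebuilt parameter sets and arms so tests do not pay
# tibble-construction costs repeatedly.
bp0 <- base_params()
ep0 <- epsilon_params()
arms0 <- standard_arms("EMT6")
obs_days <- c(0, 5, 10, 15, 20, 25)

# published per-arm residual sums of squares of the EMT6 comparison table,
# shipped as package data (inputs to the AIC arithmetic)
emt6_table <- utils::read.csv(
  system.file("extdata", "emt6_model_comparison.csv", package = "pdl1dyn"))

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
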