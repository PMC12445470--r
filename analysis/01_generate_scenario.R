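#!/usr/bin/env Rscript
# Generate the default synthetic scenario: 12 regions, baseline pyramids at
# 2023, crude vital-rate histories 2000-2023, per-stage rural-concentration
# histories. Writes the CSV input bundle consumed by the later steps.

library(schooldemand)

out_dir <- "results/scenario_inputs"
spec <- scenario_spec(seed = 1)
bundle <- generate_scenario(spec, dir = out_dir)

cat("Scenario written to", out_dir, "\n")
cat(sprintf(
  "%d regions, baseline year %d, history %d-%d\n",
  spec$n_regions, spec$baseline_year,
  min(spec$history_years), max(spec$history_years)
))
for (region in names(bundle$populations)[c(1, 12)]) {
  pop <- bundle$populations[[region]]
  cat(sprintf(
    "  %s: %.2f million women aged 0-49, mean age %.1f\n",
    region, sum(pop$counts) / 1e6,
    sum((pop$ages + 0.5) * pop$counts) / sum(pop$counts)
  ))
}
cat(sprintf(
  "Birth rate history (region_01): %.2f per mille in %d -> %.2f in %d\n",
  bundle$vitals[[1]]$birth$value[1], min(spec$history_years),
  tail(bundle$vitals[[1]]$birth$value, 1), max(spec$history_years)
))
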