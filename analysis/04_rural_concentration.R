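#!/usr/bin/env Rscript
# Estimate each stage's average annual decline in rural share from the
# 2000-2023 history (endpoint method) and extrapolate the share linearly
# over 2024-2040, clamped to [0, 100].

library(schooldemand)
suppressPackageStartupMessages(library(dplyr))

bundle <- read_scenario("results/scenario_inputs")

conc <- bind_rows(lapply(names(bundle$concentration), function(stage) {
  hist <- bundle$concentration[[stage]]
  decline <- fit_annual_decline(hist)
  last_year <- max(hist$year)
  start <- hist$value[hist$year == last_year] - decline * (2024 - last_year)
  cs <- extrapolate_concentration(2024, min(100, max(0, start)), decline, 2040, stage = stage)
  cat(sprintf(
    "%-9s: decline %.3f pp/yr, share %.2f%% (2024) -> %.2f%% (2040)\n",
    stage, decline, cs$rural_share[1], cs$rural_share[17]
  ))
  tibble::tibble(stage = stage, year = cs$year, rural_share = cs$rural_share)
}))
write.csv(conc, "results/rural_concentration.csv", row.names = FALSE)
cat("Wrote results/rural_concentration.csv\n")
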