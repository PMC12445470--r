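# Vital-rate time series: fitting, extrapolation, baseline calibration.
#
# Crude birth and death rates (per mille) are observed annually over a
# historical window and extrapolated forward with an ordinary least-squares
# line on calendar year, floored at zero. Enrollment rates are forecast with
# Holt linear exponential smoothing and capped (the cap binds in practice:
# compulsory-education enrollment is assumed 100%).

VALID_KINDS <- c("birth", "death", "enrollment", "concentration")

#' Annual rate series
#'
#' An observed time series of a demographic or schooling rate for one
#' region. Vital rates (`birth`, `death`) are in per mille (per 1,000
#' persons per year); `enrollment` and `concentration` are percentages.
#'
#' @param region region label.
#' @param kind one of `"birth"`, `"death"`, `"enrollment"`, `"concentration"`.
#' @param years strictly increasing integer years, no duplicates.
#' @param values non-negative rates, same length as `years`. Percent-valued
#'   kinds must not exceed `ceiling` (a sanity bound applied before any
#'   capping; net enrollment ratios can legitimately exceed 100).
#' @param ceiling upper sanity bound for percent-valued kinds (default 110).
#' @return a tibble of class `rate_series` with columns `year`, `value` and
#'   attributes `region`, `kind`.
#' @export
rate_series <- function(region, kind, years, values, ceiling = 110) {
  kind <- match.arg(kind, VALID_KINDS)
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) != length(values)) {
    stop_dimension("`years` and `values` must have equal length")
  }
  if (length(years) > 1 && any(diff(years) <= 0)) {
    stop_validation("`years` must be strictly increasing with no duplicates")
  }
  if (anyNA(values) || any(values < 0)) {
    stop_validation("rate values must be non-negative")
  }
  if (kind %in% c("enrollment", "concentration") && any(values > ceiling)) {
    stop_validation(sprintf("%s values exceed the sanity ceiling of %g%%", kind, ceiling))
  }
  structure(
    tibble::tibble(year = years, value = values),
    region = region, kind = kind,
    class = c("rate_series", class(tibble::tibble()))
  )
}

#' Ordinary least-squares trend of a rate series
#'
#' Fits value on calendar year by OLS over a fit window. The residual
#' standard deviation is the usual unbiased estimate (0 when the window
#' holds exactly two points, which the line interpolates).
#'
#' @param series a [rate_series()].
#' @param window length-2 numeric `c(first_year, last_year)` delimiting the
#'   observations used; `NULL` (default) uses all of them.
#' @return an object of class `trend_fit` with fields `slope` (units/yr),
#'   `intercept` (value at calendar year 0), `fit_window`, `residual_sd`,
#'   `n_obs`, `region`, `kind`.
#' @export
fit_linear_trend <- function(series, window = NULL) {
  stopifnot(inherits(series, "rate_series"))
  dat <- series
  if (!is.null(window)) {
    dat <- dat[dat$year >= window[1] & dat$year <= window[2], ]
  }
  if (nrow(dat) < 2) {
    stop_insufficient("need at least 2 observations in the fit window")
  }
  if (stats::var(dat$year) == 0) {
    stop_validation("zero variance in year: degenerate design")
  }
  fit <- stats::lm(value ~ year, data = dat)
  res <- stats::residuals(fit)
  structure(
    list(
      slope = unname(coef(fit)[["year"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      fit_window = c(min(dat$year), max(dat$year)),
      residual_sd = if (nrow(dat) == 2) 0 else sqrt(sum(res^2) / (nrow(dat) - 2)),
      n_obs = nrow(dat),
      region = attr(series, "region"),
      kind = attr(series, "kind")
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> %s/%s: slope %.4f per yr over %d-%d (n=%d, resid sd %.4f)\n",
    x$region %||% "?", x$kind %||% "?", x$slope,
    x$fit_window[1], x$fit_window[2], x$n_obs, x$residual_sd
  ))
  invisible(x)
}

#' Extrapolate a fitted trend
#'
#' Evaluates the OLS line at future years and floors negative values at
#' zero (a crude rate cannot be negative). Floored years are flagged.
#'
#' @param fit a `trend_fit`.
#' @param years forecast years, each `>=` the end of the fit window.
#' @return a [rate_series()]-shaped tibble with columns `year`, `value`,
#'   `clamped` (logical: TRUE where the line was below 0).
#' @export
forecast_rate <- function(fit, years) {
  stopifnot(inherits(fit, "trend_fit"))
  years <- as.integer(years)
  if (any(years < fit$fit_window[2])) {
    stop_range("forecast years must not precede the end of the fit window")
  }
  raw <- fit$intercept + fit$slope * years
  out <- tibble::tibble(year = years, value = pmax(0, raw), clamped = raw < 0)
  structure(out,
    region = fit$region, kind = fit$kind,
    class = c("rate_series", class(tibble::tibble()))
  )
}

# Holt linear (additive-trend) exponential smoothing.
# Initialization: level = y1, trend = y2 - y1; recursion from t = 2:
#   l_t = alpha*y_t + (1-alpha)*(l_{t-1} + b_{t-1})
#   b_t = beta*(l_t - l_{t-1}) + (1-beta)*b_{t-1}
holt_filter <- function(y, alpha, beta) {
  n <- length(y)
  level <- y[1]
  trend <- y[2] - y[1]
  fitted <- rep(NA_real_, n)
  if (n >= 2) {
    for (t in 2:n) {
      fitted[t] <- level + trend
      new_level <- alpha * y[t] + (1 - alpha) * (level + trend)
      trend <- beta * (new_level - level) + (1 - beta) * trend
      level <- new_level
    }
  }
  list(level = level, trend = trend, fitted = fitted)
}

#' Forecast an enrollment rate by exponential smoothing
#'
#' Holt linear exponential smoothing with additive trend, followed by a hard
#' cap: a net enrollment rate used by the pipeline cannot exceed 100%.
#' Smoothing parameters are chosen by least squares on the one-step-ahead
#' in-sample errors unless given explicitly.
#'
#' @param series a [rate_series()] of kind `"enrollment"` with at least 3
#'   observations.
#' @param years forecast years (after the last observation).
#' @param cap percentage cap applied after forecasting (default 100).
#' @param alpha,beta Holt smoothing parameters in `[0, 1]`; `NULL` (default)
#'   selects them by minimizing in-sample squared one-step errors, falling
#'   back to `alpha = 0.5, beta = 0.1` if optimization fails.
#' @return tibble with columns `year`, `value` (capped), `uncapped`.
#' @export
forecast_enrollment <- function(series, years, cap = 100, alpha = NULL, beta = NULL) {
  stopifnot(inherits(series, "rate_series"))
  y <- series$value
  if (length(y) < 3) {
    stop_insufficient("need at least 3 observations for exponential smoothing")
  }
  years <- as.integer(years)
  if (is.null(alpha) || is.null(beta)) {
    sse <- function(p) {
      f <- holt_filter(y, p[1], p[2])
      sum((y - f$fitted)^2, na.rm = TRUE)
    }
    opt <- tryCatch(
      stats::optim(c(0.5, 0.1), sse,
        method = "L-BFGS-B",
        lower = c(1e-4, 1e-4), upper = c(1, 1)
      ),
      error = function(e) NULL
    )
    par <- if (is.null(opt)) c(0.5, 0.1) else opt$par
    alpha <- alpha %||% par[1]
    beta <- beta %||% par[2]
  }
  f <- holt_filter(y, alpha, beta)
  h <- years - series$year[length(y)]
  if (any(h < 1)) stop_range("forecast years must follow the last observation")
  raw <- f$level + h * f$trend
  tibble::tibble(year = years, value = pmin(raw, cap), uncapped = raw)
}

#' Calibrate a baseline age vector to an official total
#'
#' Regional census age structures and yearbook totals refer to different
#' reference dates; the baseline is reconciled by fitting a linear trend to
#' a window of recorded totals, extrapolating it to the baseline year, and
#' rescaling the whole age vector proportionally to match.
#'
#' @param pop a [female_age_vector()] at the baseline year.
#' @param totals a [rate_series()]-shaped tibble of recorded totals
#'   (column `value`, same unit as `sum(pop$counts)`), or any tibble with
#'   `year`/`value` columns wrapped via [rate_series()].
#' @param window fit window passed to [fit_linear_trend()] (e.g. 2010-2022).
#' @return the rescaled [female_age_vector()]; attribute `scale_factor`
#'   records the applied ratio.
#' @export
calibrate_baseline <- function(pop, totals, window = NULL) {
  stopifnot(inherits(pop, "female_age_vector"))
  fit <- fit_linear_trend(totals, window = window)
  target <- fit$intercept + fit$slope * pop$year
  if (target <= 0) stop_validation("extrapolated baseline total is non-positive")
  current <- sum(pop$counts)
  if (current <= 0) stop_validation("baseline vector has zero total")
  out <- female_age_vector(pop$counts * (target / current), pop$year)
  attr(out, "scale_factor") <- target / current
  out
}
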