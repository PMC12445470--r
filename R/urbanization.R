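# Rural-concentration (educational urbanization) model.
#
# The rural share of a stage's enrollment declines roughly linearly as
# students concentrate in urban schools. The average annual decline is
# estimated from the historical endpoints and extrapolated forward in
# percentage points per year, clamped to [0, 100].

#' Average annual decline of a rural-share series
#'
#' Endpoint estimator: `(first value - last value) / (last year - first
#' year)`, in percentage points per year. Positive means a declining rural
#' share.
#'
#' @param history a [rate_series()] (kind `"concentration"`) or any tibble
#'   with `year` and `value` columns, at least 2 rows.
#' @return decline in percentage points per year (scalar).
#' @export
fit_annual_decline <- function(history) {
  if (nrow(history) < 2) {
    stop_insufficient("need at least 2 observations to estimate a decline")
  }
  first <- which.min(history$year)
  last <- which.max(history$year)
  (history$value[first] - history$value[last]) /
    (history$year[last] - history$year[first])
}

#' Extrapolate a rural-concentration series
#'
#' Linear decline from a starting share, clamped to `[0, 100]`:
#' `share(y) = clamp(start_share - annual_decline * (y - start_year))`.
#' Alternatively a fully specified per-year `schedule` may be supplied for
#' stages whose printed series is not exactly linear.
#'
#' @param start_year first projected year.
#' @param start_share rural share in `start_year`, percent in `[0, 100]`.
#' @param annual_decline decline in percentage points per year (positive =
#'   share falls).
#' @param end_year last projected year, `>= start_year`.
#' @param stage optional stage label attached to the result.
#' @param schedule optional tibble (`year`, `rural_share`) overriding the
#'   linear rule entirely.
#' @return tibble of class `concentration_series` with columns `year`,
#'   `rural_share`.
#' @export
extrapolate_concentration <- function(start_year, start_share, annual_decline,
                                      end_year, stage = NULL, schedule = NULL) {
  if (!is.null(schedule)) {
    if (any(schedule$rural_share < 0 | schedule$rural_share > 100)) {
      stop_validation("schedule shares must lie in [0, 100]")
    }
    out <- tibble::tibble(
      year = as.integer(schedule$year),
      rural_share = as.numeric(schedule$rural_share)
    )
  } else {
    if (start_share < 0 || start_share > 100) {
      stop_validation("`start_share` must lie in [0, 100]")
    }
    if (end_year < start_year) {
      stop_range("`end_year` must not precede `start_year`")
    }
    years <- as.integer(start_year):as.integer(end_year)
    share <- start_share - annual_decline * (years - as.integer(start_year))
    out <- tibble::tibble(year = years, rural_share = pmin(100, pmax(0, share)))
  }
  structure(out,
    stage = stage,
    class = c("concentration_series", class(tibble::tibble()))
  )
}

#' Split a stage total into rural and urban students
#'
#' @param stage_total total students (scalar or vector).
#' @param rural_share rural share in percent, `[0, 100]`, recycled against
#'   `stage_total`.
#' @return tibble with columns `rural`, `urban`; `rural + urban` equals the
#'   input total exactly.
#' @export
rural_students <- function(stage_total, rural_share) {
  if (any(rural_share < 0 | rural_share > 100)) {
    stop_validation("`rural_share` must lie in [0, 100]")
  }
  if (any(stage_total < 0)) stop_validation("`stage_total` must be non-negative")
  rural <- stage_total * rural_share / 100
  tibble::tibble(rural = rural, urban = stage_total - rural)
}
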