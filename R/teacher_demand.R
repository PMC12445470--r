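# Teacher demand from staffing ratios, and decline summaries.

#' Staffing standard (students per full-time teacher)
#'
#' National staffing norms: 1 teacher per 19 primary students, per 13.5
#' junior-high students, and per 12 preschool children (full-time
#' kindergarten teachers).
#'
#' @param preschool,primary,junior students per teacher, all positive.
#' @return named list of class `staffing_standard`.
#' @export
staffing_standard <- function(preschool = 12, primary = 19, junior = 13.5) {
  ratios <- c(preschool = preschool, primary = primary, junior = junior)
  if (any(ratios <= 0)) stop_validation("staffing ratios must be positive")
  structure(as.list(ratios), class = "staffing_standard")
}

#' Full-time teachers required for a student body
#'
#' `teachers = students / students_per_teacher(stage)`; real-valued, the
#' reporting layer rounds.
#'
#' @param students student count (scalar or vector), non-negative.
#' @param standard a [staffing_standard()].
#' @param stage stage name present in `standard`.
#' @return required full-time-equivalent teachers.
#' @export
teachers_required <- function(students, standard, stage) {
  stopifnot(inherits(standard, "staffing_standard"))
  if (!stage %in% names(standard)) {
    stop_config(sprintf("unknown stage '%s' in staffing standard", stage))
  }
  if (any(students < 0)) stop_validation("`students` must be non-negative")
  students / standard[[stage]]
}

#' Relative decline between two endpoint values
#'
#' `(v_start - v_end) / v_start * 100`, rounded half away from zero.
#' Negative results indicate growth.
#'
#' @param v_start starting value, strictly positive.
#' @param v_end ending value.
#' @param digits decimal places of the rounded percent (default 1; use 0
#'   for the integer variant).
#' @return percent decline.
#' @export
relative_decline <- function(v_start, v_end, digits = 1) {
  if (any(v_start <= 0)) stop_validation("`v_start` must be strictly positive")
  round_half_away((v_start - v_end) / v_start * 100, digits)
}

#' Summarize declines between two years of a demand table
#'
#' Applies [relative_decline()] region- and stage-wise between two years of
#' a long-format table.
#'
#' @param table tibble with columns `region`, `stage`, `year`, `value`
#'   (teachers or students).
#' @param y0,y1 start and end years, both present in `table`.
#' @param digits decimal places for the percent (default 1).
#' @return tibble (`region`, `stage`, `value_start`, `value_end`,
#'   `decline_pct`).
#' @export
demand_summary <- function(table, y0, y1, digits = 1) {
  if (!all(c(y0, y1) %in% table$year)) {
    stop_range("both summary years must be present in the table")
  }
  wide <- dplyr::inner_join(
    dplyr::rename(dplyr::filter(table, .data$year == y0), value_start = "value"),
    dplyr::rename(dplyr::filter(table, .data$year == y1), value_end = "value"),
    by = c("region", "stage")
  )
  tibble::tibble(
    region = wide$region,
    stage = wide$stage,
    value_start = wide$value_start,
    value_end = wide$value_end,
    decline_pct = relative_decline(wide$value_start, wide$value_end, digits)
  )
}
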