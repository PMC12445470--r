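# Grade-progression enrollment accounting.
#
# Grades are labelled by age: the grade "represented as" age a holds the
# mean of the populations aged a and a+1 (children in one school grade span
# two birth years). Stage label sets follow the reporting convention:
# preschool 3-5, primary 6-11, junior high 12-14 (the label means ages
# a and a+1, so label 14 covers ages 14-15).

#' Education stage definition
#'
#' @param name one of `"preschool"`, `"primary"`, `"junior"`.
#' @param entry_age first grade label (defaults: preschool 3, primary 6,
#'   junior 12).
#' @param n_grades number of grades (defaults: 3, 6, 3).
#' @return an object of class `stage_definition` with a `labels` field: the
#'   grade age-labels `entry_age .. entry_age + n_grades - 1`.
#' @export
stage_definition <- function(name = c("preschool", "primary", "junior"),
                             entry_age = NULL, n_grades = NULL) {
  name <- match.arg(name)
  defaults <- list(
    preschool = list(entry_age = 3L, n_grades = 3L),
    primary = list(entry_age = 6L, n_grades = 6L),
    junior = list(entry_age = 12L, n_grades = 3L)
  )[[name]]
  entry_age <- as.integer(entry_age %||% defaults$entry_age)
  n_grades <- as.integer(n_grades %||% defaults$n_grades)
  if (n_grades < 1) stop_validation("`n_grades` must be at least 1")
  structure(
    list(
      name = name, entry_age = entry_age, n_grades = n_grades,
      labels = entry_age + 0:(n_grades - 1L)
    ),
    class = "stage_definition"
  )
}

#' The three default education stages
#' @return named list of [stage_definition()]s.
#' @export
default_stages <- function() {
  list(
    preschool = stage_definition("preschool"),
    primary = stage_definition("primary"),
    junior = stage_definition("junior")
  )
}

# fetch persons at one (year, age) from a totals tibble (year, age, persons)
totals_at <- function(totals, year, age) {
  v <- totals$persons[totals$year == year & totals$age == age]
  if (length(v) != 1) {
    stop_coverage(sprintf("totals table does not cover year %d, age %d", year, age))
  }
  v
}

#' Population of one grade
#'
#' The grade labelled with age `a` is the two-year average of the
#' populations aged `a` and `a + 1` in that year.
#'
#' @param totals tibble with columns `year`, `age`, `persons` (from
#'   [totals_from_female()]).
#' @param year calendar year.
#' @param age_label grade age label (may be a vector).
#' @return persons in the grade(s), real-valued.
#' @export
grade_population <- function(totals, year, age_label) {
  vapply(age_label, function(a) {
    (totals_at(totals, year, a) + totals_at(totals, year, a + 1L)) / 2
  }, numeric(1))
}

#' Per-grade and stage enrollment table
#'
#' Expands a totals table into a long stage-enrollment table: one row per
#' (year, stage, grade label) with the two-year-average student count.
#'
#' @param totals tibble with `year`, `age`, `persons`.
#' @param stage a [stage_definition()].
#' @param years years to tabulate (default: all years in `totals`).
#' @return tibble (`year`, `stage`, `grade`, `students`) of class
#'   `stage_enrollment`.
#' @export
stage_enrollment <- function(totals, stage, years = NULL) {
  stopifnot(inherits(stage, "stage_definition"))
  years <- as.integer(years %||% sort(unique(totals$year)))
  out <- tidyr::expand_grid(year = years, grade = stage$labels)
  out$stage <- stage$name
  out$students <- unlist(lapply(years, function(y) grade_population(totals, y, stage$labels)))
  structure(
    out[, c("year", "stage", "grade", "students")],
    class = c("stage_enrollment", class(tibble::tibble()))
  )
}

#' Per-year stage totals
#'
#' Sums grade columns into a per-year stage total (e.g. the total
#' preschool-age population is the sum of the grades labelled 3, 4, 5).
#'
#' @inheritParams stage_enrollment
#' @return tibble (`year`, `stage`, `students`).
#' @export
stage_totals <- function(totals, stage, years = NULL) {
  enr <- stage_enrollment(totals, stage, years)
  dplyr::summarise(
    dplyr::group_by(enr, .data$year, .data$stage),
    students = sum(.data$students), .groups = "drop"
  )
}

#' First-grade primary entrants
#'
#' Six-year-old school-age children entering first grade: the grade
#' labelled 6 (mean of ages 6 and 7), scaled by the net enrollment rate.
#'
#' @param totals tibble with `year`, `age`, `persons`.
#' @param year calendar year.
#' @param enrollment_rate net enrollment rate in percent (default 100).
#' @return entrant count (persons).
#' @export
first_grade_entrants <- function(totals, year, enrollment_rate = 100) {
  grade_population(totals, year, 6L) * enrollment_rate / 100
}

#' Primary-school stock update
#'
#' One year of the stock-flow recursion for the primary stage: last year's
#' stock, minus last year's graduating sixth grade, plus this year's
#' eligible entrants.
#'
#' @param prev_total previous year's primary stock (persons).
#' @param prev_grade6 previous year's sixth-grade count.
#' @param entrants this year's first-grade entrants.
#' @return this year's primary stock.
#' @export
update_primary_stock <- function(prev_total, prev_grade6, entrants) {
  if (any(c(prev_total, prev_grade6, entrants) < 0)) {
    stop_validation("stock-update inputs must be non-negative")
  }
  if (prev_grade6 > prev_total) {
    stop_validation("grade-6 count exceeds the total stock")
  }
  prev_total - prev_grade6 + entrants
}

#' Junior-high stock update
#'
#' One year of the junior-high recursion: last year's stock, minus its
#' graduating third grade, plus the admitted share of last year's primary
#' sixth grade.
#'
#' @param prev_total previous year's junior-high stock.
#' @param prev_grade9 previous year's junior grade-3 count.
#' @param prev_grade6 previous year's primary grade-6 count.
#' @param a admission rate from primary to junior high, in `[0, 1]`
#'   (default 1: universal compulsory education).
#' @return this year's junior-high stock.
#' @export
update_junior_stock <- function(prev_total, prev_grade9, prev_grade6, a = 1) {
  if (a < 0 || a > 1) stop_validation("admission rate `a` must lie in [0, 1]")
  if (any(c(prev_total, prev_grade9, prev_grade6) < 0)) {
    stop_validation("stock-update inputs must be non-negative")
  }
  prev_total - prev_grade9 + a * prev_grade6
}

#' Single-grade progression
#'
#' `S_y = S_{y-1} * P + I`: this year's grade equals last year's same grade
#' scaled by the progression rate plus new entrants. With `P < 1` and
#' constant `I` the recursion converges to the fixed point `I / (1 - P)`.
#'
#' @param prev_same_grade last year's count for the grade.
#' @param progression_rate `P` in `[0, 1.5]`.
#' @param new_entrants `I`, newly enrolled students.
#' @return this year's grade count.
#' @export
progress_grade <- function(prev_same_grade, progression_rate, new_entrants) {
  if (progression_rate < 0 || progression_rate > 1.5) {
    stop_validation("`progression_rate` must lie in [0, 1.5]")
  }
  if (any(c(prev_same_grade, new_entrants) < 0)) {
    stop_validation("counts must be non-negative")
  }
  prev_same_grade * progression_rate + new_entrants
}

#' Grade-resolved progression series
#'
#' Advances explicit per-grade cohorts through both compulsory stages with
#' [progress_grade()]: first grade takes the year's entrants, every later
#' grade takes the previous grade of the previous year scaled by the
#' progression rate `1 - dropout`, and junior-high intake admits the share
#' `a` of the outgoing primary sixth grade. Grades are initialized from the
#' cross-sectional age structure of the first year.
#'
#' @param totals tibble with `year`, `age`, `persons`.
#' @param years consecutive years.
#' @param enrollment_rate net primary enrollment rate, percent.
#' @param a junior-high admission rate in `[0, 1]`.
#' @param dropout annual dropout rate in `[0, 1]` (default 0).
#' @return tibble (`year`, `primary`, `junior`) of grade-resolved stage
#'   stocks.
#' @export
grade_progression_series <- function(totals, years, enrollment_rate = 100,
                                     a = 1, dropout = 0) {
  if (a < 0 || a > 1) stop_validation("admission rate `a` must lie in [0, 1]")
  if (dropout < 0 || dropout > 1) stop_validation("`dropout` must lie in [0, 1]")
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop_range("`years` must be consecutive")
  }
  keep <- 1 - dropout
  prim <- grade_population(totals, years[1], 6:11) # grades 1..6
  jun <- grade_population(totals, years[1], 12:14) # grades 7..9
  out_primary <- sum(prim)
  out_junior <- sum(jun)
  for (j in seq_along(years)[-1]) {
    entrants <- first_grade_entrants(totals, years[j], enrollment_rate)
    new_prim <- c(
      progress_grade(0, keep, entrants),
      vapply(1:5, function(g) progress_grade(prim[g], keep, 0), numeric(1))
    )
    new_jun <- c(
      progress_grade(0, keep, a * prim[6]),
      vapply(1:2, function(g) progress_grade(jun[g], keep, 0), numeric(1))
    )
    prim <- new_prim
    jun <- new_jun
    out_primary <- c(out_primary, sum(prim))
    out_junior <- c(out_junior, sum(jun))
  }
  tibble::tibble(year = years, primary = out_primary, junior = out_junior)
}

#' Chained stock-flow stage series
#'
#' Runs the stock-update recursions over a span of years, seeded with the
#' cross-sectional stage total of the first year. Used to check that under
#' the model's assumptions (zero dropout, full enrollment, no school-age
#' mortality) the recursion reproduces the cross-sectional age sums.
#'
#' @param totals tibble with `year`, `age`, `persons`.
#' @param years consecutive years, recursion runs from the second onward.
#' @param enrollment_rate percent of six-year-olds entering first grade.
#' @param a junior-high admission rate in `[0, 1]`.
#' @return tibble (`year`, `primary`, `junior`) of stock-recursion totals.
#' @export
stock_flow_series <- function(totals, years, enrollment_rate = 100, a = 1) {
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop_range("`years` must be consecutive")
  }
  primary <- junior <- numeric(length(years))
  primary[1] <- sum(grade_population(totals, years[1], 6:11))
  junior[1] <- sum(grade_population(totals, years[1], 12:14))
  for (j in seq_along(years)[-1]) {
    y_prev <- years[j - 1]
    g6_prev <- grade_population(totals, y_prev, 11L) # primary sixth grade
    g9_prev <- grade_population(totals, y_prev, 14L) # junior third grade
    primary[j] <- update_primary_stock(
      primary[j - 1], g6_prev,
      first_grade_entrants(totals, years[j], enrollment_rate)
    )
    junior[j] <- update_junior_stock(junior[j - 1], g9_prev, g6_prev, a)
  }
  tibble::tibble(year = years, primary = primary, junior = junior)
}
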