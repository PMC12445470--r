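# End-to-end orchestration: vital-rate fits -> Leslie projection ->
# stage enrollment -> rural/urban split -> teacher demand -> tables.
#
# The pipeline mirrors the study layout: per-region projections are
# aggregated into a study-wide school-age table (grade labels 3-14 with
# stage totals), rural concentration is modelled per stage at the study
# level, and rural student counts and teacher requirements are reported
# per region and stage.

#' Pipeline configuration
#'
#' Collects every assumption the run uses. In synthetic mode (the default)
#' inputs come from [generate_scenario()]; otherwise they are read from
#' `input_dir` (a directory in the [write_scenario()] layout).
#'
#' @param input_dir directory of CSV inputs; `NULL` (default) enables
#'   synthetic mode.
#' @param scenario a [scenario_spec()] used in synthetic mode; defaults to
#'   `scenario_spec(seed = seed)`.
#' @param seed seed for the default synthetic scenario.
#' @param horizon projection years (default 2024-2040).
#' @param vital_fit_window years of rate history used for the OLS trend
#'   (default 2000-2023).
#' @param baseline_fit_window years used to calibrate the baseline total
#'   when a recorded totals series is supplied (default 2010-2022).
#' @param population_totals optional [rate_series()] of recorded female
#'   totals for baseline calibration; `NULL` skips calibration.
#' @param stages list of [stage_definition()]s (default [default_stages()]).
#' @param staffing a [staffing_standard()]; `NULL` takes the scenario's.
#' @param sex_ratio males per 100 females (default 105).
#' @param admission_rate primary-to-junior admission rate (default 1).
#' @param dropout_rate annual dropout rate (default 0).
#' @param enrollment_rate net primary enrollment rate used by the run, in
#'   percent. The default 100 encodes the compulsory-education assumption:
#'   the smoothed historical rate sits at the cap, so universal enrollment
#'   is imposed. Set to `NULL` to use the capped exponential-smoothing
#'   forecast instead; either way the forecast is computed and logged.
#' @param enrollment_cap cap on the forecast enrollment rate, percent
#'   (default 100).
#' @param fertility_pattern normalized fertility age pattern (default
#'   [fertility_age_pattern()]).
#' @param concentration_schedules optional named list (per stage) of
#'   tibbles (`year`, `rural_share`) overriding the fitted linear decline.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            scenario = NULL,
                            seed = 1L,
                            horizon = 2024:2040,
                            vital_fit_window = c(2000, 2023),
                            baseline_fit_window = c(2010, 2022),
                            population_totals = NULL,
                            stages = default_stages(),
                            staffing = NULL,
                            sex_ratio = 105,
                            admission_rate = 1,
                            dropout_rate = 0,
                            enrollment_rate = 100,
                            enrollment_cap = 100,
                            fertility_pattern = fertility_age_pattern(),
                            concentration_schedules = NULL) {
  if (admission_rate < 0 || admission_rate > 1) {
    stop_validation("`admission_rate` must lie in [0, 1]")
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop_validation("`dropout_rate` must lie in [0, 1]")
  }
  structure(
    list(
      input_dir = input_dir,
      synthetic = is.null(input_dir),
      scenario = scenario %||% scenario_spec(seed = seed),
      seed = as.integer(seed),
      horizon = as.integer(horizon),
      vital_fit_window = vital_fit_window,
      baseline_fit_window = baseline_fit_window,
      population_totals = population_totals,
      stages = stages,
      staffing = staffing,
      sex_ratio = sex_ratio,
      admission_rate = admission_rate,
      dropout_rate = dropout_rate,
      enrollment_rate = enrollment_rate,
      enrollment_cap = enrollment_cap,
      fertility_pattern = fertility_pattern,
      concentration_schedules = concentration_schedules
    ),
    class = "pipeline_config"
  )
}

# observed-then-extrapolated rate lookup for the projection years
rate_lookup <- function(series, fit, years) {
  vapply(years, function(y) {
    obs <- series$value[series$year == y]
    if (length(obs) == 1) obs else max(0, fit$intercept + fit$slope * y)
  }, numeric(1))
}

#' Run the full forecasting pipeline
#'
#' Executes every stage: fits and extrapolates crude vital-rate trends per
#' region, projects each region's female population with a crude-rate
#' calibrated Leslie matrix, converts to total persons, tabulates
#' school-age grades and stage totals, extrapolates rural concentration per
#' stage, splits stage enrollment into rural and urban students, converts
#' rural students to teacher requirements, and summarizes horizon declines.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_result` with elements
#'   `tables` (named list: `school_age_population`, `rural_concentration`,
#'   `rural_students`, `teacher_demand`, `stock_flow`, `decline_summary`),
#'   `trajectories`, `fits`, `log` (assumption and clamp record), and
#'   `bundle` (the inputs used).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- if (config$synthetic) {
    generate_scenario(config$scenario)
  } else {
    read_scenario(config$input_dir)
  }
  regions <- names(bundle$populations)
  staffing <- config$staffing %||% bundle$staffing
  horizon <- config$horizon
  horizon_end <- max(horizon)
  baseline_year <- bundle$populations[[1]]$year
  if (min(horizon) < baseline_year) {
    stop_config("horizon must not start before the baseline year")
  }

  # enrollment-rate forecast (capped); the configured assumption, when set,
  # overrides it (universal compulsory enrollment) but both are logged
  enroll_fc <- forecast_enrollment(bundle$enrollment, horizon, cap = config$enrollment_cap)
  enrollment_forecast <- enroll_fc$value[enroll_fc$year == min(horizon)]
  enrollment_rate <- config$enrollment_rate %||% enrollment_forecast

  log <- list(
    synthetic = config$synthetic,
    regions = regions,
    baseline_year = baseline_year,
    horizon = range(horizon),
    vital_fit_window = config$vital_fit_window,
    sex_ratio = config$sex_ratio,
    admission_rate = config$admission_rate,
    dropout_rate = config$dropout_rate,
    enrollment_rate_used = enrollment_rate,
    enrollment_rate_forecast = enrollment_forecast,
    enrollment_cap = config$enrollment_cap,
    staffing = unclass(staffing),
    clamped_forecast_years = list()
  )

  # per-region vital fits, projection, stage tables
  fits <- list()
  trajectories <- list()
  totals_by_region <- list()
  for (region in regions) {
    vit <- bundle$vitals[[region]]
    bfit <- fit_linear_trend(vit$birth, config$vital_fit_window)
    dfit <- fit_linear_trend(vit$death, config$vital_fit_window)
    fits[[region]] <- list(birth = bfit, death = dfit)

    step_years <- baseline_year:(horizon_end - 1L)
    cbr <- stats::setNames(rate_lookup(vit$birth, bfit, step_years), step_years)
    cdr <- stats::setNames(rate_lookup(vit$death, dfit, step_years), step_years)
    n_clamped <- sum(bfit$intercept + bfit$slope * step_years < 0) +
      sum(dfit$intercept + dfit$slope * step_years < 0)
    log$clamped_forecast_years[[region]] <- n_clamped

    pop0 <- bundle$populations[[region]]
    if (!is.null(config$population_totals)) {
      pop0 <- calibrate_baseline(pop0, config$population_totals, config$baseline_fit_window)
    }
    traj <- project_trajectory(
      pop0,
      fert = function(year, pop) {
        fertility_from_crude_rate(
          cbr[[as.character(year)]], pop,
          pattern = config$fertility_pattern,
          males_per_100_females = config$sex_ratio
        )
      },
      surv = function(year, pop) survival_from_crude_rate(cdr[[as.character(year)]]),
      horizon_end = horizon_end
    )
    trajectories[[region]] <- traj
    totals_by_region[[region]] <- totals_from_female(traj, config$sex_ratio)
  }

  # study-wide school-age table: aggregate total persons across regions
  totals_all <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(totals_by_region), .data$year, .data$age),
    persons = sum(.data$persons), .groups = "drop"
  )
  grades_all <- dplyr::bind_rows(lapply(config$stages, function(st) {
    stage_enrollment(totals_all, st, years = horizon)
  }))
  school_age <- tidyr::pivot_wider(
    grades_all,
    id_cols = "year", names_from = "grade", values_from = "students",
    names_prefix = "age_"
  )
  for (st in config$stages) {
    tot <- stage_totals(totals_all, st, years = horizon)
    school_age[[paste0(st$name, "_total")]] <- tot$students[match(school_age$year, tot$year)]
  }

  # rural concentration per stage: endpoint decline continued from the
  # last observation, unless an explicit schedule overrides it
  concentration <- dplyr::bind_rows(lapply(names(bundle$concentration), function(stage) {
    sched <- config$concentration_schedules[[stage]]
    if (!is.null(sched)) {
      cs <- extrapolate_concentration(NA, NA, NA, NA, stage = stage, schedule = sched)
    } else {
      hist <- bundle$concentration[[stage]]
      decline <- fit_annual_decline(hist)
      last_year <- max(hist$year)
      last_share <- hist$value[hist$year == last_year]
      start_share <- min(100, max(0, last_share - decline * (min(horizon) - last_year)))
      cs <- extrapolate_concentration(min(horizon), start_share, decline,
        horizon_end,
        stage = stage
      )
    }
    tibble::tibble(stage = stage, year = cs$year, rural_share = cs$rural_share)
  }))

  # per-region stage totals over the horizon -> rural split -> teachers
  stage_by_region <- dplyr::bind_rows(lapply(regions, function(region) {
    dplyr::bind_rows(lapply(config$stages, function(st) {
      tot <- stage_totals(totals_by_region[[region]], st, years = horizon)
      tibble::tibble(
        region = region, stage = st$name,
        year = tot$year, students = tot$students
      )
    }))
  }))
  rural <- dplyr::inner_join(stage_by_region, concentration, by = c("stage", "year"))
  split <- rural_students(rural$students, rural$rural_share)
  rural$rural <- split$rural
  rural$urban <- split$urban
  teacher <- tibble::tibble(
    region = rural$region, stage = rural$stage, year = rural$year,
    value = unlist(Map(
      function(s, st) teachers_required(s, staffing, st),
      rural$rural, rural$stage
    ))
  )
  decline <- demand_summary(teacher, min(horizon), max(horizon))

  # grade-resolved stock-flow view (responds to admission/dropout settings)
  stock_flow <- dplyr::bind_rows(lapply(regions, function(region) {
    sf <- grade_progression_series(
      totals_by_region[[region]], horizon,
      enrollment_rate = enrollment_rate,
      a = config$admission_rate, dropout = config$dropout_rate
    )
    tibble::tibble(
      region = region, year = sf$year,
      primary_stock = sf$primary, junior_stock = sf$junior
    )
  }))

  structure(
    list(
      tables = list(
        school_age_population = school_age,
        rural_concentration = concentration,
        rural_students = rural,
        teacher_demand = teacher,
        stock_flow = stock_flow,
        decline_summary = decline
      ),
      trajectories = trajectories,
      fits = fits,
      log = log,
      bundle = bundle
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d regions, horizon %d-%d, tables: %s\n",
    length(x$trajectories), x$log$horizon[1], x$log$horizon[2],
    paste(names(x$tables), collapse = ", ")
  ))
  invisible(x)
}

# reporting precision: persons-valued tables in units of 1e4 persons
WAN <- 1e4

round_for_report <- function(table_id, tab) {
  tab <- tibble::as_tibble(tab)
  if (table_id == "school_age_population") {
    num <- setdiff(names(tab), "year")
    tab[num] <- lapply(tab[num], function(v) round_half_away(v / WAN, 1))
  } else if (table_id == "rural_concentration") {
    tab$rural_share <- round_half_away(tab$rural_share, 2)
  } else if (table_id %in% c("rural_students", "teacher_demand", "stock_flow")) {
    num <- intersect(
      c("students", "rural", "urban", "value", "primary_stock", "junior_stock"),
      names(tab)
    )
    tab[num] <- lapply(tab[num], function(v) round_half_away(v / WAN, 2))
    if ("rural_share" %in% names(tab)) {
      tab$rural_share <- round_half_away(tab$rural_share, 2)
    }
  } else if (table_id == "decline_summary") {
    tab$value_start <- round_half_away(tab$value_start / WAN, 2)
    tab$value_end <- round_half_away(tab$value_end / WAN, 2)
  }
  tab
}

#' Write one result table to CSV
#'
#' Emits a table from a [run_pipeline()] result at reporting precision:
#' populations in units of 10,000 persons to 1 decimal, students and
#' teachers in units of 10,000 to 2 decimals, percentages to 2 decimals.
#' `format = "wide"` pivots per-region tables to year rows x region
#' columns (one stage per file via `stage`); `"long"` writes the tidy
#' layout unchanged.
#'
#' @param result a `pipeline_result`.
#' @param table_id one of the names of `result$tables`.
#' @param path output CSV path.
#' @param format `"long"` (default) or `"wide"`.
#' @param stage for `format = "wide"` on per-region tables: which stage to
#'   pivot.
#' @return `path`, invisibly.
#' @export
emit_table <- function(result, table_id, path, format = c("long", "wide"),
                       stage = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  format <- match.arg(format)
  if (!table_id %in% names(result$tables)) {
    stop_config(sprintf("unknown table_id '%s'", table_id))
  }
  tab <- round_for_report(table_id, result$tables[[table_id]])
  if (format == "wide" && table_id %in% c("rural_students", "teacher_demand")) {
    if (is.null(stage)) stop_config("`stage` is required for wide per-region tables")
    value_col <- if (table_id == "rural_students") "rural" else "value"
    tab <- tidyr::pivot_wider(
      dplyr::select(
        dplyr::filter(tab, .data$stage == !!stage),
        "year", "region", dplyr::all_of(value_col)
      ),
      names_from = "region", values_from = dplyr::all_of(value_col)
    )
  } else if (format == "wide" && table_id == "rural_concentration") {
    tab <- tidyr::pivot_wider(tab, names_from = "stage", values_from = "rural_share")
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
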