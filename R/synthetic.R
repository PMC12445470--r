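# Seeded synthetic scenarios emulating census-style pipeline inputs:
# smooth age pyramids, linearly trending crude vital rates with additive
# Gaussian noise, and linearly declining rural-concentration series.
# Everything is deterministic given the scenario seed; the generating
# parameters are recorded in a manifest for parameter-recovery tests.

#' Synthetic scenario specification
#'
#' Defines the study conditions a generated scenario emulates: a set of
#' regions with smooth female age pyramids at the baseline year, 2000-2023
#' crude birth/death-rate histories trending linearly with additive noise,
#' per-stage rural-concentration histories declining linearly, and the
#' staffing standard. Defaults are sized like the western-China study:
#' 12 regions, history 2000-2023, projection horizon 2024-2040, birth rates
#' drifting down from about 12.5 per mille, death rates near 7 per mille and
#' slowly rising, rural shares starting near 28/28/15 percent and declining
#' by 0.43/0.37/0.25 percentage points per year for preschool, primary and
#' junior high respectively.
#'
#' @param seed integer RNG seed; every random draw in the scenario derives
#'   from it.
#' @param n_regions number of regions.
#' @param history_years years of observed rate history.
#' @param horizon_years projection years.
#' @param baseline_year year of the initial age pyramids (last history year).
#' @param total_females per-region female population totals (recycled);
#'   defaults to a deterministic spread from 2 to 30 million.
#' @param pyramid_shape length-2 beta shape parameters of the age density.
#'   The density is evaluated over ages -10 to 60 and truncated to 0-49, so
#'   the pyramid does not artificially vanish at the age boundaries; the
#'   default `(2.6, 2.4)` puts the mean age in the mid-20s and leaves the
#'   infant classes consistent with a crude birth rate near 10 per mille.
#' @param birth_trend list `(intercept, slope, sigma)`: per-mille birth rate
#'   at the first history year, its per-year drift, and the s.d. of the
#'   additive Gaussian noise.
#' @param death_trend same structure for the death rate.
#' @param concentration per-stage list of `(start, decline, sigma)`: rural
#'   share (percent) at the first history year, decline in percentage
#'   points per year, noise s.d.
#' @param enrollment_history mean and s.d. of the historical net primary
#'   enrollment rate (percent).
#' @param staffing a [staffing_standard()].
#' @param sex_ratio males per 100 females.
#' @param admission_rate primary-to-junior admission rate in `[0, 1]`.
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1L,
                          n_regions = 12L,
                          history_years = 2000:2023,
                          horizon_years = 2024:2040,
                          baseline_year = 2023L,
                          total_females = NULL,
                          pyramid_shape = c(2.6, 2.4),
                          birth_trend = list(intercept = 12.5, slope = -0.2, sigma = 0.4),
                          death_trend = list(intercept = 6.8, slope = 0.04, sigma = 0.2),
                          concentration = list(
                            preschool = list(start = 28, decline = 0.43, sigma = 0.5),
                            primary = list(start = 28, decline = 0.37, sigma = 0.5),
                            junior = list(start = 15.2, decline = 0.25, sigma = 0.5)
                          ),
                          enrollment_history = list(mean = 99.91, sigma = 0.05),
                          staffing = staffing_standard(),
                          sex_ratio = 105,
                          admission_rate = 1) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 1) stop_validation("`n_regions` must be at least 1")
  sigmas <- c(
    birth_trend$sigma, death_trend$sigma,
    vapply(concentration, function(s) s$sigma, numeric(1)),
    enrollment_history$sigma
  )
  if (any(sigmas < 0)) stop_validation("noise s.d. values must be non-negative")
  total_females <- total_females %||% round(seq(2e6, 3e7, length.out = n_regions))
  structure(
    list(
      seed = as.integer(seed),
      n_regions = n_regions,
      regions = sprintf("region_%02d", seq_len(n_regions)),
      history_years = as.integer(history_years),
      horizon_years = as.integer(horizon_years),
      baseline_year = as.integer(baseline_year),
      total_females = rep_len(total_females, n_regions),
      pyramid_shape = pyramid_shape,
      birth_trend = birth_trend,
      death_trend = death_trend,
      concentration = concentration,
      enrollment_history = enrollment_history,
      staffing = staffing,
      sex_ratio = sex_ratio,
      admission_rate = admission_rate
    ),
    class = "scenario_spec"
  )
}

#' Generate a smooth baseline age pyramid
#'
#' A beta-density age profile scaled to the requested total: smooth,
#' non-negative and fully deterministic (the pyramid shape carries no
#' sampling noise; noise enters the scenario through the rate series).
#' The beta density is evaluated over a padded age support (-10 to 60) and
#' truncated to ages 0-49 so the boundary classes keep realistic mass.
#'
#' @param spec a [scenario_spec()].
#' @param region region index (1-based) selecting the total.
#' @return a [female_age_vector()] at the baseline year.
#' @export
generate_initial_population <- function(spec, region = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  total <- spec$total_females[[region]]
  if (total < 0) stop_validation("total females must be non-negative")
  dens <- pyramid_density(0:(K_AGES - 1L), spec$pyramid_shape)
  counts <- if (sum(dens) > 0 && total > 0) dens / sum(dens) * total else rep(0, K_AGES)
  female_age_vector(counts, year = spec$baseline_year)
}

# beta density over ages mapped from the padded support [-pad, K + pad)
PYRAMID_PAD <- 10
pyramid_density <- function(ages, shape) {
  x <- (ages + 0.5 + PYRAMID_PAD) / (K_AGES + 2 * PYRAMID_PAD)
  stats::dbeta(x, shape[1], shape[2])
}

# linear trend + additive Gaussian noise, clamped at 0; seeded per stream
generate_trending_series <- function(region, kind, years, intercept, slope, sigma,
                                     seed, stream, ceiling = 110) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, stream))
  noise <- if (sigma > 0) stats::rnorm(length(years), 0, sigma) else rep(0, length(years))
  values <- intercept + slope * (years - years[1]) + noise
  values <- pmax(0, values)
  if (kind %in% c("enrollment", "concentration")) values <- pmin(values, 100)
  rate_series(region, kind, years, values, ceiling = ceiling)
}

# save/restore the global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate crude birth- and death-rate histories for one region
#'
#' Linearly trending per-mille series with additive Gaussian noise, clamped
#' at zero, reproducible from the scenario seed and region index.
#'
#' @param spec a [scenario_spec()].
#' @param region region index (1-based).
#' @return list with [rate_series()] elements `birth` and `death`.
#' @export
generate_vital_series <- function(spec, region = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  label <- spec$regions[[region]]
  list(
    birth = generate_trending_series(
      label, "birth", spec$history_years,
      spec$birth_trend$intercept, spec$birth_trend$slope, spec$birth_trend$sigma,
      spec$seed, stream = 2L * region
    ),
    death = generate_trending_series(
      label, "death", spec$history_years,
      spec$death_trend$intercept, spec$death_trend$slope, spec$death_trend$sigma,
      spec$seed, stream = 2L * region + 1L
    )
  )
}

#' Generate per-stage rural-concentration histories
#'
#' One linearly declining, noisy percent series per education stage,
#' shared across regions (educational urbanization is modelled at the
#' study-area level).
#'
#' @param spec a [scenario_spec()].
#' @return named list of [rate_series()] (kind `"concentration"`), one per
#'   stage.
#' @export
generate_concentration_history <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  stages <- names(spec$concentration)
  out <- lapply(seq_along(stages), function(i) {
    p <- spec$concentration[[stages[i]]]
    generate_trending_series(
      "all", "concentration", spec$history_years,
      p$start, -p$decline, p$sigma,
      spec$seed, stream = 10000L + i
    )
  })
  names(out) <- stages
  out
}

#' Generate a full scenario bundle
#'
#' Assembles every input the pipeline needs: per-region baseline pyramids
#' and vital-rate histories, per-stage concentration histories, a national
#' enrollment-rate history, the staffing standard, and a manifest recording
#' all generating parameters. Optionally written to a directory as the CSV
#' dialects the pipeline reads, plus `manifest.yaml`.
#'
#' @param spec a [scenario_spec()].
#' @param dir optional directory; when given, all inputs are written there.
#' @return a list of class `scenario_bundle` with elements `populations`,
#'   `vitals`, `concentration`, `enrollment`, `staffing`, `manifest`,
#'   `spec`.
#' @export
generate_scenario <- function(spec = scenario_spec(), dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  populations <- lapply(seq_len(spec$n_regions), function(r) generate_initial_population(spec, r))
  names(populations) <- spec$regions
  vitals <- lapply(seq_len(spec$n_regions), function(r) generate_vital_series(spec, r))
  names(vitals) <- spec$regions
  concentration <- generate_concentration_history(spec)
  enrollment <- generate_trending_series(
    "all", "enrollment", spec$history_years,
    spec$enrollment_history$mean, 0, spec$enrollment_history$sigma,
    spec$seed, stream = 20000L
  )
  manifest <- list(
    seed = spec$seed,
    n_regions = spec$n_regions,
    baseline_year = spec$baseline_year,
    history_years = range(spec$history_years),
    horizon_years = range(spec$horizon_years),
    total_females = as.list(stats::setNames(spec$total_females, spec$regions)),
    pyramid_shape = spec$pyramid_shape,
    birth_trend = spec$birth_trend,
    death_trend = spec$death_trend,
    concentration = spec$concentration,
    enrollment_history = spec$enrollment_history,
    sex_ratio = spec$sex_ratio,
    admission_rate = spec$admission_rate,
    staffing = unclass(spec$staffing)
  )
  bundle <- structure(
    list(
      populations = populations, vitals = vitals, concentration = concentration,
      enrollment = enrollment, staffing = spec$staffing, manifest = manifest,
      spec = spec
    ),
    class = "scenario_bundle"
  )
  if (!is.null(dir)) write_scenario(bundle, dir)
  bundle
}

#' Write a scenario bundle to CSV inputs
#'
#' @param bundle a `scenario_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (region in names(bundle$populations)) {
    write_age_vector(
      bundle$populations[[region]],
      file.path(dir, sprintf("population_%s.csv", region))
    )
  }
  rates <- dplyr::bind_rows(c(
    lapply(names(bundle$vitals), function(region) {
      dplyr::bind_rows(lapply(bundle$vitals[[region]], function(s) {
        tibble::tibble(
          region = attr(s, "region"), kind = attr(s, "kind"),
          year = s$year, value = s$value
        )
      }))
    }),
    lapply(names(bundle$concentration), function(stage) {
      s <- bundle$concentration[[stage]]
      tibble::tibble(region = stage, kind = "concentration", year = s$year, value = s$value)
    }),
    list(tibble::tibble(
      region = "all", kind = "enrollment",
      year = bundle$enrollment$year, value = bundle$enrollment$value
    ))
  ))
  utils::write.csv(rates, file.path(dir, "rates.csv"), row.names = FALSE)
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
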