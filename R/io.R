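# Delimited-text (CSV, UTF-8, header row) readers and writers for the
# pipeline's interchange formats:
#   age vectors   age,count
#   schedules     age,rate
#   trajectories  year,age,count
#   rate tables   region,kind,year,value

#' Write an age vector to CSV
#' @param pop a [female_age_vector()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_age_vector <- function(pop, path) {
  stopifnot(inherits(pop, "female_age_vector"))
  utils::write.csv(
    data.frame(age = pop$ages, count = pop$counts),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Read an age vector from CSV
#' @param path CSV with columns `age`, `count`.
#' @param year calendar year to label the vector with.
#' @return a [female_age_vector()].
#' @export
read_age_vector <- function(path, year) {
  dat <- utils::read.csv(path)
  if (!all(c("age", "count") %in% names(dat))) {
    stop_validation(sprintf("'%s' must have columns age, count", path))
  }
  dat <- dat[order(dat$age), ]
  if (!identical(as.integer(dat$age), 0:(K_AGES - 1L))) {
    stop_validation(sprintf("'%s' must cover ages 0..%d exactly once", path, K_AGES - 1L))
  }
  female_age_vector(dat$count, year = year)
}

#' Write a per-age schedule to CSV
#' @param rates numeric vector of length 50 (per-age rates).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(rates, path) {
  utils::write.csv(
    data.frame(age = 0:(K_AGES - 1L), rate = as.numeric(rates)),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a per-age schedule from CSV
#' @param path CSV with columns `age`, `rate`.
#' @return numeric vector of length 50, ordered by age.
#' @export
read_schedule <- function(path) {
  dat <- utils::read.csv(path)
  if (!all(c("age", "rate") %in% names(dat))) {
    stop_validation(sprintf("'%s' must have columns age, rate", path))
  }
  dat <- dat[order(dat$age), ]
  dat$rate
}

#' Write a trajectory to long CSV
#' @param traj a `population_trajectory`.
#' @param path output file (columns `year`, `age`, `count`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "population_trajectory"))
  tab <- as_tibble(traj)
  utils::write.csv(
    data.frame(year = tab$year, age = tab$age, count = tab$females),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a trajectory from long CSV
#' @param path CSV with columns `year`, `age`, `count`.
#' @return a `population_trajectory`.
#' @export
read_trajectory <- function(path) {
  dat <- utils::read.csv(path)
  if (!all(c("year", "age", "count") %in% names(dat))) {
    stop_validation(sprintf("'%s' must have columns year, age, count", path))
  }
  years <- sort(unique(dat$year))
  counts <- vapply(years, function(y) {
    sl <- dat[dat$year == y, ]
    sl <- sl[order(sl$age), ]
    if (!identical(as.integer(sl$age), 0:(K_AGES - 1L))) {
      stop_validation(sprintf("year %d must cover ages 0..%d", y, K_AGES - 1L))
    }
    sl$count
  }, numeric(K_AGES))
  structure(
    list(
      years = as.integer(years),
      counts = matrix(counts, K_AGES,
        dimnames = list(0:(K_AGES - 1L), years)
      )
    ),
    class = "population_trajectory"
  )
}

#' Read a long rate table into rate series
#'
#' @param path CSV with columns `region`, `kind`, `year`, `value`.
#' @return named nested list: `out[[region]][[kind]]` is a [rate_series()].
#' @export
read_rate_table <- function(path) {
  dat <- utils::read.csv(path)
  if (!all(c("region", "kind", "year", "value") %in% names(dat))) {
    stop_validation(sprintf("'%s' must have columns region, kind, year, value", path))
  }
  out <- list()
  for (region in unique(dat$region)) {
    for (kind in unique(dat$kind[dat$region == region])) {
      sl <- dat[dat$region == region & dat$kind == kind, ]
      sl <- sl[order(sl$year), ]
      out[[region]][[kind]] <- rate_series(region, kind, sl$year, sl$value)
    }
  }
  out
}

#' Read a scenario bundle back from a directory
#'
#' Inverse of [write_scenario()]: reconstructs populations, vital series,
#' concentration and enrollment histories, the staffing standard and the
#' manifest from the CSV inputs.
#'
#' @param dir directory written by [write_scenario()].
#' @return a `scenario_bundle`.
#' @export
read_scenario <- function(dir) {
  manifest_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(manifest_path)) {
    stop_config(sprintf("no manifest.yaml under '%s'", dir))
  }
  manifest <- yaml::read_yaml(manifest_path)
  rates <- read_rate_table(file.path(dir, "rates.csv"))
  stage_names <- names(manifest$concentration)
  regions <- setdiff(names(rates), c(stage_names, "all"))
  populations <- lapply(regions, function(region) {
    read_age_vector(
      file.path(dir, sprintf("population_%s.csv", region)),
      year = manifest$baseline_year
    )
  })
  names(populations) <- regions
  vitals <- lapply(regions, function(region) rates[[region]][c("birth", "death")])
  names(vitals) <- regions
  concentration <- lapply(stage_names, function(stage) rates[[stage]]$concentration)
  names(concentration) <- stage_names
  structure(
    list(
      populations = populations,
      vitals = vitals,
      concentration = concentration,
      enrollment = rates[["all"]]$enrollment,
      staffing = do.call(staffing_standard, manifest$staffing),
      manifest = manifest,
      spec = NULL
    ),
    class = "scenario_bundle"
  )
}
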