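# Leslie-matrix projection of a female population in one-year age groups.
#
# The model tracks women aged 0..49 (k = 50 classes). A projection step
# applies age-specific fertility to produce the age-0 class of the next year
# and moves survivors one class up; women ageing past 49 leave the model.
# The population is closed: no migration.

#' Number of one-year age classes tracked (ages 0 to 49)
#' @export
K_AGES <- 50L

#' Female age-distribution vector
#'
#' Counts of women by single year of age at one point in time. Counts are
#' real-valued: fractional persons are permitted mid-pipeline, rounding
#' happens only in reporting. A vector labelled year `Y` represents the
#' mid-year population of `Y`; age is in completed years.
#'
#' @param counts numeric vector of length 50, non-negative; element `i`
#'   holds the count of women aged `i - 1`.
#' @param year calendar year the vector refers to.
#' @return an object of class `female_age_vector` with fields `year`,
#'   `counts` and `ages` (0:49).
#' @export
female_age_vector <- function(counts, year) {
  counts <- as.numeric(counts)
  if (length(counts) != K_AGES) {
    stop_dimension(sprintf("`counts` must have length %d, got %d", K_AGES, length(counts)))
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop_validation("all counts must be non-negative and non-missing")
  }
  structure(
    list(year = as.integer(year), counts = counts, ages = 0:(K_AGES - 1L)),
    class = "female_age_vector"
  )
}

#' @export
print.female_age_vector <- function(x, ...) {
  cat(sprintf(
    "<female_age_vector> year %d, %d age classes, total %.1f\n",
    x$year, length(x$counts), sum(x$counts)
  ))
  invisible(x)
}

#' Age-specific fertility schedule
#'
#' Annual fertility rates `b_i` (births of either sex per woman of age `i`
#' per year) together with the female fraction of newborns `f`. Fertility is
#' restricted to the reproductive ages 15-49; rates outside that band must
#' be zero.
#'
#' @param rates numeric vector of length 50 of per-age fertility rates,
#'   indexed by age 0..49.
#' @param female_fraction proportion of newborns that are female, in (0, 1).
#'   The default corresponds to a sex ratio at birth of 105 males per 100
#'   females: 100/205.
#' @return an object of class `fertility_schedule`.
#' @export
fertility_schedule <- function(rates, female_fraction = 100 / 205) {
  rates <- as.numeric(rates)
  if (length(rates) != K_AGES) {
    stop_dimension(sprintf("`rates` must have length %d", K_AGES))
  }
  if (anyNA(rates) || any(rates < 0)) {
    stop_validation("fertility rates must be non-negative")
  }
  ages <- 0:(K_AGES - 1L)
  if (any(rates[ages < 15] > 0)) {
    stop_validation("fertility must be zero outside ages 15-49")
  }
  if (!is.numeric(female_fraction) || length(female_fraction) != 1 ||
      female_fraction <= 0 || female_fraction >= 1) {
    stop_validation("`female_fraction` must be a single number in (0, 1)")
  }
  structure(
    list(rates = rates, female_fraction = female_fraction),
    class = "fertility_schedule"
  )
}

#' Age-specific survival schedule
#'
#' Annual survival probabilities `s_i = 1 - d_i`, where `d_i` is the
#' probability that a woman aged `i` dies within the year.
#'
#' @param survival numeric vector of length 50 with values in `[0, 1]`.
#' @return an object of class `survival_schedule`.
#' @export
survival_schedule <- function(survival) {
  survival <- as.numeric(survival)
  if (length(survival) != K_AGES) {
    stop_dimension(sprintf("`survival` must have length %d", K_AGES))
  }
  if (anyNA(survival) || any(survival < 0) || any(survival > 1)) {
    stop_validation("survival probabilities must lie in [0, 1]")
  }
  structure(list(survival = survival), class = "survival_schedule")
}

#' Normalized age pattern of fertility
#'
#' Discretized Gaussian fertility pattern over the reproductive ages,
#' used to distribute a crude (all-age) birth rate across mothers' ages when
#' no empirical age-specific schedule is available. The pattern is zero
#' outside ages 15-49 and sums to 1 over them.
#'
#' @param mean_age mean age at childbearing (default 27 years).
#' @param sd_age standard deviation of the age-at-childbearing distribution
#'   (default 5 years).
#' @return numeric vector of length 50 summing to 1.
#' @export
fertility_age_pattern <- function(mean_age = 27, sd_age = 5) {
  ages <- 0:(K_AGES - 1L)
  w <- stats::dnorm(ages, mean = mean_age, sd = sd_age)
  w[ages < 15] <- 0
  w / sum(w)
}

#' Fertility schedule calibrated to a crude birth rate
#'
#' Scales a normalized age pattern so that the births it implies on a given
#' population reproduce a crude birth rate (births per 1,000 total persons
#' per year). Total persons are derived from the female vector through the
#' sex ratio. With an all-zero pattern-weighted population the schedule is
#' all-zero (no mothers implies no births).
#'
#' @param crude_rate crude birth rate, per mille (per 1,000 persons).
#' @param pop a [female_age_vector()]: the population the rate refers to.
#' @param pattern normalized fertility age pattern (length 50), as from
#'   [fertility_age_pattern()].
#' @param female_fraction proportion of newborns that are female.
#' @param males_per_100_females sex ratio used to convert female counts to
#'   total persons for the crude-rate denominator.
#' @return a [fertility_schedule()] whose implied births equal
#'   `crude_rate / 1000` times the total population.
#' @export
fertility_from_crude_rate <- function(crude_rate, pop, pattern = fertility_age_pattern(),
                                      female_fraction = 100 / 205,
                                      males_per_100_females = 105) {
  if (crude_rate < 0) stop_validation("`crude_rate` must be non-negative")
  total_persons <- sum(pop$counts) * (1 + males_per_100_females / 100)
  target_births <- crude_rate / 1000 * total_persons
  weighted <- sum(pattern * pop$counts)
  rates <- if (weighted > 0) pattern * (target_births / weighted) else rep(0, K_AGES)
  fertility_schedule(rates, female_fraction = female_fraction)
}

#' Survival schedule from a crude death rate
#'
#' Applies a crude (all-age) death rate uniformly across ages:
#' `s_i = 1 - d/1000` for every age class. Supply an age-specific override
#' through [survival_schedule()] when an empirical life table is available.
#'
#' @param crude_rate crude death rate, per mille.
#' @return a [survival_schedule()].
#' @export
survival_from_crude_rate <- function(crude_rate) {
  if (crude_rate < 0 || crude_rate > 1000) {
    stop_validation("`crude_rate` must lie in [0, 1000] per mille")
  }
  survival_schedule(rep(1 - crude_rate / 1000, K_AGES))
}

#' Build the Leslie projection matrix
#'
#' Assembles the k-by-k projection operator: the first row holds the
#' fertility contributions `f * b_i`, the subdiagonal holds the survival
#' probabilities `s_i`, and every other entry is zero.
#'
#' @param fert a [fertility_schedule()].
#' @param surv a [survival_schedule()].
#' @return a `leslie_matrix`: a 50 x 50 numeric matrix with class attribute.
#' @export
build_leslie_matrix <- function(fert, surv) {
  stopifnot(inherits(fert, "fertility_schedule"), inherits(surv, "survival_schedule"))
  k <- length(fert$rates)
  if (k != length(surv$survival)) {
    stop_dimension("fertility and survival schedules must have matching length")
  }
  L <- matrix(0, k, k)
  L[1, ] <- fert$female_fraction * fert$rates
  L[cbind(2:k, 1:(k - 1))] <- surv$survival[1:(k - 1)]
  structure(L, class = c("leslie_matrix", "matrix", "array"))
}

#' Advance the population one year
#'
#' One projection step: the age-0 class of year `t + 1` collects the female
#' newborns of all mothers, and each age class `i` moves to `i + 1` with
#' probability `s_i`. Equivalent to the matrix-vector product `L %*% n`.
#'
#' @param pop a [female_age_vector()].
#' @param L a `leslie_matrix` from [build_leslie_matrix()].
#' @return a [female_age_vector()] for `pop$year + 1`.
#' @export
project_step <- function(pop, L) {
  stopifnot(inherits(pop, "female_age_vector"))
  if (nrow(L) != length(pop$counts)) {
    stop_dimension("population vector length does not match matrix dimension")
  }
  female_age_vector(drop(unclass(L) %*% pop$counts), year = pop$year + 1L)
}

#' Project a population trajectory
#'
#' Repeated application of [project_step()], rebuilding the Leslie matrix
#' each year from per-year schedules. Schedules may be supplied as a single
#' constant schedule, a list keyed by projection year (the year the step
#' starts from, as `"2023"`), or a function `f(year, pop)` returning the
#' schedule — the functional form supports crude-rate calibration, where the
#' fertility schedule depends on the current age structure.
#'
#' @param initial a [female_age_vector()] for the baseline year.
#' @param fert fertility specification: a [fertility_schedule()], a named
#'   list of them keyed by year, or `function(year, pop)`.
#' @param surv survival specification, same forms as `fert`.
#' @param horizon_end final calendar year of the trajectory (inclusive);
#'   must be `>= initial$year`.
#' @return a `population_trajectory`: list with `years` and a 50 x n_years
#'   matrix `counts` (one column per year).
#' @export
project_trajectory <- function(initial, fert, surv, horizon_end) {
  stopifnot(inherits(initial, "female_age_vector"))
  horizon_end <- as.integer(horizon_end)
  if (horizon_end < initial$year) {
    stop_range("`horizon_end` must not precede the initial year")
  }
  years <- initial$year:horizon_end
  counts <- matrix(0, K_AGES, length(years), dimnames = list(0:(K_AGES - 1L), years))
  counts[, 1] <- initial$counts
  pop <- initial
  if (length(years) > 1) {
    for (j in seq_len(length(years) - 1L)) {
      y <- years[j]
      L <- build_leslie_matrix(
        resolve_schedule(fert, y, pop, "fertility_schedule"),
        resolve_schedule(surv, y, pop, "survival_schedule")
      )
      pop <- project_step(pop, L)
      counts[, j + 1L] <- pop$counts
    }
  }
  structure(list(years = years, counts = counts), class = "population_trajectory")
}

resolve_schedule <- function(spec, year, pop, cls) {
  out <- if (inherits(spec, cls)) {
    spec
  } else if (is.function(spec)) {
    spec(year, pop)
  } else if (is.list(spec)) {
    spec[[as.character(year)]] %||%
      stop_config(sprintf("no %s supplied for projection year %d", cls, year))
  } else {
    stop_config(sprintf("invalid %s specification", cls))
  }
  if (!inherits(out, cls)) stop_config(sprintf("schedule for year %d is not a %s", year, cls))
  out
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf(
    "<population_trajectory> %d-%d (%d years), totals %.1f -> %.1f\n",
    x$years[1], x$years[length(x$years)], length(x$years),
    sum(x$counts[, 1]), sum(x$counts[, ncol(x$counts)])
  ))
  invisible(x)
}

#' Trajectory as a tidy table
#'
#' @param x a `population_trajectory`.
#' @param ... unused.
#' @return a tibble with columns `year`, `age`, `females`.
#' @export
as_tibble.population_trajectory <- function(x, ...) {
  tibble::tibble(
    year = rep(x$years, each = K_AGES),
    age = rep(0:(K_AGES - 1L), times = length(x$years)),
    females = as.vector(x$counts)
  )
}

#' Total persons by year and age from a female trajectory
#'
#' Inflates female counts to total persons with a sex ratio (males per 100
#' females), either a scalar or a per-age vector of length 50:
#' `total = females * (1 + ratio/100)`.
#'
#' @param traj a `population_trajectory`.
#' @param males_per_100_females scalar or length-50 positive numeric.
#' @return a tibble with columns `year`, `age`, `persons`.
#' @export
totals_from_female <- function(traj, males_per_100_females = 105) {
  stopifnot(inherits(traj, "population_trajectory"))
  r <- as.numeric(males_per_100_females)
  if (!length(r) %in% c(1L, K_AGES) || anyNA(r) || any(r <= 0)) {
    stop_validation("`males_per_100_females` must be positive, length 1 or 50")
  }
  factor <- 1 + r / 100
  tibble::tibble(
    year = rep(traj$years, each = K_AGES),
    age = rep(0:(K_AGES - 1L), times = length(traj$years)),
    persons = as.vector(traj$counts * factor)
  )
}
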