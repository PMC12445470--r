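# Independent oracles: deliberately naive implementations used to check
# the package's vectorized/matrix paths.

# explicit per-cohort bookkeeping for one projection year
oracle_cohort_step <- function(counts, rates, female_fraction, survival) {
  k <- length(counts)
  out <- numeric(k)
  births <- 0
  for (i in seq_len(k)) {
    births <- births + female_fraction * rates[i] * counts[i]
    if (i < k) out[i + 1] <- survival[i] * counts[i]
  }
  out[1] <- births
  out
}

oracle_cohort_chain <- function(counts, rates, female_fraction, survival, steps) {
  for (s in seq_len(steps)) {
    counts <- oracle_cohort_step(counts, rates, female_fraction, survival)
  }
  counts
}

# entry-by-entry loop construction of the projection matrix
oracle_leslie_matrix <- function(rates, female_fraction, survival) {
  k <- length(rates)
  L <- matrix(0, k, k)
  for (j in seq_len(k)) {
    L[1, j] <- female_fraction * rates[j]
    if (j < k) L[j + 1, j] <- survival[j]
  }
  L
}

# closed-form OLS by two-pass summation
oracle_ols <- function(x, y) {
  xbar <- sum(x) / length(x)
  ybar <- sum(y) / length(y)
  slope <- sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
  list(slope = slope, intercept = ybar - slope * xbar)
}

# Holt linear smoothing by explicit recursion, h-step-ahead forecast
oracle_holt_forecast <- function(y, alpha, beta, h) {
  l <- y[1]
  b <- y[2] - y[1]
  for (t in 2:length(y)) {
    l_new <- alpha * y[t] + (1 - alpha) * (l + b)
    b <- beta * (l_new - l) + (1 - beta) * b
    l <- l_new
  }
  l + h * b
}

# dominant eigenvalue by power iteration
oracle_power_iteration <- function(M, iters = 500) {
  v <- rep(1, nrow(M))
  lambda <- NA_real_
  for (i in seq_len(iters)) {
    w <- M %*% v
    lambda <- sqrt(sum(w^2)) / sqrt(sum(v^2))
    v <- w / sqrt(sum(w^2))
  }
  lambda
}

# random valid schedule pair and population under a given seed
random_demography <- function(seed) {
  set.seed(seed)
  rates <- rep(0, 50)
  rates[16:50] <- runif(35, 0, 0.15) # ages 15..49
  survival <- runif(50, 0.95, 1)
  counts <- runif(50, 0, 1000)
  list(
    fert = fertility_schedule(rates, female_fraction = runif(1, 0.45, 0.52)),
    surv = survival_schedule(survival),
    pop = female_age_vector(counts, year = 2023)
  )
}

# totals tibble (year, age, persons) built from an age->count function
# advanced as a pure shift with constant annual births
shift_totals <- function(first_year, n_years, base_counts) {
  ages <- 0:49
  rows <- lapply(seq_len(n_years), function(j) {
    # shift: age a in year j equals age a-(j-1) in year 1; younger ages
    # refill with the age-0 value (constant birth stream)
    shifted <- numeric(length(ages))
    for (a in ages) {
      src <- a - (j - 1)
      shifted[a + 1] <- if (src >= 0) base_counts[src + 1] else base_counts[1]
    }
    tibble::tibble(year = first_year + j - 1, age = ages, persons = shifted)
  })
  dplyr::bind_rows(rows)
}

extdata <- function(file) {
  system.file("extdata", file, package = "schooldemand", mustWork = TRUE)
}
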