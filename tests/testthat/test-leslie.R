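test_that("Leslie matrix has fertility first row, survival subdiagonal, zeros elsewhere", {
  # pure ageing: no births, certain survival
  L <- build_leslie_matrix(
    fertility_schedule(rep(0, 50)),
    survival_schedule(rep(1, 50))
  )
  expect_equal(L[1, ], rep(0, 50), ignore_attr = TRUE)
  expect_equal(L[cbind(2:50, 1:49)], rep(1, 49))
  expect_equal(sum(L != 0), 49L)

  # single fertile age: b_20 = 0.1 at f = 0.5 puts 0.05 in the age-20 column
  rates <- rep(0, 50)
  rates[21] <- 0.1
  L2 <- build_leslie_matrix(
    fertility_schedule(rates, female_fraction = 0.5),
    survival_schedule(rep(1, 50))
  )
  expect_equal(L2[1, 21], 0.05)
  expect_equal(sum(L2[1, ] != 0), 1L)
})

test_that("matrix construction matches a loop-built reference and column sums", {
  for (seed in 1:20) {
    d <- random_demography(seed)
    L <- build_leslie_matrix(d$fert, d$surv)
    ref <- oracle_leslie_matrix(d$fert$rates, d$fert$female_fraction, d$surv$survival)
    expect_equal(unclass(L), ref, ignore_attr = TRUE)
    expect_equal(
      colSums(L)[1:49],
      (d$surv$survival + d$fert$female_fraction * d$fert$rates)[1:49],
      ignore_attr = TRUE
    )
  }
})

test_that("schedule and vector validation rejects invalid inputs", {
  expect_error(female_age_vector(rep(1, 49), 2020), class = "schooldemand_error_dimension")
  expect_error(female_age_vector(c(-1, rep(1, 49)), 2020), class = "schooldemand_error_validation")
  expect_error(survival_schedule(c(rep(0.9, 49), 1.2)), class = "schooldemand_error_validation")
  bad <- rep(0, 50)
  bad[5] <- 0.1 # fertility at age 4
  expect_error(fertility_schedule(bad), class = "schooldemand_error_validation")
  expect_error(fertility_schedule(rep(0, 50), female_fraction = 1.2),
    class = "schooldemand_error_validation"
  )
})

test_that("a projection step is a pure shift when b = 0, s = 1", {
  counts <- c(10, 20, 30, rep(0, 47))
  pop <- female_age_vector(counts, 2020)
  L <- build_leslie_matrix(fertility_schedule(rep(0, 50)), survival_schedule(rep(1, 50)))
  nxt <- project_step(pop, L)
  expect_equal(nxt$year, 2021L)
  expect_equal(nxt$counts, c(0, 10, 20, 30, rep(0, 46)))

  # shift conservation: ages 1..49 at t+1 equal ages 0..48 at t
  d <- random_demography(99)
  nxt2 <- project_step(d$pop, L)
  expect_equal(nxt2$counts[2:50], d$pop$counts[1:49])
})

test_that("uniform halving removes half of everyone and the top class exits", {
  d <- random_demography(7)
  L <- build_leslie_matrix(fertility_schedule(rep(0, 50)), survival_schedule(rep(0.5, 50)))
  nxt <- project_step(d$pop, L)
  total <- sum(d$pop$counts)
  expect_equal(sum(nxt$counts), 0.5 * (total - d$pop$counts[50]))
})

test_that("matrix projection equals explicit cohort bookkeeping over 10 steps", {
  for (seed in c(1, 2, 3)) {
    d <- random_demography(seed)
    L <- build_leslie_matrix(d$fert, d$surv)
    pop <- d$pop
    for (step in 1:10) pop <- project_step(pop, L)
    ref <- oracle_cohort_chain(d$pop$counts, d$fert$rates, d$fert$female_fraction,
      d$surv$survival,
      steps = 10
    )
    expect_equal(pop$counts, ref, tolerance = 1e-9)
  }
})

test_that("projection is linear and preserves non-negativity", {
  d <- random_demography(11)
  e <- random_demography(12)
  L <- build_leslie_matrix(d$fert, d$surv)
  lhs <- project_step(
    female_age_vector(2 * d$pop$counts + 3 * e$pop$counts, 2023), L
  )$counts
  rhs <- 2 * project_step(d$pop, L)$counts + 3 * project_step(e$pop, L)$counts
  expect_equal(lhs, rhs, tolerance = 1e-12)
  for (seed in 1:10) {
    f <- random_demography(seed + 100)
    expect_true(all(project_step(f$pop, build_leslie_matrix(f$fert, f$surv))$counts >= 0))
  }
})

test_that("a zero-step trajectory is just the initial vector", {
  d <- random_demography(5)
  traj <- project_trajectory(d$pop, d$fert, d$surv, horizon_end = d$pop$year)
  expect_equal(traj$years, d$pop$year)
  expect_equal(as.vector(traj$counts), d$pop$counts)
})

test_that("trajectory equals repeated single steps and a missing schedule errors", {
  d <- random_demography(21)
  traj <- project_trajectory(d$pop, d$fert, d$surv, horizon_end = d$pop$year + 15L)
  L <- build_leslie_matrix(d$fert, d$surv)
  pop <- d$pop
  for (j in 1:15) {
    pop <- project_step(pop, L)
    expect_identical(unname(traj$counts[, j + 1]), pop$counts)
  }
  by_year <- list("2023" = d$fert) # only the first projection year supplied
  expect_error(
    project_trajectory(d$pop, by_year, d$surv, d$pop$year + 5L),
    class = "schooldemand_error_config"
  )
})

test_that("long-run growth factor converges to the dominant eigenvalue", {
  d <- random_demography(42)
  L <- build_leslie_matrix(d$fert, d$surv)
  traj <- project_trajectory(d$pop, d$fert, d$surv, horizon_end = d$pop$year + 80L)
  totals <- colSums(traj$counts)
  growth <- totals[81] / totals[80]
  lambda <- oracle_power_iteration(unclass(L))
  expect_equal(unname(growth), as.numeric(lambda), tolerance = 0.01)
})

test_that("female counts inflate to total persons by the sex ratio", {
  pop <- female_age_vector(rep(50, 50), 2024)
  traj <- project_trajectory(pop,
    fertility_schedule(rep(0, 50)), survival_schedule(rep(1, 50)),
    horizon_end = 2024
  )
  tot100 <- totals_from_female(traj, 100)
  expect_equal(tot100$persons, rep(100, 50))

  pop2 <- female_age_vector(rep(200, 50), 2024)
  traj2 <- project_trajectory(pop2,
    fertility_schedule(rep(0, 50)), survival_schedule(rep(1, 50)),
    horizon_end = 2024
  )
  expect_equal(totals_from_female(traj2, 105)$persons, rep(410, 50))

  # per-age ratio vector applied element-wise
  ratios <- seq(90, 120, length.out = 50)
  tot <- totals_from_female(traj2, ratios)
  expect_equal(tot$persons, 200 * (1 + ratios / 100))
  expect_error(totals_from_female(traj2, -5), class = "schooldemand_error_validation")
})

test_that("crude-rate calibration reproduces the crude birth rate exactly", {
  d <- random_demography(3)
  fert <- fertility_from_crude_rate(9.5, d$pop, males_per_100_females = 105)
  implied_births <- sum(fert$rates * d$pop$counts)
  total_persons <- sum(d$pop$counts) * 2.05
  expect_equal(implied_births / total_persons * 1000, 9.5, tolerance = 1e-12)
  # uniform crude death rate
  surv <- survival_from_crude_rate(7)
  expect_equal(surv$survival, rep(1 - 0.007, 50))
})
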