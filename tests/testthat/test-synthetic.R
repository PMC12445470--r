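test_that("scenario generation is fully deterministic under a fixed seed", {
  b1 <- generate_scenario(scenario_spec(seed = 11))
  b2 <- generate_scenario(scenario_spec(seed = 11))
  expect_identical(b1$populations, b2$populations)
  expect_identical(
    lapply(b1$vitals, lapply, function(s) s$value),
    lapply(b2$vitals, lapply, function(s) s$value)
  )
  expect_identical(
    lapply(b1$concentration, function(s) s$value),
    lapply(b2$concentration, function(s) s$value)
  )

  # written inputs are byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(b1, d1)
  write_scenario(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    )
  }
  # different seeds differ
  b3 <- generate_scenario(scenario_spec(seed = 12))
  expect_false(identical(b1$vitals[[1]]$birth$value, b3$vitals[[1]]$birth$value))
})

test_that("pyramids are smooth, scaled, and ordered by their shape mean", {
  spec <- scenario_spec(seed = 1, total_females = 1e6)
  pop <- generate_initial_population(spec, 1)
  expect_equal(sum(pop$counts), 1e6)
  expect_true(all(pop$counts > 0))
  # smooth: relative step between adjacent ages is small
  expect_true(max(abs(diff(pop$counts)) / pop$counts[-50]) < 0.2)

  zero <- generate_initial_population(scenario_spec(total_females = 0), 1)
  expect_equal(zero$counts, rep(0, 50))

  # mean-age ordering matches the analytic means of the shape densities,
  # computed by numeric integration of the truncated densities
  shapes <- list(young = c(2, 3.5), old = c(3.5, 2))
  analytic_mean <- function(shape) {
    pad <- 10
    f <- function(a) dbeta((a + pad) / (50 + 2 * pad), shape[1], shape[2])
    stats::integrate(function(a) a * f(a), 0, 50)$value /
      stats::integrate(f, 0, 50)$value
  }
  emp_mean <- function(shape) {
    p <- generate_initial_population(
      scenario_spec(total_females = 1e6, pyramid_shape = shape), 1
    )
    # class i spans [i, i+1): its midpoint age is i + 0.5
    sum((p$ages + 0.5) * p$counts) / sum(p$counts)
  }
  expect_lt(emp_mean(shapes$young), emp_mean(shapes$old))
  expect_lt(analytic_mean(shapes$young), analytic_mean(shapes$old))
  expect_equal(emp_mean(shapes$young), analytic_mean(shapes$young), tolerance = 0.005)
})

test_that("noiseless series are exactly linear and their slopes recovered", {
  spec <- scenario_spec(
    seed = 3,
    birth_trend = list(intercept = 12.5, slope = -0.2, sigma = 0),
    death_trend = list(intercept = 6.8, slope = 0.04, sigma = 0),
    concentration = list(
      preschool = list(start = 28, decline = 0.43, sigma = 0),
      primary = list(start = 28, decline = 0.37, sigma = 0),
      junior = list(start = 15.2, decline = 0.25, sigma = 0)
    )
  )
  vit <- generate_vital_series(spec, 1)
  expect_equal(max(abs(diff(diff(vit$birth$value)))), 0, tolerance = 1e-12)
  expect_equal(fit_linear_trend(vit$birth)$slope, -0.2, tolerance = 1e-10)
  expect_equal(fit_linear_trend(vit$death)$slope, 0.04, tolerance = 1e-10)

  conc <- generate_concentration_history(spec)
  expect_equal(fit_annual_decline(conc$primary), 0.37, tolerance = 1e-10)
  expect_equal(fit_annual_decline(conc$junior), 0.25, tolerance = 1e-10)
  expect_equal(conc$preschool$value[1], 28)
})

test_that("fitted slopes are unbiased across seeded replicates", {
  n_rep <- 300
  sigma <- 0.5
  slopes <- vapply(seq_len(n_rep), function(r) {
    spec <- scenario_spec(
      seed = r,
      birth_trend = list(intercept = 12.5, slope = -0.2, sigma = sigma)
    )
    fit_linear_trend(generate_vital_series(spec, 1)$birth)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(n_rep)
  expect_lt(abs(mean(slopes) - (-0.2)), 3 * se)

  # endpoint decline estimator is unbiased too
  declines <- vapply(seq_len(n_rep), function(r) {
    spec <- scenario_spec(
      seed = r,
      concentration = list(primary = list(start = 28, decline = 0.37, sigma = sigma))
    )
    fit_annual_decline(generate_concentration_history(spec)$primary)
  }, numeric(1))
  se_d <- sd(declines) / sqrt(n_rep)
  expect_lt(abs(mean(declines) - 0.37), 3 * se_d)
})

test_that("generated inputs satisfy every downstream invariant", {
  b <- generate_scenario(scenario_spec(seed = 6))
  for (region in names(b$vitals)) {
    expect_true(all(b$vitals[[region]]$birth$value >= 0))
    expect_true(all(b$vitals[[region]]$death$value >= 0))
  }
  for (stage in names(b$concentration)) {
    v <- b$concentration[[stage]]$value
    expect_true(all(v >= 0 & v <= 100))
  }
  expect_true(all(b$enrollment$value <= 100))
  for (pop in b$populations) expect_true(all(pop$counts >= 0))

  # clamped-at-zero generation never leaks negatives
  steep <- scenario_spec(seed = 2, birth_trend = list(intercept = 3, slope = -0.3, sigma = 0.5))
  expect_true(all(generate_vital_series(steep, 1)$birth$value >= 0))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_scenario(scenario_spec(seed = 4)))
  expect_identical(.Random.seed, before)
})
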