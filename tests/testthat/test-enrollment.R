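test_that("a grade is the two-year average of its age and the next", {
  totals <- tibble::tibble(year = 2024, age = 0:49, persons = 0)
  totals$persons[totals$age == 6] <- 100
  totals$persons[totals$age == 7] <- 100
  expect_equal(grade_population(totals, 2024, 6L), 100)

  totals$persons[totals$age == 5] <- 90
  totals$persons[totals$age == 6] <- 110
  expect_equal(grade_population(totals, 2024, 5L), 100)
  expect_error(grade_population(totals, 2025, 5L), class = "schooldemand_error_coverage")

  # every grade equals a directly indexed mean
  set.seed(31)
  totals$persons <- runif(50, 100, 1000)
  for (a in 3:14) {
    expect_equal(
      grade_population(totals, 2024, a),
      (totals$persons[totals$age == a] + totals$persons[totals$age == a + 1]) / 2
    )
  }
})

test_that("stage totals are the sum of their grade columns", {
  set.seed(17)
  totals <- dplyr::bind_rows(lapply(2024:2030, function(y) {
    tibble::tibble(year = y, age = 0:49, persons = runif(50, 1e4, 1e6))
  }))
  for (st in default_stages()) {
    enr <- stage_enrollment(totals, st)
    tot <- stage_totals(totals, st)
    by_hand <- vapply(
      2024:2030,
      function(y) sum(grade_population(totals, y, st$labels)), numeric(1)
    )
    expect_equal(tot$students, by_hand)
    sums <- dplyr::summarise(dplyr::group_by(enr, year),
      s = sum(students), .groups = "drop"
    )
    expect_equal(sums$s, tot$students)
  }
  # all-zero population gives zero totals
  z <- tibble::tibble(year = 2024, age = 0:49, persons = 0)
  expect_equal(stage_totals(z, stage_definition("preschool"))$students, 0)
})

test_that("printed stage totals are additive over their printed grade columns", {
  # published totals carry one-decimal rounding of unrounded grade values,
  # so column sums can drift by a few tenths (they do, in two rows)
  t1 <- read.csv(extdata("table1_school_age_population.csv"))
  expect_lt(max(abs(t1$preschool_total - (t1$age_3 + t1$age_4 + t1$age_5))), 0.5)
  expect_lt(
    max(abs(t1$primary_total -
      (t1$age_6 + t1$age_7 + t1$age_8 + t1$age_9 + t1$age_10 + t1$age_11))),
    0.5
  )
  expect_lt(max(abs(t1$junior_total - (t1$age_12 + t1$age_13 + t1$age_14))), 0.5)
  # the 2024 rows are exactly additive: 329.4 + 343.5 + 340.4 = 1013.3
  expect_equal(t1$preschool_total[t1$year == 2024], 1013.3)
  expect_equal(
    sum(t1[t1$year == 2024, c("age_3", "age_4", "age_5")]),
    t1$preschool_total[t1$year == 2024]
  )
})

test_that("first-grade entrants scale the age-6 grade by the enrollment rate", {
  totals <- tibble::tibble(year = 2024, age = 0:49, persons = 200)
  expect_equal(first_grade_entrants(totals, 2024, 100), 200)
  expect_equal(first_grade_entrants(totals, 2024, 0), 0)
  expect_equal(first_grade_entrants(totals, 2024, 95), 190)
})

test_that("stock updates follow the balance equations and reject inconsistency", {
  expect_equal(update_primary_stock(1000, 150, 150), 1000)
  expect_equal(update_primary_stock(1000, 200, 100), 900)
  expect_error(update_primary_stock(100, 150, 10), class = "schooldemand_error_validation")

  expect_equal(update_junior_stock(300, 100, 100, 1), 300)
  expect_equal(update_junior_stock(300, 100, 100, 0), 200)
  expect_error(update_junior_stock(300, 100, 100, 1.5), class = "schooldemand_error_validation")
})

test_that("grade progression has the geometric fixed point I / (1 - P)", {
  expect_equal(progress_grade(100, 1, 0), 100)
  expect_equal(progress_grade(100, 0.9, 10), 100)
  s <- 0
  for (i in 1:200) s <- progress_grade(s, 0.8, 20)
  expect_equal(s, 100, tolerance = 1e-6)
  expect_error(progress_grade(10, 1.6, 0), class = "schooldemand_error_validation")
})

test_that("stock-flow recursion equals cross-sectional sums on a shifting population", {
  set.seed(8)
  base <- runif(50, 500, 1500)
  totals <- shift_totals(2024, 12, base)
  sf <- stock_flow_series(totals, 2024:2035)
  cross_primary <- vapply(2024:2035, function(y) sum(grade_population(totals, y, 6:11)), numeric(1))
  cross_junior <- vapply(2024:2035, function(y) sum(grade_population(totals, y, 12:14)), numeric(1))
  expect_equal(sf$primary, cross_primary, tolerance = 1e-9)
  expect_equal(sf$junior, cross_junior, tolerance = 1e-9)

  # grade-resolved recursion agrees too under full enrollment and admission
  gp <- grade_progression_series(totals, 2024:2035)
  expect_equal(gp$primary, cross_primary, tolerance = 1e-9)
  expect_equal(gp$junior, cross_junior, tolerance = 1e-9)
})

test_that("with admission stopped the junior stage empties within three years", {
  set.seed(12)
  totals <- shift_totals(2024, 8, runif(50, 500, 1500))
  gp <- grade_progression_series(totals, 2024:2031, a = 0)
  expect_true(all(gp$junior[gp$year >= 2027] == 0))
  expect_true(all(diff(gp$junior[1:4]) < 0))
})
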