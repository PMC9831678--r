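test_that("cohort fixture expands to the published margins", {
  cohort <- table1_cohort()
  expect_equal(nrow(cohort), 218L)
  expect_equal(sum(cohort$culture_result == "negative"), 113L)
  expect_equal(sum(cohort$culture_result == "positive"), 105L)

  diab <- crosstab(cohort, "diabetes")
  expect_equal(unclass(diab),
               matrix(c(9L, 104L, 22L, 83L), 2, byrow = TRUE,
                      dimnames = list(culture_result = c("negative",
                                                         "positive"),
                                      diabetes = c("Yes", "No"))))
  tstg <- crosstab(cohort, "t_staging")
  expect_equal(unname(unclass(tstg)),
               matrix(c(56L, 37L, 20L, 33L, 20L, 52L), 2, byrow = TRUE))
  expect_equal(unname(rowSums(tstg)), c(113, 105))

  expect_error(crosstab(cohort[0, ], "diabetes"), "empty")
  one_level <- dplyr::mutate(cohort, fixed = factor("x"))
  expect_error(crosstab(one_level, "fixed"), "single observed level")
})

test_that("chi-square test reproduces the published cohort p-values", {
  flat <- chi_square_test(contingency_table(matrix(10, 2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  cohort <- table1_cohort()
  diab <- chi_square_test(crosstab(cohort, "diabetes"))
  expect_equal(diab$test, "chi-square (Yates)")
  expect_equal(diab$dof, 1)
  expect_equal(round(diab$p_value, 3), 0.011)
  expect_equal(diab$statistic, 6.4994, tolerance = 1e-4)

  tstg <- chi_square_test(crosstab(cohort, "t_staging"))
  expect_equal(tstg$test, "chi-square (Pearson)")
  expect_equal(tstg$dof, 2)
  expect_lt(tstg$p_value, 0.001)
  expect_equal(tstg$statistic, 24.976, tolerance = 1e-3)

  met <- chi_square_test(crosstab(cohort, "cervical_lymph_node_metastasis"))
  expect_equal(round(met$p_value, 3), 0.040)

  # invariant to row/column permutation
  m <- unclass(crosstab(cohort, "t_staging"))
  shuf <- contingency_table(m[2:1, c(3, 1, 2)])
  expect_equal(chi_square_test(shuf)$statistic, tstg$statistic,
               tolerance = 1e-12)

  tiny <- chi_square_test(contingency_table(matrix(c(1, 0, 50, 50), 2)))
  expect_true(tiny$small_expected)
})

test_that("pooled t-tests work from values and from printed summaries", {
  ident <- two_sample_location_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1, tolerance = 1e-12)

  sep <- two_sample_location_test(c(0, 0, 0, 0) + c(1e-4, -1e-4, 0, 0),
                                  c(10, 10, 10, 10) + c(1e-4, -1e-4, 0, 0))
  expect_lt(sep$p_value, 1e-6)

  flat <- two_sample_location_test(rep(2, 5), rep(2, 4))
  expect_equal(flat$p_value, 1)

  age <- t_test_from_summary(113, 52.06, 12.59, 105, 52.81, 12.44,
                             variable = "age")
  expect_equal(round(age$p_value, 2), 0.66)

  # summary-form equals value-form on generated data
  withr::with_seed(40, {
    x <- stats::rnorm(30, 5, 2); y <- stats::rnorm(25, 6, 2)
    a <- two_sample_location_test(x, y)
    b <- t_test_from_summary(30, mean(x), sd(x), 25, mean(y), sd(y))
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  })
})

test_that("cohort summary reproduces the published headline numbers", {
  cohort <- table1_cohort()
  smry <- cohort_summary(cohort, continuous = table1_continuous())
  expect_equal(smry$n_total, 218L)
  male <- smry$categorical[smry$categorical$variable == "gender" &
                             smry$categorical$level == "Male", ]
  expect_equal(male$count, 149L)
  expect_equal(male$pct, 68.3)
  age <- smry$continuous_pooled$pooled_mean[
    smry$continuous_pooled$variable == "age"]
  expect_equal(round(age, 1), 52.4)
  # percentages sum to 100 per variable (up to rounding)
  per_var <- tapply(smry$categorical$pct, smry$categorical$variable, sum)
  expect_true(all(abs(per_var - 100) <= 0.1 + 1e-9))

  single <- cohort_summary(cohort[1, ])
  expect_equal(single$n_total, 1L)
  expect_equal(
    as.character(single$categorical$level[
      single$categorical$variable == "gender" &
        single$categorical$count == 1]),
    as.character(cohort$gender[1]))
})

test_that("association screen flags exactly the published significant set", {
  cohort <- table1_cohort()
  screen <- association_screen(cohort)
  expect_equal(screen$variable,
               setdiff(names(cohort), c("patient_id", "culture_result")))
  expect_setequal(
    screen$variable[screen$significant],
    c("diabetes", "t_staging", "cervical_lymph_node_metastasis"))
  expect_true(all(screen$significant == (screen$p_value < 0.05)))

  cont <- screen_continuous_summary(table1_continuous())
  expect_false(any(cont$significant))
  expect_equal(round(cont$p_value[cont$variable == "age"], 2), 0.66)

  expect_equal(nrow(association_screen(cohort, character(0))), 0L)
  expect_error(association_screen(cohort, "nope"), "nope")

  adj <- association_screen(cohort, p_adjust = TRUE)
  expect_true(all(adj$p_adjusted >= adj$p_value - 1e-12))
})

test_that("screen holds its size on outcome-shuffled cohorts", {
  cohort <- table1_cohort()
  n_rep <- 60
  flags <- 0; total <- 0
  for (i in seq_len(n_rep)) {
    shuffled <- dplyr::mutate(
      cohort,
      culture_result = withr::with_seed(500 + i, sample(culture_result)))
    s <- association_screen(shuffled)
    flags <- flags + sum(s$significant)
    total <- total + nrow(s)
  }
  # Yates correction makes the 2x2 rows conservative, so the pooled rate
  # sits at or below the nominal 5%
  expect_lte(flags / total, 0.08)
})
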