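test_that("attainment-loss draws scale with days and centre correctly", {
  expect_equal(attainment_loss_draws(0, "male", n = 50, seed = 1),
               rep(0, 50))
  boys <- attainment_loss_draws(54, "male", n = 5e4, seed = 2)
  girls <- attainment_loss_draws(54, "female", n = 5e4, seed = 2)
  expect_true(all(boys >= 0) && all(girls >= 0))
  expect_equal(median(boys), 54 * 0.0262 / 10, tolerance = 0.01)
  expect_equal(median(girls), 54 * 0.0217 / 10, tolerance = 0.01)
  expect_error(attainment_loss_draws(54, "child"), "arg")
  expect_error(attainment_loss_draws(-3, "male"), "non-negative")
})

test_that("hazard multipliers follow the relative-risk power law", {
  expect_identical(hazard_multiplier(0.75, 0), 1)
  expect_equal(hazard_multiplier(0.75, 1), 4 / 3)
  expect_equal(hazard_multiplier(0.75, 0.1415),
               exp(0.1415 * log(1 / 0.75)))
  expect_equal(hazard_multiplier(0.75, 0.1415), 1.0415, tolerance = 1e-4)
  expect_error(hazard_multiplier(-0.1, 1), "positive")
})

test_that("per-child YLL vanishes at multiplier 1 and matches the oracle", {
  lt <- child_toy_table()
  expect_equal(per_child_yll(lt, 8, 1), 0)
  for (m in c(1.05, 1.3)) {
    for (rate in c(0, 0.03)) {
      q2 <- lt$qx
      q2[9:15] <- pmin(1, q2[9:15] * m)
      q2[15] <- 1
      expect_equal(per_child_yll(lt, 8, m, rate = rate, horizon = Inf),
                   oracle_expectancy(lt$qx, 8, rate) -
                     oracle_expectancy(q2, 8, rate),
                   tolerance = 1e-12)
    }
  }
  expect_true(per_child_yll(lt, 8, 1.2) > 0)
  expect_error(per_child_yll(lt, 3, 1.2), "5-11")
})

test_that("population YLL equals the cell-by-cell hand computation", {
  # zero-variance draws make the whole stage deterministic
  tabs <- builtin_life_tables()
  pop <- data.frame(state = rep(c("A", "B"), each = 4),
                    sex = rep(c("male", "female"), 4),
                    race = "All",
                    age = c(5, 7, 9, 11, 6, 8, 10, 11),
                    count = c(100, 250, 0, 50, 80, 120, 200, 10))
  closures <- data.frame(state = c("A", "B"), closure_days = c(40, 70))
  draws <- list(rr = rep(0.75, 3), coef_male = rep(0.0262, 3),
                coef_female = rep(0.0217, 3))
  for (rate in c(0, 0.03)) {
    got <- population_education_yll(pop, closures, tabs, rate = rate,
                                    draws = draws)
    manual <- 0
    for (i in seq_len(nrow(pop))) {
      days <- closures$closure_days[closures$state == pop$state[i]]
      coef <- if (pop$sex[i] == "male") 0.0262 else 0.0217
      m <- hazard_multiplier(0.75, days / 10 * coef)
      manual <- manual + pop$count[i] *
        per_child_yll(tabs[[pop$sex[i]]], pop$age[i], m, rate = rate)
    }
    expect_equal(got, rep(manual, 3), tolerance = 1e-9)
  }
})

test_that("population YLL is linear in counts and zero for no children", {
  tabs <- builtin_life_tables()
  pop <- data.frame(state = "A", sex = c("male", "female"), race = "All",
                    age = c(8, 9), count = c(1000, 1200))
  closures <- data.frame(state = "A", closure_days = 54)
  draws <- draw_model_params(n = 200, seed = 5)
  base <- population_education_yll(pop, closures, tabs, draws = draws)
  pop2 <- pop
  pop2$count <- 2 * pop2$count
  expect_equal(population_education_yll(pop2, closures, tabs, draws = draws),
               2 * base, tolerance = 1e-12)
  empty <- pop[0, ]
  expect_equal(population_education_yll(empty, closures, tabs,
                                        draws = draws),
               rep(0, 200))
})

test_that("more missed school days means more life lost, draw by draw", {
  tabs <- builtin_life_tables()
  pop <- data.frame(state = "A", sex = "male", race = "All", age = 8,
                    count = 1e6)
  draws <- draw_model_params(n = 500, seed = 6)
  y40 <- population_education_yll(pop, data.frame(state = "A",
                                                  closure_days = 40),
                                  tabs, draws = draws)
  y80 <- population_education_yll(pop, data.frame(state = "A",
                                                  closure_days = 80),
                                  tabs, draws = draws)
  # shared parameter draws: dominance holds pathwise where rr < 1
  protective <- draws$rr < 1
  expect_true(all(y80[protective] >= y40[protective]))
  expect_true(median(y80) > median(y40))
})

test_that("education YLL medians shrink as the discount rate grows", {
  tabs <- builtin_life_tables()
  pop <- data.frame(state = "A", sex = c("male", "female"), race = "All",
                    age = 8, count = c(5e5, 5e5))
  closures <- data.frame(state = "A", closure_days = 54)
  draws <- draw_model_params(n = 500, seed = 7)
  meds <- vapply(c(0, 0.005, 0.03), function(r)
    median(population_education_yll(pop, closures, tabs, rate = r,
                                    draws = draws)), 0)
  expect_true(meds[3] < meds[2] && meds[2] < meds[1])
})

test_that("education YLL draws are almost surely non-negative", {
  tabs <- builtin_life_tables()
  pop <- data.frame(state = "A", sex = "male", race = "All", age = 8,
                    count = 1000)
  closures <- data.frame(state = "A", closure_days = 54)
  y <- population_education_yll(pop, closures, tabs, n = 2000, seed = 8)
  expect_gt(mean(y >= 0), 0.99)
})

test_that("strata without a life table are a configuration error", {
  tabs <- builtin_life_tables()
  pop <- data.frame(state = "A", sex = "male", race = "All", age = 8,
                    count = 10)
  closures <- data.frame(state = "A", closure_days = 54)
  expect_error(population_education_yll(pop, closures,
                                        tabs["female"], n = 10, seed = 1),
               "no life table")
  expect_error(population_education_yll(pop,
                                        data.frame(state = "B",
                                                   closure_days = 1),
                                        tabs, n = 10, seed = 1),
               "no closure duration")
  # race-specific override takes precedence over the sex-level table
  race_tabs <- c(tabs, list("male:Black" = tabs$female))
  popb <- transform(pop, race = "Black")
  draws <- list(rr = 0.8, coef_male = 0.03, coef_female = 0.02)
  got <- population_education_yll(popb, closures, race_tabs, draws = draws)
  m <- hazard_multiplier(0.8, 5.4 * 0.03)
  expect_equal(got, 10 * per_child_yll(tabs$female, 8, m), tolerance = 1e-9)
})

test_that("effect-parameter constructors validate their inputs", {
  expect_error(attainment_effect(male_coef = -1), "non-negative")
  expect_error(education_mortality_effect(rr_mean = 0.5,
                                          rr_ci = c(0.6, 0.9)), "bracket")
  em <- education_mortality_effect()
  expect_equal(em$rr_sd, (0.90 - 0.60) / (2 * qnorm(0.975)))
})
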