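test_that("the generated population matches its specification exactly", {
  spec <- population_spec()
  pop <- generate_population(spec)
  expect_identical(sum(pop$count), 24200000L)
  race_totals <- tapply(pop$count, pop$race, sum)
  expect_identical(unname(race_totals["White"]), 11400000L)
  expect_identical(unname(race_totals["Hispanic"]), 4300000L)
  expect_identical(unname(race_totals["Black"]), 3600000L)
  expect_identical(unname(race_totals["Other"]), 4900000L)
  expect_true(all(pop$age %in% 5:11))
  expect_true(all(pop$count >= 0))
  # male share lands on the specified fraction
  expect_equal(sum(pop$count[pop$sex == "male"]) / sum(pop$count), 0.512,
               tolerance = 1e-5)
  expect_identical(generate_population(spec, seed = 1),
                   generate_population(spec, seed = 2))
})

test_that("infeasible population specifications are rejected", {
  expect_error(population_spec(total_children = 1e6,
                               race_counts = c(White = 2e6, Black = 1e6,
                                               Hispanic = 0, Other = 0)),
               "sum")
  expect_error(population_spec(male_fraction = 1.2), "\\(0, 1\\)")
  expect_error(population_spec(n_states = 3), "state_shares")
  small <- population_spec(total_children = 1000,
                           race_counts = c(White = 600, Hispanic = 200,
                                           Black = 100, Other = 100),
                           n_states = 2, state_shares = c(0.5, 0.5))
  expect_identical(sum(generate_population(small)$count), 1000L)
})

test_that("closure durations hit the published median and IQR every seed", {
  spec <- population_spec()
  for (seed in c(1, 7, 99, 2024)) {
    cl <- generate_closure_days(spec, seed = seed)
    expect_identical(nrow(cl), 51L)
    expect_lte(abs(median(cl$closure_days) - 54), 2)
    q <- quantile(cl$closure_days, c(0.25, 0.75), names = FALSE)
    expect_lte(abs(q[1] - 48), 2)
    expect_lte(abs(q[2] - 62.5), 2)
  }
  # same seed, same assignment
  expect_identical(generate_closure_days(spec, seed = 3),
                   generate_closure_days(spec, seed = 3))
})

test_that("a collapsed IQR gives every state the median closure", {
  spec <- population_spec(closure_iqr = c(54, 54))
  cl <- generate_closure_days(spec, seed = 1)
  expect_true(all(cl$closure_days == 54))
})

test_that("the calibrated closure distribution has the target quartiles", {
  cal <- schoolyll:::calibrate_closure_beta(54, c(48, 62.5))
  set.seed(10)
  big <- cal$lower + (cal$upper - cal$lower) *
    rbeta(1e5, cal$alpha, cal$beta)
  q <- quantile(big, c(0.25, 0.5, 0.75), names = FALSE)
  expect_lte(abs(q[1] - 48), 1)
  expect_lte(abs(q[2] - 54), 1)
  expect_lte(abs(q[3] - 62.5), 1)
})

test_that("the bundled death table matches the published one", {
  tbl <- builtin_death_table()
  expect_identical(total_deaths(tbl), 88241L)
  expect_identical(tbl$deaths[tbl$sex == "female" &
                                tbl$midpoint_age == 85], 17647L)
  expect_identical(nrow(as.data.frame(tbl)), 22L)
})

test_that("the death table round-trips losslessly through CSV", {
  tbl <- builtin_death_table()
  path <- tempfile(fileext = ".csv")
  write_death_bands(tbl, path)
  again <- read_death_bands(path)
  expect_identical(as.data.frame(again), as.data.frame(tbl))
})

test_that("bundled anchors are valid and shape the fitted tables", {
  anchors <- builtin_expectancy_anchors()
  for (sex in c("male", "female")) {
    a <- anchors[[sex]]
    adult <- a$ex[a$age >= 1]
    expect_true(all(diff(adult) < 0))
    expect_identical(nrow(a), 11L)
  }
  expect_equal(anchors$male$ex[anchors$male$age == 0], 76.0)
  lt <- life_table_from_anchors(anchors$male, sex = "male")
  expect_equal(remaining_life(lt, 50), 29.7, tolerance = 0.2)
})

test_that("state shares form a proper weight vector", {
  shares <- builtin_state_shares()
  expect_identical(length(shares), 51L)
  expect_equal(sum(shares), 1)
  expect_true(all(shares > 0))
})

test_that("generated inputs pass their consumers' validation", {
  spec <- population_spec()
  pop <- generate_population(spec)
  cl <- generate_closure_days(spec, seed = 4)
  tabs <- builtin_life_tables()
  draws <- list(rr = 0.75, coef_male = 0.0262, coef_female = 0.0217)
  expect_no_error(population_education_yll(pop, cl, tabs, draws = draws))
})
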